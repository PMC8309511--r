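#' Construct a gaze recording
#'
#' A gaze recording is the basic container handled by every stage of the
#' package: a time-ordered table of gaze samples plus the screen geometry,
#' the coordinate unit, and the tracker's nominal sampling rate. Timestamps
#' are milliseconds since the start of the recording and must be strictly
#' increasing. Per-sample validity flags record whether each eye was detected
#' by the tracker; when a tracker does not report them they default to valid.
#'
#' @param samples A data.frame with columns `t` (ms), `x`, `y`, and optionally
#'   logical `valid_l`, `valid_r`.
#' @param geometry A [screen_geometry()] object.
#' @param unit `"pixels"` or `"degrees"` — the unit of `x`/`y`.
#' @param nominal_rate Nominal sampling rate in Hz (e.g. 40 or 500).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, geometry, unit = c("pixels", "degrees"),
                           nominal_rate) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(samples))
  need <- c("t", "x", "y")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns t, x, y")
  }
  if (is.null(samples$valid_l)) samples$valid_l <- TRUE
  if (is.null(samples$valid_r)) samples$valid_r <- TRUE
  samples <- samples[, c("t", "x", "y", "valid_l", "valid_r")]
  if (any(!is.finite(samples$t)) || any(samples$t < 0)) {
    stop("timestamps must be finite and non-negative")
  }
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!inherits(geometry, "screen_geometry")) {
    stop("geometry must be a screen_geometry object")
  }
  if (!is.numeric(nominal_rate) || nominal_rate <= 0) {
    stop("nominal_rate must be positive")
  }
  structure(
    list(samples = samples, geometry = geometry, unit = unit,
         nominal_rate = nominal_rate),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  dur <- if (n > 1) (x$samples$t[n] - x$samples$t[1]) / 1000 else 0
  cat(sprintf("gaze_recording: %d samples, %.2f s, unit = %s, nominal %g Hz\n",
              n, dur, x$unit, x$nominal_rate))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A `gaze_recording`.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Read a gaze CSV file
#'
#' Reads a comma-separated gaze export with header `t,x,y` and optional
#' `valid_l,valid_r` columns (`t` in milliseconds). Rows that do not parse as
#' numbers raise an error naming the offending line; non-increasing
#' timestamps raise a validation error.
#'
#' @param path CSV file path.
#' @param geometry A [screen_geometry()] object.
#' @param unit Unit of the stored coordinates, `"pixels"` or `"degrees"`.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return A [gaze_recording()].
#' @export
read_gaze_csv <- function(path, geometry, unit = c("pixels", "degrees"),
                          nominal_rate = 40) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("gaze CSV must have columns t, x, y")
  }
  for (col in intersect(c("t", "x", "y"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("malformed value in column '%s' at data line %d of %s",
                     col, bad[1], path))
      }
      df[[col]] <- vn
    }
  }
  if (anyNA(df$t) || anyNA(df$x) || anyNA(df$y)) {
    bad <- which(is.na(df$t) | is.na(df$x) | is.na(df$y))[1]
    stop(sprintf("missing value at data line %d of %s", bad, path))
  }
  for (col in c("valid_l", "valid_r")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  gaze_recording(df, geometry, unit, nominal_rate)
}

#' Write a gaze recording to CSV
#'
#' Inverse of [read_gaze_csv()]; writes `t,x,y,valid_l,valid_r`.
#'
#' @param rec A `gaze_recording`.
#' @param path Output file path.
#' @export
write_gaze_csv <- function(rec, path) {
  utils::write.csv(rec$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove binocular dropouts
#'
#' Blinks and tracking losses appear as samples that were detected in neither
#' eye; those samples are treated as outliers and removed. Samples detected
#' in at least one eye are retained. Ordering of the surviving samples is
#' preserved.
#'
#' @param rec A `gaze_recording`.
#' @return A list with `recording` (the filtered recording) and `mask`
#'   (logical, one entry per input sample, `TRUE` where a sample was removed).
#' @export
remove_binocular_dropouts <- function(rec) {
  drop <- !rec$samples$valid_l & !rec$samples$valid_r
  out <- rec
  out$samples <- rec$samples[!drop, , drop = FALSE]
  rownames(out$samples) <- NULL
  list(recording = out, mask = drop)
}

#' Convert a recording from pixels to degrees of visual angle
#'
#' Positions are re-expressed as visual angle from the screen center using
#' the recording's geometry. If the recording is already in degrees it is
#' returned unchanged with a warning.
#'
#' @param rec A `gaze_recording` with `unit == "pixels"`.
#' @return The recording with `unit == "degrees"`.
#' @export
to_degrees <- function(rec) {
  if (rec$unit == "degrees") {
    warning("recording already in degrees; returning unchanged")
    return(rec)
  }
  d <- pixels_to_degrees(rec$samples$x, rec$samples$y, rec$geometry)
  rec$samples$x <- d$x
  rec$samples$y <- d$y
  rec$unit <- "degrees"
  rec
}

#' Convert a recording from degrees back to pixels
#'
#' @param rec A `gaze_recording` with `unit == "degrees"`.
#' @return The recording with `unit == "pixels"`.
#' @export
to_pixels <- function(rec) {
  if (rec$unit == "pixels") {
    warning("recording already in pixels; returning unchanged")
    return(rec)
  }
  p <- degrees_to_pixels(rec$samples$x, rec$samples$y, rec$geometry)
  rec$samples$x <- p$x
  rec$samples$y <- p$y
  rec$unit <- "pixels"
  rec
}

#' Per-sample angular velocities
#'
#' Velocity is the two-point backward difference: the Euclidean angular
#' displacement between samples i-1 and i divided by their time difference,
#' in deg/s. The first sample's velocity is defined as 0, so the first sample
#' can never start a saccade.
#'
#' @param rec A `gaze_recording` in degrees.
#' @return Numeric vector of length `n_samples(rec)`.
#' @export
sample_velocities <- function(rec) {
  if (rec$unit != "degrees") stop("velocities require a recording in degrees")
  n <- nrow(rec$samples)
  if (n < 2) stop("velocity computation requires at least 2 samples")
  dx <- diff(rec$samples$x)
  dy <- diff(rec$samples$y)
  dt <- diff(rec$samples$t) / 1000  # ms -> s
  c(0, sqrt(dx^2 + dy^2) / dt)
}

#' Angular velocity at one sample
#'
#' @param rec A `gaze_recording` in degrees.
#' @param i Sample index, `2 <= i <= n`; index 1 returns 0 by convention.
#' @return Velocity in deg/s.
#' @export
sample_velocity <- function(rec, i) {
  n <- nrow(rec$samples)
  if (i < 1 || i > n) stop("index out of range")
  if (i == 1) return(0)
  sample_velocities(rec)[i]
}
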