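#' Specification of a behavior window
#'
#' A behavior window is a square raster, centered on the current gaze sample,
#' onto which the recent gaze trail is drawn as dots on a black background.
#' The dots become more transparent the further back in time they lie, so the
#' raster encodes the local movement behavior: a tight bright blob for a
#' stationary eye, a compact trail for smooth pursuit, and sparse separated
#' dots for a saccade. The default extent is 32 x 32 degrees — wide enough
#' that a 10-30 deg/s pursuit trail stays inside the window — rasterized at
#' 64 x 64 pixels so the 1-2 degree foveal structure is resolved.
#'
#' @param extent_deg Side length of the window in degrees.
#' @param resolution_px Raster side length in pixels (>= 8).
#' @param history_n Number of past samples included beyond the current one.
#' @param fade Function mapping age (0 = current sample) to opacity in (0,1];
#'   must be strictly decreasing with `fade(0) = 1`. Default is linear:
#'   `(history_n + 1 - age) / (history_n + 1)`.
#' @param dot_radius_px Dot radius in pixels.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(extent_deg = 32, resolution_px = 64, history_n = 8,
                        fade = NULL, dot_radius_px = 1) {
  stopifnot(extent_deg > 0, resolution_px >= 8, history_n >= 0)
  if (is.null(fade)) {
    fade <- local({
      h <- history_n
      function(age) (h + 1 - age) / (h + 1)
    })
  }
  if (abs(fade(0) - 1) > 1e-12) stop("fade(0) must equal 1")
  if (history_n > 0) {
    vals <- vapply(0:history_n, fade, 1)
    if (any(diff(vals) >= 0)) stop("fade must be strictly decreasing in age")
    if (any(vals <= 0)) stop("fade must stay positive over the history")
  }
  structure(
    list(extent_deg = extent_deg, resolution_px = resolution_px,
         history_n = history_n, fade = fade, dot_radius_px = dot_radius_px),
    class = "window_spec"
  )
}

# degree -> raster index map for a window centered at (cx, cy):
# the window spans [c - extent/2, c + extent/2]; a coordinate maps to
# column/row floor((p - lo) / extent * res) + 1. The anchor itself lands at
# index res/2 + 1 (for even res), the raster center. The bin coordinate is
# rounded to 1e-9 before flooring so that translating the whole recording
# (which perturbs p - lo by ~1 ulp) cannot flip a sample sitting exactly on
# a bin boundary.
.win_index <- function(p, lo, extent, res) {
  floor(round((p - lo) / extent * res, 9)) + 1
}

#' Extract one behavior window
#'
#' Renders samples `i - history_n ... i` of the recording into a square
#' grayscale raster centered on sample `i`. Dots are drawn oldest-first with
#' opacity `fade(age)`, so the newest (full-opacity) dot is on top; samples
#' outside the window or before the start of the recording are skipped.
#' Overlapping dots combine by maximum intensity, keeping intensities between 0 and 1.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param i Anchor sample index (1-based).
#' @param spec A [window_spec()].
#' @return A list of class `behavior_window` with fields `raster`
#'   (`resolution_px` x `resolution_px` matrix, rows = y), `anchor_index`,
#'   and `label` (initialized to `"unlabeled"`).
#' @export
extract_window <- function(rec, i, spec = window_spec()) {
  n <- nrow(rec$samples)
  if (i < 1 || i > n) stop("anchor index out of range")
  if (rec$unit != "degrees") stop("behavior windows require degrees")
  res <- spec$resolution_px
  cx <- rec$samples$x[i]
  cy <- rec$samples$y[i]
  lo_x <- cx - spec$extent_deg / 2
  lo_y <- cy - spec$extent_deg / 2
  raster <- matrix(0, nrow = res, ncol = res)
  first <- max(1, i - spec$history_n)
  idx <- first:i
  ages <- i - idx
  # oldest first so the newest dot is drawn on top
  ord <- order(ages, decreasing = TRUE)
  r_dot <- spec$dot_radius_px
  offs <- expand.grid(dx = -r_dot:r_dot, dy = -r_dot:r_dot)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_dot^2, ]
  for (k in ord) {
    col <- .win_index(rec$samples$x[idx[k]], lo_x, spec$extent_deg, res)
    row <- .win_index(rec$samples$y[idx[k]], lo_y, spec$extent_deg, res)
    if (col < 1 || col > res || row < 1 || row > res) next
    a <- spec$fade(ages[k])
    rr <- row + offs$dy
    cc <- col + offs$dx
    keep <- rr >= 1 & rr <= res & cc >= 1 & cc <= res
    ij <- cbind(rr[keep], cc[keep])
    raster[ij] <- pmax(raster[ij], a)
  }
  structure(
    list(raster = raster, anchor_index = i, label = "unlabeled"),
    class = "behavior_window"
  )
}

#' Extract one window per sample of a recording
#'
#' The window slides from the first to the last sample in time order,
#' producing exactly one [extract_window()] result per sample.
#'
#' @inheritParams extract_window
#' @param indices Optional subset of anchor indices (default all samples).
#' @return List of `behavior_window` objects.
#' @export
extract_windows <- function(rec, spec = window_spec(), indices = NULL) {
  if (is.null(indices)) indices <- seq_len(nrow(rec$samples))
  lapply(indices, function(i) extract_window(rec, i, spec))
}

#' Map oculomotor event labels to the stare/move taxonomy
#'
#' Fixation and smooth pursuit are both actions that hold the target on the
#' fovea, so they map to `stare`; saccades and post-saccadic oscillations are
#' repositioning movements and map to `move`. Anything else (blinks, unknown)
#' maps to `unlabeled` and is excluded from training datasets.
#'
#' @param labels Character vector of per-sample event labels (alphabet:
#'   `fixation`, `smooth_pursuit`, `saccade`, `pso`, other).
#' @return Character vector over `stare` / `move` / `unlabeled`.
#' @export
behavior_labels <- function(labels) {
  out <- rep("unlabeled", length(labels))
  out[labels %in% c("fixation", "smooth_pursuit")] <- "stare"
  out[labels %in% c("saccade", "pso")] <- "move"
  out
}

#' Label behavior windows from per-sample ground truth
#'
#' Assigns each window the stare/move behavior of its anchor sample via
#' [behavior_labels()].
#'
#' @param windows List of `behavior_window` objects.
#' @param truth Character vector of per-sample event labels covering every
#'   anchor index.
#' @return The windows with `label` filled in.
#' @export
label_from_events <- function(windows, truth) {
  lapply(windows, function(w) {
    if (w$anchor_index > length(truth) || is.na(truth[w$anchor_index])) {
      stop("missing truth label for anchor index ", w$anchor_index)
    }
    w$label <- behavior_labels(truth[w$anchor_index])[1]
    w
  })
}

#' Build a balanced stare/move image dataset
#'
#' Collects labeled behavior windows from one or more recordings, draws
#' exactly `n_per_class` windows of each class (sampling without replacement
#' with the given seed), and splits each class by `split` into training and
#' validation sets. Optionally serializes the images as 8-bit grayscale PNG
#' files under `out_dir` (`train/stare/*.png`, `train/move/*.png`,
#' `val/...`) plus a `manifest.csv` (file, recording_id, anchor_index,
#' label).
#'
#' @param recordings List of lists with elements `recording` (a
#'   `gaze_recording` in degrees) and `truth` (per-sample event labels), as
#'   returned by [simulate_gaze()].
#' @param spec A [window_spec()].
#' @param n_per_class Number of windows to keep per class.
#' @param split Fraction of each class assigned to the training set.
#' @param seed Integer seed for the class subsampling and the split.
#' @param out_dir Optional output directory for PNG serialization.
#' @return A list with `train` and `val`, each containing `x` (matrix,
#'   one flattened raster per row), `y` (factor with levels `move`, `stare`),
#'   and `manifest` (data.frame); and `spec`.
#' @export
build_dataset <- function(recordings, spec = window_spec(), n_per_class,
                          split = 0.5, seed = 1L, out_dir = NULL) {
  stopifnot(split > 0, split < 1)
  # first pass: anchors and labels only; rasterize just the selected windows
  pool_lab <- character(0)
  pool_rec <- integer(0)
  pool_anchor <- integer(0)
  for (rid in seq_along(recordings)) {
    truth <- recordings[[rid]]$truth
    beh <- behavior_labels(truth)
    keep <- which(beh != "unlabeled")
    pool_lab <- c(pool_lab, beh[keep])
    pool_rec <- c(pool_rec, rep(rid, length(keep)))
    pool_anchor <- c(pool_anchor, keep)
  }
  counts <- table(pool_lab)
  for (cl in c("stare", "move")) {
    have <- if (cl %in% names(counts)) counts[[cl]] else 0
    if (have < n_per_class) {
      stop(sprintf("insufficient %s windows: need %d, have %d (short by %d)",
                   cl, n_per_class, have, n_per_class - have))
    }
  }
  .with_seed(seed, {
    sel <- lapply(c("move", "stare"), function(cl) {
      cand <- which(pool_lab == cl)
      cand <- cand[sample.int(length(cand), n_per_class)]
      n_tr <- round(n_per_class * split)
      list(train = cand[seq_len(n_tr)],
           val = cand[(n_tr + 1):n_per_class])
    })
  })
  names(sel) <- c("move", "stare")
  pack <- function(which_set) {
    ix <- c(sel$move[[which_set]], sel$stare[[which_set]])
    x <- matrix(0, nrow = length(ix), ncol = spec$resolution_px^2)
    for (k in seq_along(ix)) {
      w <- extract_window(recordings[[pool_rec[ix[k]]]]$recording,
                          pool_anchor[ix[k]], spec)
      x[k, ] <- as.vector(w$raster)
    }
    y <- factor(pool_lab[ix], levels = c("move", "stare"))
    manifest <- data.frame(
      file = sprintf("%s/%s/w%06d.png", which_set, pool_lab[ix], ix),
      recording_id = pool_rec[ix],
      anchor_index = pool_anchor[ix],
      label = pool_lab[ix],
      stringsAsFactors = FALSE
    )
    list(x = x, y = y, manifest = manifest)
  }
  out <- list(train = pack("train"), val = pack("val"), spec = spec)
  if (!is.null(out_dir)) {
    res <- spec$resolution_px
    for (set in c("train", "val")) {
      for (cl in c("stare", "move")) {
        dir.create(file.path(out_dir, set, cl), recursive = TRUE,
                   showWarnings = FALSE)
      }
      d <- out[[set]]
      for (k in seq_len(nrow(d$x))) {
        img <- matrix(d$x[k, ], nrow = res)
        png::writePNG(img, file.path(out_dir, d$manifest$file[k]))
      }
      utils::write.csv(d$manifest,
                       file.path(out_dir, paste0("manifest_", set, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  out
}
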