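#' FQnS: fixation qualitative score
#'
#' Fraction (as a percentage) of stimulus fixation samples for which the
#' detector reports a fixation at that time with a centroid within
#' `dist_tol` degrees of the stimulus position. A saccadic-latency allowance
#' excludes the first `latency_ms` of every stimulus fixation period from
#' the comparison, since the eye cannot land on a new target instantly.
#' 100 means every (non-latency) stimulus fixation sample was matched.
#'
#' @param detected A `gaze_events` data.frame from a detector.
#' @param stim A `stimulus_signal` aligned to the same recording (equal
#'   sample count).
#' @param dist_tol Centroid-to-stimulus tolerance in degrees (default 1.5,
#'   mid-foveal).
#' @param latency_ms Saccadic-latency allowance after each stimulus
#'   transition.
#' @param labels Detector labels counted as fixation.
#' @return Percentage in `[0, 100]`.
#' @export
fqns <- function(detected, stim, dist_tol = 1.5, latency_ms = 200,
                 labels = c("fixation", "stare")) {
  n <- nrow(stim)
  eligible <- .stim_fix_eligible(stim, latency_ms)
  if (!any(stim$type == "fixation")) {
    stop("stimulus contains no fixation samples")
  }
  det <- .detected_centroid_per_sample(detected, n, labels)
  matched <- eligible & !is.na(det$cx) &
    sqrt((det$cx - stim$x)^2 + (det$cy - stim$y)^2) <= dist_tol
  100 * sum(matched) / sum(eligible)
}

# stimulus fixation samples past the latency window of their period
.stim_fix_eligible <- function(stim, latency_ms) {
  is_fix <- stim$type == "fixation"
  r <- rle(is_fix)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  eligible <- rep(FALSE, nrow(stim))
  for (q in which(r$values)) {
    a <- starts[q]; b <- ends[q]
    t0 <- stim$t[a]
    keep <- which(stim$t[a:b] - t0 >= latency_ms)
    # periods shorter than the latency window still contribute their tail
    if (length(keep) == 0) keep <- length(a:b)
    eligible[a:b][keep] <- TRUE
  }
  eligible
}

# per-sample detected-fixation centroid (NA outside fixations)
.detected_centroid_per_sample <- function(detected, n, labels) {
  cx <- rep(NA_real_, n)
  cy <- rep(NA_real_, n)
  fx <- detected[detected$label %in% labels, , drop = FALSE]
  for (k in seq_len(nrow(fx))) {
    span <- fx$start_index[k]:fx$end_index[k]
    cx[span] <- fx$centroid_x[k]
    cy[span] <- fx$centroid_y[k]
  }
  list(cx = cx, cy = cy)
}

#' FQlS: fixation quantitative score
#'
#' Mean Euclidean distance, in degrees, between the detected fixation
#' centroid and the stimulus fixation position over all samples where both
#' are defined (stimulus fixation outside the latency window and a detected
#' fixation covering that time). 0 means the detector reproduces the
#' stimulus positions exactly; lower is better.
#'
#' @inheritParams fqns
#' @return Mean distance in degrees (>= 0).
#' @export
fqls <- function(detected, stim, latency_ms = 200,
                 labels = c("fixation", "stare")) {
  n <- nrow(stim)
  eligible <- .stim_fix_eligible(stim, latency_ms)
  det <- .detected_centroid_per_sample(detected, n, labels)
  use <- eligible & !is.na(det$cx)
  if (!any(use)) stop("no matched fixation samples")
  mean(sqrt((det$cx[use] - stim$x[use])^2 + (det$cy[use] - stim$y[use])^2))
}

#' Smooth-pursuit position and velocity scores
#'
#' Two percentages over the stimulus pursuit samples, following the
#' qualitative-score construction: a pursuit sample counts for the position
#' score when the detector labels it smooth pursuit and the gaze position is
#' within `pos_tol` degrees of the target, and for the velocity score when
#' the detector labels it smooth pursuit and the gaze speed is within
#' `vel_tol` deg/s of the target speed. A perfect unit-gain pursuit detector
#' scores 100 on both; a detector that never reports pursuit scores 0.
#' (These are the scores referred to elsewhere as PQnS/PQlS_P and PQlS_V;
#' the neutral names are used here.)
#'
#' @param detected A `gaze_events` data.frame.
#' @param rec The `gaze_recording` that was parsed (degrees).
#' @param stim The aligned `stimulus_signal`.
#' @param pos_tol Position tolerance in degrees.
#' @param vel_tol Velocity tolerance in deg/s.
#' @return List with `position` and `velocity`, both in `[0, 100]`.
#' @export
pursuit_scores <- function(detected, rec, stim, pos_tol = 4, vel_tol = 10) {
  n <- nrow(stim)
  is_sp <- stim$type == "pursuit"
  if (!any(is_sp)) stop("stimulus contains no pursuit samples")
  pred <- labels_from_segments(detected, n)
  det_sp <- pred == "smooth_pursuit"
  gaze_v <- sample_velocities(rec)
  stim_speed <- sqrt(stim$vx^2 + stim$vy^2)
  pos_ok <- det_sp & is_sp &
    sqrt((rec$samples$x - stim$x)^2 + (rec$samples$y - stim$y)^2) <= pos_tol
  vel_ok <- det_sp & is_sp & abs(gaze_v - stim_speed) <= vel_tol
  list(position = 100 * sum(pos_ok) / sum(is_sp),
       velocity = 100 * sum(vel_ok) / sum(is_sp))
}

#' Range-coefficient parameter sweep
#'
#' Evaluates a detector over a family of thresholds indexed by an integer
#' range coefficient. At range coefficient rc the swept parameter takes the
#' value `C + rc * Vi * T`, where `C` is the initial value, `Vi` the
#' per-step increment, and `T` a base scale factor; with `C = 0` and
#' `Vi * T` equal to the base threshold, rc = 1 reproduces that base
#' threshold. `Vi = 0` gives a constant threshold across the sweep.
#' Non-positive thresholds are skipped with a warning.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param stim The aligned `stimulus_signal` used for scoring.
#' @param algo Detector name (see [detect_events()]).
#' @param param Name of the swept parameter (e.g. `"v_T"`, `"D_T"`,
#'   `"dur_T"`).
#' @param T_base,Vi,C Sweep rule constants.
#' @param rc_values Integer range coefficients to evaluate.
#' @param score Scoring function: `"fqns"`, `"fqls"`,
#'   `"pursuit_position"`, or `"pursuit_velocity"`.
#' @param fixed Named list of the detector's other parameters (defaults from
#'   [recommended_params()]).
#' @return Data.frame of class `rc_sweep` with columns `rc`, `threshold`,
#'   `score`.
#' @export
rc_sweep <- function(rec, stim, algo, param, T_base = 1, Vi = 1, C = 0,
                     rc_values = 1:10,
                     score = c("fqns", "fqls", "pursuit_position",
                               "pursuit_velocity"),
                     fixed = list()) {
  score <- match.arg(score)
  rows <- list()
  for (r in rc_values) {
    th <- C + r * Vi * T_base
    if (th <= 0) {
      warning("skipping rc = ", r, ": non-positive threshold")
      next
    }
    params <- utils::modifyList(fixed, stats::setNames(list(th), param))
    ev <- detect_events(rec, algo, params)
    s <- switch(score,
      fqns = fqns(ev, stim),
      fqls = fqls(ev, stim),
      pursuit_position = pursuit_scores(ev, rec, stim)$position,
      pursuit_velocity = pursuit_scores(ev, rec, stim)$velocity
    )
    rows[[length(rows) + 1]] <- data.frame(rc = r, threshold = th, score = s)
  }
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(rc = integer(0), threshold = numeric(0), score = numeric(0))
  }
  class(out) <- c("rc_sweep", "data.frame")
  out
}

#' Per-class sample-level F1
#'
#' Precision, recall and F1 per class over aligned per-sample label vectors.
#' Supports the classical alphabet (fixation / saccade / smooth_pursuit) and
#' the behavioral one (stare / move). Classes absent from the truth get `NA`
#' scores and are reported as missing.
#'
#' @param predicted,truth Character vectors of equal length.
#' @param classes Classes to score (default: union of both vectors).
#' @return Data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
event_f1 <- function(predicted, truth, classes = NULL) {
  stopifnot(length(predicted) == length(truth))
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    support <- sum(truth == cl)
    if (support == 0) {
      return(data.frame(class = cl, precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, support = 0L))
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = support)
  })
  do.call(rbind, rows)
}

#' Read a Lund2013-style annotated sample export
#'
#' Adapter for plain-text exports of the Lund2013 annotated eye-movement
#' dataset: one sample per line with columns `t` (ms), `x`, `y` (degrees)
#' and an integer event code (1 fixation, 2 saccade, 3 PSO, 4 smooth
#' pursuit, 5 blink, 6 undefined). Only activated when the user supplies
#' downloaded/exported files; the package ships no Lund2013 data.
#'
#' @param path CSV file with header `t,x,y,label`.
#' @param geometry A [screen_geometry()] for the recording container.
#' @param nominal_rate Sampling rate of the export (500 Hz for Lund2013).
#' @return List with `recording` (a `gaze_recording` in degrees) and
#'   `truth` (character labels per sample).
#' @export
read_lund2013_csv <- function(path, geometry = default_geometry(),
                              nominal_rate = 500) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "label")
  if (!all(need %in% names(df))) {
    stop("expected columns t, x, y, label")
  }
  code_map <- c("fixation", "saccade", "pso", "smooth_pursuit", "blink",
                "undefined")
  bad <- !df$label %in% seq_along(code_map)
  if (any(bad)) stop("unknown label code at line ", which(bad)[1])
  rec <- gaze_recording(df[, c("t", "x", "y")], geometry, "degrees",
                        nominal_rate)
  list(recording = rec, truth = code_map[df$label])
}
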