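#' Build event segments from per-sample labels
#'
#' Collapses maximal runs of identical per-sample labels into contiguous
#' segments. Each segment records its inclusive start/end sample indices, the
#' centroid (mean position of member samples, in the recording's unit), and
#' its duration `t[end] - t[start]` in milliseconds. The segments partition
#' the sample index range.
#'
#' @param rec A `gaze_recording`.
#' @param labels Character vector, one label per sample.
#' @return A data.frame of class `gaze_events` with columns `label`,
#'   `start_index`, `end_index`, `start_ms`, `end_ms`, `centroid_x`,
#'   `centroid_y`, `duration_ms`, `n_samples`.
#' @export
segments_from_labels <- function(rec, labels) {
  n <- nrow(rec$samples)
  stopifnot(length(labels) == n)
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1
  ev <- data.frame(
    label = r$values,
    start_index = start,
    end_index = end,
    stringsAsFactors = FALSE
  )
  ev$start_ms <- rec$samples$t[ev$start_index]
  ev$end_ms <- rec$samples$t[ev$end_index]
  ev$centroid_x <- mapply(function(a, b) mean(rec$samples$x[a:b]),
                          ev$start_index, ev$end_index)
  ev$centroid_y <- mapply(function(a, b) mean(rec$samples$y[a:b]),
                          ev$start_index, ev$end_index)
  ev$duration_ms <- ev$end_ms - ev$start_ms
  ev$n_samples <- ev$end_index - ev$start_index + 1
  class(ev) <- c("gaze_events", "data.frame")
  ev
}

#' Expand event segments back to per-sample labels
#'
#' @param events A `gaze_events` data.frame that partitions `1..n`.
#' @param n Total number of samples.
#' @return Character vector of length `n`.
#' @export
labels_from_segments <- function(events, n) {
  out <- rep(NA_character_, n)
  for (k in seq_len(nrow(events))) {
    out[events$start_index[k]:events$end_index[k]] <- events$label[k]
  }
  if (anyNA(out)) stop("events do not cover every sample")
  out
}

#' Merge nearby fixation segments
#'
#' Post-hoc utility that joins consecutive fixation-like segments (labels
#' `fixation` or `stare`) whose centroids are within `max_dist_deg` and whose
#' temporal gap is at most `max_gap_ms`, absorbing the short in-between
#' segments. Useful for counting distinct dwell regions when a detector
#' fragments one physical fixation into several segments (the blip problem).
#' Off by default in all detectors.
#'
#' @param events A `gaze_events` data.frame.
#' @param rec The `gaze_recording` the events came from (for recomputing
#'   centroids of merged spans).
#' @param max_dist_deg Maximum centroid distance to merge across (degrees).
#' @param max_gap_ms Maximum temporal gap between merged segments (ms).
#' @param labels Labels treated as fixation-like.
#' @return A `gaze_events` data.frame of the merged fixation-like regions
#'   only (non-fixation segments are dropped).
#' @export
merge_fixations <- function(events, rec, max_dist_deg = 2, max_gap_ms = 500,
                            labels = c("fixation", "stare")) {
  fx <- events[events$label %in% labels, , drop = FALSE]
  if (nrow(fx) == 0) return(fx)
  groups <- integer(nrow(fx))
  groups[1] <- 1
  if (nrow(fx) > 1) {
    for (k in 2:nrow(fx)) {
      prev <- which(groups == groups[k - 1])
      # compare against the running centroid of the open group
      idx <- unlist(mapply(seq, fx$start_index[prev], fx$end_index[prev]))
      cx <- mean(rec$samples$x[idx]); cy <- mean(rec$samples$y[idx])
      d <- sqrt((fx$centroid_x[k] - cx)^2 + (fx$centroid_y[k] - cy)^2)
      gap <- fx$start_ms[k] - fx$end_ms[k - 1]
      groups[k] <- if (d <= max_dist_deg && gap <= max_gap_ms)
        groups[k - 1] else groups[k - 1] + 1
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(fx)), groups), function(ix) {
    member <- unlist(mapply(seq, fx$start_index[ix], fx$end_index[ix]))
    data.frame(
      label = fx$label[ix[1]],
      start_index = min(fx$start_index[ix]),
      end_index = max(fx$end_index[ix]),
      start_ms = min(fx$start_ms[ix]),
      end_ms = max(fx$end_ms[ix]),
      centroid_x = mean(rec$samples$x[member]),
      centroid_y = mean(rec$samples$y[member]),
      duration_ms = max(fx$end_ms[ix]) - min(fx$start_ms[ix]),
      n_samples = length(member),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("gaze_events", "data.frame")
  out
}

#' Write detected events to CSV
#'
#' Columns: `label,start_index,end_index,start_ms,end_ms,centroid_x_deg,
#' centroid_y_deg,duration_ms`.
#'
#' @param events A `gaze_events` data.frame.
#' @param path Output path.
#' @export
write_events_csv <- function(events, path) {
  out <- data.frame(
    label = events$label,
    start_index = events$start_index,
    end_index = events$end_index,
    start_ms = events$start_ms,
    end_ms = events$end_ms,
    centroid_x_deg = events$centroid_x,
    centroid_y_deg = events$centroid_y,
    duration_ms = events$duration_ms
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an events CSV written by [write_events_csv()]
#'
#' Also accepts label output of external event classifiers in the same
#' column layout.
#'
#' @param path CSV path.
#' @return A `gaze_events` data.frame.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "centroid_x_deg"] <- "centroid_x"
  names(df)[names(df) == "centroid_y_deg"] <- "centroid_y"
  df$n_samples <- df$end_index - df$start_index + 1
  class(df) <- c("gaze_events", "data.frame")
  df
}
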