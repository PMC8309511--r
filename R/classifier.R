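#' Convolutional architectures for stare/move classification
#'
#' Three small feed-forward architectures operating on square grayscale
#' behavior windows:
#'
#' * `cnn3` — three 3x3 convolutions (widths 32/64/128) with ReLU and a
#'   single 4x4 max-pool after the first convolution, followed by two fully
#'   connected layers.
#' * `alexnet_like` — a scaled-down AlexNet: five 3x3 convolutions (widths
#'   16/32/48/48/32) with ReLU and three 2x2 max-pools, followed by three
#'   fully connected layers. The largest model of the three.
#' * `lenet_like` — a LeNet-5-style net: two 5x5 convolutions (widths 6/16),
#'   two 2x2 max-pools, and three fully connected layers (120/84/2), all with
#'   sigmoid activations.
#'
#' Kernel sizes, channel widths and the optimizer settings are fixed design
#' choices of this package; only layer counts and activations are inherent
#' to the architecture names.
#'
#' @param name Architecture name.
#' @param input_px Side length of the input raster in pixels (must be
#'   divisible by 8).
#' @return A list of class `cnn_architecture` with `name`, `input_px`,
#'   `layers`, and `sigmoid_net`.
#' @export
cnn_architecture <- function(name = c("cnn3", "alexnet_like", "lenet_like"),
                             input_px = 64) {
  name <- match.arg(name)
  conv <- function(i, o, k) list(type = "conv", in_c = i, out_c = o, k = k)
  pool <- function(k) list(type = "pool", k = k)
  fc <- function(i, o) list(type = "fc", in_n = i, out_n = o)
  act <- function(a) list(type = a)
  p <- input_px
  layers <- switch(name,
    cnn3 = {
      q <- p / 4
      list(conv(1, 32, 3), act("relu"), pool(4),
           conv(32, 64, 3), act("relu"),
           conv(64, 128, 3), act("relu"),
           fc(128 * q * q, 128), act("relu"),
           fc(128, 2))
    },
    alexnet_like = {
      q <- p / 8
      list(conv(1, 16, 3), act("relu"), pool(2),
           conv(16, 32, 3), act("relu"), pool(2),
           conv(32, 48, 3), act("relu"),
           conv(48, 48, 3), act("relu"),
           conv(48, 32, 3), act("relu"), pool(2),
           fc(32 * q * q, 256), act("relu"),
           fc(256, 64), act("relu"),
           fc(64, 2))
    },
    lenet_like = {
      q <- p / 4
      list(conv(1, 6, 5), act("sigmoid"), pool(2),
           conv(6, 16, 5), act("sigmoid"), pool(2),
           fc(16 * q * q, 120), act("sigmoid"),
           fc(120, 84), act("sigmoid"),
           fc(84, 2))
    }
  )
  structure(
    list(name = name, input_px = input_px, layers = layers,
         sigmoid_net = (name == "lenet_like")),
    class = "cnn_architecture"
  )
}

#' Train a stare/move window classifier
#'
#' Trains one of the [cnn_architecture()] networks on a balanced dataset
#' from [build_dataset()] using Adam (learning rate 1e-3) on softmax
#' cross-entropy, mini-batches of 64. Training is deterministic given
#' `seed` on a fixed machine: weight initialization and epoch shuffling use
#' a private generator seeded from it.
#'
#' @param arch A [cnn_architecture()] or an architecture name.
#' @param dataset A dataset from [build_dataset()] (`train`/`val` with `x`
#'   rows in `[0, 1]` and factor `y` with levels `move`, `stare`).
#' @param epochs Number of training epochs.
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size.
#' @return A list of class `gaze_cnn` with `arch`, `weights`, `history`
#'   (per-epoch train/validation accuracy and loss), `seed`, and `classes`.
#' @export
train_behavior_classifier <- function(arch, dataset, epochs = 10, seed = 1L,
                                      lr = 1e-3, batch = 64) {
  if (is.character(arch)) {
    arch <- cnn_architecture(arch, input_px = dataset$spec$resolution_px)
  }
  if (nrow(dataset$train$x) == 0) stop("empty training set")
  ytr <- as.integer(dataset$train$y) - 1L  # move = 0, stare = 1
  yval <- as.integer(dataset$val$y) - 1L
  fit <- cnn_train_cpp(arch$layers, dataset$train$x, ytr,
                       dataset$val$x, yval, arch$input_px,
                       as.integer(epochs), as.integer(batch), lr,
                       as.integer(seed), arch$sigmoid_net)
  structure(
    list(arch = arch, weights = fit$weights, history = fit$history,
         seed = as.integer(seed), classes = c("move", "stare")),
    class = "gaze_cnn"
  )
}

#' @export
print.gaze_cnn <- function(x, ...) {
  h <- x$history
  cat(sprintf("gaze_cnn: %s, %d epochs, final val acc %.3f, val loss %.4f\n",
              x$arch$name, nrow(h), h$val_acc[nrow(h)], h$val_loss[nrow(h)]))
  invisible(x)
}

#' Predict stare/move probabilities for raster windows
#'
#' @param model A `gaze_cnn` model.
#' @param x Matrix with one flattened raster per row (values in `[0, 1]`).
#' @return Matrix `n x 2` of class probabilities, columns `move`, `stare`.
#' @export
predict_windows <- function(model, x) {
  p <- cnn_predict_cpp(model$arch$layers, model$weights, x,
                       model$arch$input_px)
  colnames(p) <- model$classes
  p
}

#' Save / load a trained classifier checkpoint
#'
#' The checkpoint is a single RDS file embedding the architecture, weights,
#' training history and seed.
#'
#' @param model A `gaze_cnn`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gaze_cnn")) stop("not a gaze_cnn checkpoint")
  model
}

#' Classification accuracy from a confusion table
#'
#' `(TP + TN) / (TP + FP + FN + TN)`, with `stare` as the positive class.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("empty confusion table")
  (tp + tn) / total
}

#' Cross-entropy between a true and a predicted distribution
#'
#' `H(P, Q) = -sum(P * log(Q))`, the training loss of the classifiers.
#' Predicted probabilities are clipped below at `eps` so that a zero
#' prediction under positive truth yields a large finite value rather than
#' infinity.
#'
#' @param p True distribution (non-negative, sums to 1).
#' @param q Predicted distribution (same length).
#' @param eps Clipping floor for `q`.
#' @return Non-negative scalar (natural log).
#' @export
cross_entropy <- function(p, q, eps = 1e-12) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1")
  q <- pmax(q, eps)
  -sum(p * log(q))
}

#' Segment a recording into stare/move events with a trained classifier
#'
#' Extracts one behavior window per sample, predicts stare/move for each,
#' merges prediction runs shorter than `min_run` into the neighboring
#' majority label (ties resolved toward `stare`), and collapses maximal runs
#' into segments partitioning the recording. `min_run = 1` leaves the raw
#' per-sample predictions untouched.
#'
#' @param model A `gaze_cnn`, or a function mapping a raster matrix (one row
#'   per window) to a character vector of labels (useful for truth-replay
#'   testing).
#' @param rec A `gaze_recording` in degrees.
#' @param spec The [window_spec()] used at training time.
#' @param min_run Minimum run length in samples.
#' @return A `gaze_events` data.frame with labels `stare` / `move`.
#' @export
classify_recording <- function(model, rec, spec = window_spec(),
                               min_run = 2) {
  n <- nrow(rec$samples)
  x <- matrix(0, nrow = n, ncol = spec$resolution_px^2)
  for (i in seq_len(n)) {
    x[i, ] <- as.vector(extract_window(rec, i, spec)$raster)
  }
  labels <- if (inherits(model, "gaze_cnn")) {
    p <- predict_windows(model, x)
    model$classes[max.col(p, ties.method = "first")]
  } else {
    model(x)
  }
  labels <- merge_short_runs(labels, min_run)
  segments_from_labels(rec, labels)
}

#' Merge short label runs into their neighborhood majority
#'
#' Repeatedly relabels maximal runs shorter than `min_run` to the majority
#' label of their adjacent runs (sample-weighted; ties toward `stare`).
#'
#' @param labels Character vector of per-sample labels.
#' @param min_run Minimum run length; 1 is the identity.
#' @return Character vector of the same length.
#' @export
merge_short_runs <- function(labels, min_run = 2) {
  if (min_run <= 1) return(labels)
  repeat {
    r <- rle(labels)
    k <- length(r$values)
    if (k <= 1) return(labels)
    short <- which(r$lengths < min_run)
    if (length(short) == 0) return(labels)
    q <- short[1]
    votes <- c(prev = if (q > 1) r$lengths[q - 1] else 0,
               nxt = if (q < k) r$lengths[q + 1] else 0)
    cand <- c(if (q > 1) r$values[q - 1] else NA,
              if (q < k) r$values[q + 1] else NA)
    if (all(is.na(cand))) return(labels)
    if (!is.na(cand[1]) && !is.na(cand[2]) && cand[1] == cand[2]) {
      new <- cand[1]
    } else if (!is.na(cand[1]) && (is.na(cand[2]) || votes[1] > votes[2])) {
      new <- cand[1]
    } else if (!is.na(cand[2]) && (is.na(cand[1]) || votes[2] > votes[1])) {
      new <- cand[2]
    } else {
      # equal-weight disagreement: prefer stare
      new <- if ("stare" %in% cand) "stare" else cand[1]
    }
    r$values[q] <- new
    labels <- inverse.rle(r)
  }
}
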