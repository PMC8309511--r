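# CNN training/prediction mechanics, metrics, and window-to-segment logic

make_fake_dataset <- function(xtr, ytr, xv, yv, res) {
  list(train = list(x = xtr, y = factor(ytr, levels = c("move", "stare"))),
       val = list(x = xv, y = factor(yv, levels = c("move", "stare"))),
       spec = list(resolution_px = res))
}

test_that("a separable black/white problem is solved within 5 epochs", {
  set.seed(1)
  n <- 80
  x <- matrix(stats::runif(n * 256, 0, 0.1), n)
  y <- rep(c("move", "stare"), each = n / 2)
  x[y == "stare", ] <- x[y == "stare", ] + 0.8
  sh <- sample(n)
  ds <- make_fake_dataset(x[sh[1:60], ], y[sh[1:60]],
                          x[sh[61:80], ], y[sh[61:80]], 16)
  m <- train_behavior_classifier("cnn3", ds, epochs = 5, seed = 2)
  expect_equal(max(m$history$val_acc), 1)
  p <- predict_windows(m, ds$val$x)
  expect_equal(colnames(p), c("move", "stare"))
  expect_true(all(abs(rowSums(p) - 1) < 1e-5))
})

test_that("randomly permuted labels stay at chance level", {
  set.seed(5)
  n <- 600
  x <- matrix(stats::runif(n * 256), n)
  y <- sample(rep(c("move", "stare"), n / 2))  # labels independent of x
  ds <- make_fake_dataset(x[1:200, ], y[1:200], x[201:n, ], y[201:n], 16)
  m <- train_behavior_classifier("cnn3", ds, epochs = 2, seed = 3)
  final <- m$history$val_acc[2]
  expect_gt(final, 0.45)
  expect_lt(final, 0.55)
})

test_that("training is reproducible at a fixed seed", {
  set.seed(2)
  x <- matrix(stats::runif(40 * 256), 40)
  y <- rep(c("move", "stare"), 20)
  ds <- make_fake_dataset(x[1:30, ], y[1:30], x[31:40, ], y[31:40], 16)
  m1 <- train_behavior_classifier("lenet_like", ds, epochs = 2, seed = 11)
  m2 <- train_behavior_classifier("lenet_like", ds, epochs = 2, seed = 11)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_behavior_classifier("lenet_like", ds, epochs = 2, seed = 12)
  expect_false(identical(m3$weights, m1$weights))
})

test_that("checkpoints round-trip through a single file", {
  set.seed(2)
  x <- matrix(stats::runif(20 * 256), 20)
  y <- rep(c("move", "stare"), 10)
  ds <- make_fake_dataset(x[1:10, ], y[1:10], x[11:20, ], y[11:20], 16)
  m <- train_behavior_classifier("cnn3", ds, epochs = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, m$weights)
  expect_equal(predict_windows(back, ds$val$x), predict_windows(m, ds$val$x))
})

test_that("accuracy follows (TP+TN)/total", {
  expect_equal(accuracy(50, 0, 0, 50), 1)
  expect_equal(accuracy(3, 1, 4, 2), 0.5)
  expect_equal(accuracy(0, 5, 7, 0), 0)
  expect_error(accuracy(0, 0, 0, 0), "empty")
  expect_error(accuracy(-1, 0, 0, 2), "non-negative")
})

test_that("cross-entropy matches closed forms and is linear over batches", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_true(is.finite(cross_entropy(c(1, 0), c(0, 1))))

  set.seed(6)
  qs <- lapply(1:10, function(i) { q <- stats::runif(3); q / sum(q) })
  ps <- lapply(1:10, function(i) {
    p <- c(0, 0, 0); p[sample(3, 1)] <- 1; p
  })
  per_item <- mapply(cross_entropy, ps, qs)
  batch_mean <- mean(per_item)
  expect_equal(mean(vapply(1:10, function(i) {
    cross_entropy(ps[[i]], qs[[i]])
  }, 1)), batch_mean)
  expect_error(cross_entropy(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("classify_recording replays truth boundaries through windows", {
  sim <- simulate_gaze(make_script("six_point_updown", stops = TRUE), 40,
                       oculomotor_params(seed = 8, dropout_rate = 0))
  rec <- sim$recording
  truth_beh <- behavior_labels(sim$truth)
  spec <- window_spec(32, 16, 2)
  # truth-replay "model": a function ignoring pixels, returning truth labels
  replay <- local({
    i <- 0
    function(x) truth_beh[seq_len(nrow(x))]
  })
  seg <- classify_recording(replay, rec, spec, min_run = 1)
  expect_identical(labels_from_segments(seg, nrow(rec$samples)), truth_beh)
  r <- rle(truth_beh)
  expect_equal(nrow(seg), length(r$values))

  # pursuit portions come out as stare, not move
  sp <- which(sim$truth == "smooth_pursuit")
  got <- labels_from_segments(seg, nrow(rec$samples))[sp]
  expect_true(all(got == "stare"))

  # a model that always says stare gives a single segment
  all_stare <- function(x) rep("stare", nrow(x))
  seg1 <- classify_recording(all_stare, rec, spec)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$label, "stare")
})

test_that("short-run merging is majority-driven with stare tie-break", {
  labs <- c("stare", "stare", "stare", "move", "stare", "stare")
  expect_equal(merge_short_runs(labs, 2), rep("stare", 6))
  labs2 <- c("move", "move", "stare", "move", "move")
  expect_equal(merge_short_runs(labs2, 2), rep("move", 5))
  # min_run = 1 is the identity
  labs3 <- c("stare", "move", "stare")
  expect_identical(merge_short_runs(labs3, 1), labs3)
  # equal-weight neighbors disagreeing: tie resolved toward stare
  labs4 <- c("stare", "stare", "move", "stare", "stare")
  expect_equal(merge_short_runs(labs4, 2), rep("stare", 5))
})
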