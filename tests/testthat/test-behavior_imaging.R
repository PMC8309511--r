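# sliding-window rasterization, labeling, and dataset construction

test_that("a history-free window is one full-opacity dot at the center", {
  rec <- tiny_rec(c(3, 3.1), c(-2, -2.05))
  spec <- window_spec(32, 64, history_n = 0)
  w <- extract_window(rec, 2, spec)
  center <- 64 / 2 + 1
  expect_equal(w$raster[center, center], 1)
  # dot radius 1: the center pixel plus its 4-neighborhood
  expect_equal(sum(w$raster > 0), 5)
  expect_true(all(w$raster %in% c(0, 1)))
})

test_that("past samples land at the affine-mapped pixels with faded opacity", {
  # anchor at origin; two past samples at +4 and +2 degrees x
  rec <- tiny_rec(c(4, 2, 0), c(0, 0, 0))
  spec <- window_spec(32, 64, history_n = 2, dot_radius_px = 0)
  w <- extract_window(rec, 3, spec)
  # independent affine map: col = floor((x - (cx - 16)) / 32 * 64) + 1
  col_of <- function(x) floor((x + 16) / 32 * 64) + 1
  row <- col_of(0)
  expect_equal(w$raster[row, col_of(0)], 1)          # age 0
  expect_equal(w$raster[row, col_of(2)], 2 / 3)      # age 1
  expect_equal(w$raster[row, col_of(4)], 1 / 3)      # age 2
  expect_equal(sum(w$raster > 0), 3)

  # opacity strictly decreasing with age under the default fade
  ages <- 0:8
  spec8 <- window_spec(32, 64, history_n = 8)
  ops <- vapply(ages, spec8$fade, 1)
  expect_true(all(diff(ops) < 0))
  expect_equal(ops[1], 1)
})

test_that("windows slide one per sample and are translation-equivariant", {
  sim <- simulate_gaze(make_script("six_point_zshape", stops = FALSE), 40,
                       oculomotor_params(seed = 9))
  rec <- sim$recording
  spec <- window_spec(32, 32, history_n = 4)
  ws <- extract_windows(rec, spec)
  expect_length(ws, nrow(rec$samples))
  expect_equal(vapply(ws, function(w) w$anchor_index, 1),
               seq_len(nrow(rec$samples)))

  shifted <- rec
  shifted$samples$x <- shifted$samples$x + 7
  shifted$samples$y <- shifted$samples$y - 3
  ws2 <- extract_windows(shifted, spec)
  for (i in c(1, 10, 40, length(ws))) {
    expect_identical(ws[[i]]$raster, ws2[[i]]$raster)
  }
})

test_that("fast saccades leave only the anchor dot inside the window", {
  # inter-sample displacement > extent/2 pushes all history outside
  rec <- tiny_rec(c(0, 40, 80, 120), c(0, 0, 0, 0))
  spec <- window_spec(32, 64, history_n = 3, dot_radius_px = 0)
  w <- extract_window(rec, 4, spec)
  expect_equal(sum(w$raster > 0), 1)
  center <- 64 / 2 + 1
  expect_equal(w$raster[center, center], 1)
})

test_that("behavior labels map events onto stare/move and drop the rest", {
  truth <- c("fixation", "saccade", "smooth_pursuit", "pso", "blink")
  expect_equal(behavior_labels(truth),
               c("stare", "move", "stare", "move", "unlabeled"))

  rec <- tiny_rec(rnorm(5), rnorm(5))
  ws <- extract_windows(rec, window_spec(32, 16, 1))
  labeled <- label_from_events(ws, truth)
  expect_equal(vapply(labeled, function(w) w$label, ""),
               c("stare", "move", "stare", "move", "unlabeled"))
  expect_error(label_from_events(ws, truth[1:3]), "missing truth")

  # alternating truth follows anchors
  alt <- rep(c("fixation", "saccade"), length.out = 5)
  labeled <- label_from_events(ws, alt)
  expect_equal(vapply(labeled, function(w) w$label, ""),
               rep(c("stare", "move"), length.out = 5))
})

test_that("dataset construction balances classes and is deterministic", {
  # saccade-rich search-like scripts so both classes are well populated
  sims <- lapply(1:2, function(s) {
    set.seed(s)
    wp <- data.frame(x = stats::runif(10, -12, 12),
                     y = stats::runif(10, -12, 12))
    simulate_gaze(make_script("custom", waypoints = wp, stay_s = 0.25,
                              speed_deg_s = 150),
                  40, oculomotor_params(seed = s, dropout_rate = 0))
  })
  spec <- window_spec(32, 16, 4)
  ds <- build_dataset(sims, spec, n_per_class = 10, split = 0.5, seed = 3)
  expect_equal(as.vector(table(ds$train$y)), c(5, 5))
  expect_equal(as.vector(table(ds$val$y)), c(5, 5))
  expect_equal(nrow(ds$train$x), 10)
  expect_equal(ncol(ds$train$x), 16^2)

  ds2 <- build_dataset(sims, spec, n_per_class = 10, split = 0.5, seed = 3)
  expect_identical(ds$train$manifest, ds2$train$manifest)
  expect_identical(ds$train$x, ds2$train$x)

  # class pool sizes equal the truth-label counts at anchors
  beh <- unlist(lapply(sims, function(s) behavior_labels(s$truth)))
  expect_error(
    build_dataset(sims, spec, n_per_class = sum(beh == "move") + 1,
                  split = 0.5, seed = 1),
    "insufficient move")

  # PNG serialization writes one file per manifest row
  dir <- withr::local_tempdir()
  build_dataset(sims, spec, n_per_class = 6, split = 0.5, seed = 3,
                out_dir = dir)
  m <- utils::read.csv(file.path(dir, "manifest_train.csv"))
  expect_true(all(file.exists(file.path(dir, m$file))))
})

test_that("saccade windows are sparser than pursuit windows", {
  # mean nearest-neighbor distance between rendered dots, >= 100 windows
  sims <- lapply(1:3, function(s) {
    simulate_gaze(make_script("six_point_updown", stops = FALSE), 40,
                  oculomotor_params(seed = s + 20, dropout_rate = 0))
  })
  spec <- window_spec(32, 64, 8, dot_radius_px = 0)
  nn_mean <- function(w) {
    pts <- which(w$raster > 0, arr.ind = TRUE)
    if (nrow(pts) < 2) return(NA_real_)
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  vals <- list(saccade = numeric(0), smooth_pursuit = numeric(0))
  for (sim in sims) {
    for (lab in names(vals)) {
      idx <- which(sim$truth == lab)
      ws <- extract_windows(sim$recording, spec, idx)
      vals[[lab]] <- c(vals[[lab]],
                       stats::na.omit(vapply(ws, nn_mean, 1)))
    }
  }
  expect_gte(length(vals$smooth_pursuit) + length(vals$saccade), 100)
  expect_gt(mean(vals$saccade), mean(vals$smooth_pursuit))
})
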