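# the four gaze parsers against hand examples and brute-force oracles

test_that("I-VT separates a step displacement and collapses runs", {
  rec <- tiny_rec(rep(0, 30), rep(0, 30))
  ev <- ivt(rec, 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "fixation")
  expect_equal(ev$start_index, 1)
  expect_equal(ev$end_index, 30)

  # 12 samples, 5-degree jump entering sample 7: fixation / saccade / fixation
  x <- c(rep(0, 6), rep(5, 6))
  rec <- tiny_rec(x, rep(0, 12))
  ev <- ivt(rec, 50)
  expect_equal(ev$label, c("fixation", "saccade", "fixation"))
  expect_equal(ev$start_index, c(1, 7, 8))
  expect_equal(ev$end_index, c(6, 7, 12))
  expect_equal(ev$centroid_x, c(0, 5, 5))

  expect_error(ivt(tiny_rec(1, 1), 10), "2 samples")
  expect_error(ivt(rec, -1), "positive")
})

test_that("I-VT matches its per-sample oracle and is monotone in v_T", {
  rec <- random_trace(120, seed = 42)
  v_grid <- seq(2, 400, length.out = 25)
  prev <- -1
  for (v_T in v_grid) {
    ev <- ivt(rec, v_T)
    expect_identical(labels_from_segments(ev, 120),
                     oracle_ivt_labels(rec, v_T))
    n_fix <- sum(ev$n_samples[ev$label == "fixation"])
    expect_gte(n_fix, prev)
    prev <- n_fix
  }
})

test_that("I-DT emits dispersion- and duration-bounded fixations", {
  # all samples at one point, long enough
  rec <- tiny_rec(rep(1, 20), rep(2, 20))
  ev <- idt(rec, 0.5, 100)
  expect_equal(ev$label, "fixation")
  expect_equal(ev$n_samples, 20)

  # two tight clusters separated by a jump
  set.seed(7)
  x <- c(rnorm(8, 0, 0.05), rnorm(7, 10, 0.05))
  rec <- tiny_rec(x, rnorm(15, 0, 0.05))
  ev <- idt(rec, 1, 100)
  expect_identical(labels_from_segments(ev, 15),
                   oracle_idt_labels(rec, 1, 100))
  expect_equal(sum(ev$label == "fixation"), 2)

  # threshold far below the noise level finds nothing
  set.seed(8)
  noisy <- tiny_rec(rnorm(40, 0, 1), rnorm(40, 0, 1))
  ev <- idt(noisy, 1e-4, 100)
  expect_equal(sum(ev$label == "fixation"), 0)

  # every emitted fixation satisfies both bounds
  rec <- random_trace(150, seed = 9)
  ev <- idt(rec, 2, 80)
  fx <- ev[ev$label == "fixation", ]
  for (k in seq_len(nrow(fx))) {
    span <- fx$start_index[k]:fx$end_index[k]
    disp <- diff(range(rec$samples$x[span])) +
      diff(range(rec$samples$y[span]))
    expect_lte(disp, 2)
    expect_gte(fx$duration_ms[k], 80)
  }
})

test_that("IQR epsilon equals the quartile of centroid distances", {
  # four points at distances 1,2,3,4 from their centroid (origin):
  # Q3 by linear interpolation = 3.25
  rec <- tiny_rec(c(1, 0, -3, 0), c(0, 2, 0, -4))
  cx <- mean(rec$samples$x); cy <- mean(rec$samples$y)
  d <- sort(sqrt((rec$samples$x - cx)^2 + (rec$samples$y - cy)^2))
  h <- 1 + 3 * 0.75                     # type-7 interpolation index
  expected <- d[3] + (h - 3) * (d[4] - d[3])
  expect_equal(dbscan_eps_iqr(rec), expected)

  same <- tiny_rec(rep(2, 5), rep(3, 5))
  expect_equal(dbscan_eps_iqr(same), 0)
  expect_error(dbscan_iqr(same, 3), "eps")

  shifted <- tiny_rec(rec$samples$x + 100, rec$samples$y - 40,
                      t = rec$samples$t)
  expect_equal(dbscan_eps_iqr(shifted), dbscan_eps_iqr(rec))
})

test_that("DBSCAN clustering matches the quadratic reference", {
  # one dense cluster
  set.seed(3)
  rec <- tiny_rec(rnorm(12, 0, 0.1), rnorm(12, 0, 0.1))
  ev <- dbscan_iqr(rec, min_points = 4, eps = 1)
  expect_equal(unique(ev$label), "fixation")

  # two well-separated clusters: assignment identical to the oracle
  set.seed(4)
  rec <- tiny_rec(c(rnorm(15, 0, 0.2), rnorm(15, 12, 0.2)),
                  rnorm(30, 0, 0.2))
  eps <- dbscan_eps_iqr(rec)
  ev <- dbscan_iqr(rec, min_points = 4, time_weight = 1)
  expect_identical(attr(ev, "assignment"),
                   oracle_dbscan_assign(rec, 4, 1, eps))
  # at a foveal-scale radius the two spatial clusters separate
  ev1 <- dbscan_iqr(rec, min_points = 4, time_weight = 1, eps = 1)
  expect_identical(attr(ev1, "assignment"),
                   oracle_dbscan_assign(rec, 4, 1, 1))
  expect_equal(length(unique(stats::na.omit(ev1$cluster))), 2)

  # min_points changes the fixation count substantially on the same trace
  sim <- simulate_gaze(make_script("four_target"), 40,
                       oculomotor_params(seed = 6))
  n_small <- sum(dbscan_iqr(sim$recording, 3, 5, eps = 1.5)$label ==
                   "fixation")
  n_large <- sum(dbscan_iqr(sim$recording, 40, 5, eps = 1.5)$label ==
                   "fixation")
  expect_false(n_small == n_large)
})

test_that("I-VDT stages velocity and dispersion into three event types", {
  rec <- tiny_rec(rep(0, 30), rep(0, 30))
  ev <- ivdt(rec, 50, 1.5)
  expect_equal(ev$label, "fixation")

  # hold -> 20 deg/s ramp -> hold: fixation, pursuit, fixation in order
  rec <- hold_ramp_hold()
  ev <- ivdt(rec, 50, 1.5)
  expect_identical(labels_from_segments(ev, nrow(rec$samples)),
                   oracle_ivdt_labels(rec, 50, 1.5))
  kinds <- rle(ev$label)$values
  expect_equal(kinds, c("fixation", "smooth_pursuit", "fixation"))

  # a dispersion threshold below the fixational noise scale fragments the
  # parse into many alternating fixations and pursuits
  sim <- simulate_gaze(make_script("four_target"), 40,
                       oculomotor_params(seed = 3))
  frag <- ivdt(sim$recording, 50, 0.2)
  coarse <- ivdt(sim$recording, 50, 1.5)
  expect_gt(sum(frag$label %in% c("fixation", "smooth_pursuit")),
            sum(coarse$label %in% c("fixation", "smooth_pursuit")))
})

test_that("detect_events dispatches with recommended defaults", {
  sim <- simulate_gaze(make_script("four_target"), 40,
                       oculomotor_params(seed = 1))
  for (algo in c("ivt", "idt", "dbscan", "ivdt")) {
    ev <- detect_events(sim$recording, algo)
    n <- nrow(sim$recording$samples)
    expect_equal(ev$start_index[1], 1)
    expect_equal(ev$end_index[nrow(ev)], n)
    expect_true(all(ev$start_index[-1] == ev$end_index[-nrow(ev)] + 1))
  }
})
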