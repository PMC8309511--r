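# detector evaluation scores

# build a stimulus signal and the events of an idealized detector that
# reproduces it exactly (truth replay)
replay_setup <- function(seed = 1, rate = 40) {
  sc <- make_script("four_target")
  sim <- simulate_gaze(sc, rate, oculomotor_params(seed = seed,
                                                   dropout_rate = 0))
  stim <- sim$stimulus
  # replay detector: stimulus-type runs as segments with stimulus centroids
  stim_rec <- gaze_recording(
    data.frame(t = stim$t, x = stim$x, y = stim$y),
    test_geometry(), "degrees", rate)
  map <- c(fixation = "fixation", pursuit = "smooth_pursuit",
           transition = "saccade")
  ev <- segments_from_labels(stim_rec, unname(map[stim$type]))
  list(sim = sim, stim = stim, events = ev, rec = stim_rec)
}

test_that("truth replay scores perfectly on FQnS and FQlS", {
  rs <- replay_setup()
  expect_equal(fqns(rs$events, rs$stim), 100)
  expect_equal(fqls(rs$events, rs$stim), 0)
})

test_that("FQnS counts matched eligible samples proportionally", {
  # 2 s fixation at origin, sampled at 40 Hz
  n <- 80
  stim <- data.frame(t = (0:(n - 1)) * 25, type = "fixation",
                     x = 0, y = 0, vx = 0, vy = 0)
  class(stim) <- c("stimulus_signal", "data.frame")
  rec <- tiny_rec(rep(0, n), rep(0, n))
  # eligible samples start after the 200 ms latency window: t >= 200
  eligible <- sum(stim$t >= 200)
  # detector that fixates only the first half of the recording
  labels <- c(rep("fixation", n / 2), rep("saccade", n / 2))
  ev <- segments_from_labels(rec, labels)
  covered <- sum(stim$t >= 200 & seq_len(n) <= n / 2)
  expect_equal(fqns(ev, stim), 100 * covered / eligible)

  # far-away centroid never matches
  rec_far <- tiny_rec(rep(30, n), rep(0, n))
  ev_far <- segments_from_labels(rec_far, rep("fixation", n))
  expect_equal(fqns(ev_far, stim), 0)

  stim_sp <- stim
  stim_sp$type <- "pursuit"
  expect_error(fqns(ev, stim_sp), "no fixation")
})

test_that("FQlS equals a constant offset and is translation-invariant", {
  n <- 60
  stim <- data.frame(t = (0:(n - 1)) * 25, type = "fixation",
                     x = 3, y = -2, vx = 0, vy = 0)
  class(stim) <- c("stimulus_signal", "data.frame")
  rec <- tiny_rec(rep(4, n), rep(-2, n))  # centroid 1 degree off
  ev <- segments_from_labels(rec, rep("fixation", n))
  expect_equal(fqls(ev, stim), 1)

  stim2 <- stim; stim2$x <- stim2$x + 7; stim2$y <- stim2$y + 5
  rec2 <- tiny_rec(rec$samples$x + 7, rec$samples$y + 5)
  ev2 <- segments_from_labels(rec2, rep("fixation", n))
  expect_equal(fqls(ev2, stim2), fqls(ev, stim))
})

test_that("pursuit scores reward unit-gain tracking and punish misses", {
  rate <- 40
  sc <- make_script("six_point_zshape", stops = FALSE)
  stim <- script_to_stimulus_signal(sc, rate)
  # perfect gain-1 pursuit: gaze equals the target everywhere
  rec <- gaze_recording(data.frame(t = stim$t, x = stim$x, y = stim$y),
                        test_geometry(), "degrees", rate)
  ev <- segments_from_labels(rec, rep("smooth_pursuit", nrow(stim)))
  s <- pursuit_scores(ev, rec, stim)
  expect_equal(s$position, 100)
  expect_gt(s$velocity, 90)   # backward difference blurs direction changes

  ev0 <- segments_from_labels(rec, rep("fixation", nrow(stim)))
  s0 <- pursuit_scores(ev0, rec, stim)
  expect_equal(s0$position, 0)
  expect_equal(s0$velocity, 0)

  stay <- script_to_stimulus_signal(make_script("four_target",
                                                transitions_s = 0.1), rate)
  expect_error(pursuit_scores(ev, rec, stay[stay$type == "fixation", ]),
               "no pursuit")
})

test_that("range-coefficient sweeps unroll to manual detector runs", {
  rs <- replay_setup(seed = 4)
  rec <- rs$sim$recording
  stim <- rs$stim
  sweep <- rc_sweep(rec, stim, "ivt", "v_T", T_base = 10, Vi = 1, C = 0,
                    rc_values = 1:6, score = "fqns")
  expect_equal(sweep$threshold, 10 * (1:6))
  manual <- vapply(sweep$threshold, function(th) {
    fqns(ivt(rec, th), stim)
  }, 1)
  expect_equal(sweep$score, manual)

  # Vi = 0: constant threshold, constant score
  flat <- rc_sweep(rec, stim, "ivt", "v_T", T_base = 50, Vi = 0, C = 30,
                   rc_values = 1:5, score = "fqns")
  expect_equal(length(unique(flat$threshold)), 1)
  expect_equal(length(unique(flat$score)), 1)

  expect_warning(
    sw <- rc_sweep(rec, stim, "ivt", "v_T", T_base = 10, Vi = 1, C = -20,
                   rc_values = c(1, 3), score = "fqns"),
    "non-positive")
  expect_equal(sw$rc, 3)  # the non-positive threshold row was dropped
})

test_that("per-class F1 matches hand-computed confusion arithmetic", {
  truth <- c("fixation", "fixation", "saccade", "saccade")
  pred <- c("fixation", "saccade", "saccade", "saccade")
  f1 <- event_f1(pred, truth)
  expect_equal(f1$f1[f1$class == "fixation"], 2 / 3)
  expect_equal(f1$f1[f1$class == "saccade"], 0.8)

  same <- event_f1(truth, truth)
  expect_true(all(same$f1 == 1))

  # class absent from truth reported as missing
  f1m <- event_f1(pred, truth, classes = c("fixation", "saccade",
                                           "smooth_pursuit"))
  expect_true(is.na(f1m$f1[f1m$class == "smooth_pursuit"]))
  expect_equal(f1m$support[f1m$class == "smooth_pursuit"], 0L)

  # invariant under consistent relabeling
  remap <- c(fixation = "stare", saccade = "move")
  f1r <- event_f1(unname(remap[pred]), unname(remap[truth]))
  expect_equal(sort(f1r$f1), sort(f1$f1))
})

test_that("the Lund2013-format adapter parses synthetic exports", {
  # synthetic stand-in written in the annotation export layout
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 400
  t <- (0:(n - 1)) * 2        # 500 Hz
  x <- c(rep(0, 150), seq(0, 10, length.out = 10), rep(10, 140),
         (0:99) * 0.04 + 10)
  lab <- c(rep(1, 150), rep(2, 10), rep(1, 140), rep(4, 100))
  utils::write.csv(data.frame(t = t, x = x, y = 0, label = lab), path,
                   row.names = FALSE)
  lund <- read_lund2013_csv(path)
  expect_s3_class(lund$recording, "gaze_recording")
  expect_equal(unique(lund$truth),
               c("fixation", "saccade", "smooth_pursuit"))

  # the F1 harness runs end-to-end on the adapter output
  ev <- ivdt(lund$recording, 50, 1.5)
  pred <- labels_from_segments(ev, n)
  f1 <- event_f1(pred, lund$truth,
                 classes = c("fixation", "saccade", "smooth_pursuit"))
  expect_true(all(f1$f1[!is.na(f1$f1)] >= 0 & f1$f1[!is.na(f1$f1)] <= 1))

  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = 0:2, x = 0, y = 0, label = c(1, 9, 1)),
                   bad, row.names = FALSE)
  expect_error(read_lund2013_csv(bad), "label code")
})
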