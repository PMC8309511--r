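#' Bundled synthetic stare/move dataset
#'
#' Generates a balanced, labeled behavior-window dataset entirely from the
#' oculomotor simulator, mixing three kinds of recordings so both classes are
#' well represented with varied structure:
#'
#' * search-like scripts — waypoints scattered uniformly over +/-12 degrees
#'   with short 0.25 s dwells and fast transitions, yielding many saccades
#'   (the `move` class) interleaved with brief fixations;
#' * six-point pursuit runs without stops, so the `stare` class includes
#'   smooth-pursuit trails and catch-up saccades add further `move` samples;
#' * four-target box-following runs contributing long clean fixations.
#'
#' Windows are rasterized with `spec` at each labeled sample and balanced
#' exactly via [build_dataset()].
#'
#' @param n_per_class Windows per class in the balanced dataset.
#' @param split Fraction of each class used for training.
#' @param seed Integer seed driving both the simulations and the subsampling.
#' @param rate_hz Sampling rate of the simulated recordings.
#' @param spec A [window_spec()].
#' @return A dataset list as returned by [build_dataset()].
#' @export
synthetic_behavior_dataset <- function(n_per_class = 2500, split = 0.8,
                                       seed = 1L, rate_hz = 40,
                                       spec = window_spec()) {
  recs <- list()
  n_move <- 0
  n_stare <- 0
  batch <- 0
  while (n_move < n_per_class * 1.1 || n_stare < n_per_class * 1.1) {
    batch <- batch + 1
    if (batch > 400) stop("simulation failed to produce enough windows")
    kind <- (batch - 1) %% 4
    # stay within 32-bit integer range whatever the caller's seed
    sub_seed <- as.integer((as.numeric(seed) * 131 + batch * 7919) %%
                             2147483647)
    sim <- if (kind < 2) {
      wp <- .with_seed(sub_seed, {
        data.frame(x = stats::runif(12, -12, 12),
                   y = stats::runif(12, -12, 12))
      })
      sc <- make_script("custom", waypoints = wp, stay_s = 0.25,
                        speed_deg_s = 150)
      simulate_gaze(sc, rate_hz, oculomotor_params(seed = sub_seed))
    } else if (kind == 2) {
      pat <- if (batch %% 8 < 4) "six_point_updown" else "six_point_zshape"
      sc <- make_script(pat, stops = FALSE)
      simulate_gaze(sc, rate_hz, oculomotor_params(seed = sub_seed))
    } else {
      sc <- make_script("four_target")
      simulate_gaze(sc, rate_hz, oculomotor_params(seed = sub_seed))
    }
    beh <- behavior_labels(sim$truth)
    n_move <- n_move + sum(beh == "move")
    n_stare <- n_stare + sum(beh == "stare")
    recs[[length(recs) + 1]] <- sim
  }
  build_dataset(recs, spec, n_per_class = n_per_class, split = split,
                seed = seed)
}
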