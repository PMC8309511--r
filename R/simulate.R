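#' Oculomotor noise and behavior parameters
#'
#' Parameters of the synthetic eye model. Fixational noise follows the
#' classical decomposition into tremor (a minute oscillation near 90 Hz),
#' microsaccades (fast micro-jumps that tend to return toward the fixation
#' center), and drift (a slow wander away from it). Pursuit runs at a gain
#' slightly below 1, so positional lag accumulates and is cleared by catch-up
#' saccades once it exceeds `catchup_lag_deg`. Saccades follow a
#' main-sequence-style fixed-duration model, `duration_ms = 2.2 * amplitude +
#' 21`, with a symmetric triangular velocity profile. Binocular dropouts
#' (blink-like samples invalid in both eyes) are injected at `dropout_rate`.
#'
#' @param tremor_amplitude Tremor amplitude in degrees.
#' @param tremor_frequency Tremor frequency in Hz.
#' @param microsaccade_rate Microsaccade rate per second.
#' @param microsaccade_amplitude Microsaccade amplitude in degrees.
#' @param return_bias Probability that a microsaccade points back toward the
#'   fixation center.
#' @param drift_speed Drift speed in deg/s.
#' @param pursuit_gain Eye/target velocity ratio during smooth pursuit
#'   (must be <= 1.2).
#' @param catchup_lag_deg Positional lag triggering a catch-up saccade.
#' @param dropout_rate Per-sample probability of a binocular dropout.
#' @param seed Integer seed making the simulation reproducible.
#' @return A list of class `oculomotor_params`.
#' @export
oculomotor_params <- function(tremor_amplitude = 0.05,
                              tremor_frequency = 90,
                              microsaccade_rate = 1.5,
                              microsaccade_amplitude = 0.3,
                              return_bias = 0.7,
                              drift_speed = 0.5,
                              pursuit_gain = 0.95,
                              catchup_lag_deg = 2,
                              dropout_rate = 0.01,
                              seed = 1L) {
  stopifnot(tremor_amplitude >= 0, microsaccade_rate >= 0,
            microsaccade_amplitude >= 0, drift_speed >= 0,
            pursuit_gain >= 0, pursuit_gain <= 1.2,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(tremor_amplitude = tremor_amplitude,
         tremor_frequency = tremor_frequency,
         microsaccade_rate = microsaccade_rate,
         microsaccade_amplitude = microsaccade_amplitude,
         return_bias = return_bias,
         drift_speed = drift_speed,
         pursuit_gain = pursuit_gain,
         catchup_lag_deg = catchup_lag_deg,
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "oculomotor_params"
  )
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a stimulus script
#'
#' A stimulus script is the ground-truth description of a moving-target task:
#' ordered waypoints, how long the target stays at each, and how long each
#' transition leg takes. Three built-in patterns are provided.
#'
#' `four_target` places four targets on the corners of a rectangle so that
#' the T1-T2 and T3-T4 visual angles are 15 degrees and T2-T3 is 27.5
#' degrees, with 3 s stays; transition times default to 0.2 s per leg.
#' `six_point_updown` and `six_point_zshape` move the target at a fixed
#' 30 deg/s over six points spanning a 20 degree grid, either alternating up
#' and down or tracing a Z; `stops = TRUE` holds 3 s at each point,
#' `stops = FALSE` passes through without pausing.
#'
#' @param pattern One of `"four_target"`, `"six_point_updown"`,
#'   `"six_point_zshape"`, `"custom"`.
#' @param transitions_s Transition durations in seconds (four_target; length
#'   3, recycled).
#' @param stay_s Stay duration at each waypoint in seconds.
#' @param stops For six-point patterns, whether the target pauses at points.
#' @param speed_deg_s Target speed for six-point patterns (deg/s).
#' @param waypoints For `pattern = "custom"`, a data.frame with `x`, `y` in
#'   degrees.
#' @return A list of class `stimulus_script` with `waypoints`, `stay_ms`,
#'   `transition_ms`, `pattern`.
#' @export
make_script <- function(pattern = c("four_target", "six_point_updown",
                                    "six_point_zshape", "custom"),
                        transitions_s = c(0.2, 0.2, 0.2),
                        stay_s = 3, stops = TRUE, speed_deg_s = 30,
                        waypoints = NULL) {
  pattern <- match.arg(pattern)
  if (pattern == "four_target") {
    wp <- data.frame(
      x = c(-13.75, -13.75, 13.75, 13.75),
      y = c(-7.5, 7.5, 7.5, -7.5)
    )
    transitions_s <- rep_len(transitions_s, 3)
    stay_ms <- rep(stay_s * 1000, 4)
    transition_ms <- transitions_s * 1000
  } else if (pattern %in% c("six_point_updown", "six_point_zshape")) {
    wp <- if (pattern == "six_point_updown") {
      data.frame(x = seq(-10, 10, length.out = 6),
                 y = rep(c(-5, 5), 3))
    } else {
      data.frame(x = c(-10, 0, 10, 0, -10, 10),
                 y = c(-5, -5, -5, 0, 5, 5))
    }
    stay_ms <- if (stops) rep(stay_s * 1000, 6) else rep(0, 6)
    d <- sqrt(diff(wp$x)^2 + diff(wp$y)^2)
    transition_ms <- d / speed_deg_s * 1000
  } else {
    if (is.null(waypoints) || nrow(waypoints) < 1) {
      stop("custom pattern requires waypoints")
    }
    wp <- waypoints[, c("x", "y")]
    stay_ms <- rep(stay_s * 1000, nrow(wp))
    transition_ms <- if (nrow(wp) > 1) {
      sqrt(diff(wp$x)^2 + diff(wp$y)^2) / speed_deg_s * 1000
    } else {
      numeric(0)
    }
  }
  if (nrow(wp) > 1 &&
      any(sqrt(diff(wp$x)^2 + diff(wp$y)^2) == 0)) {
    stop("consecutive waypoints must be distinct")
  }
  structure(
    list(waypoints = wp, stay_ms = stay_ms, transition_ms = transition_ms,
         pattern = pattern),
    class = "stimulus_script"
  )
}

#' Total scripted duration in ms
#' @param script A `stimulus_script`.
#' @export
script_duration_ms <- function(script) {
  sum(script$stay_ms) + sum(script$transition_ms)
}

# phase table: one row per stay/transition with type, start/end ms, endpoints
.script_phases <- function(script) {
  wp <- script$waypoints
  k <- nrow(wp)
  rows <- list()
  t0 <- 0
  for (i in seq_len(k)) {
    if (script$stay_ms[i] > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "stay", t0 = t0, t1 = t0 + script$stay_ms[i],
        x0 = wp$x[i], y0 = wp$y[i], x1 = wp$x[i], y1 = wp$y[i]
      )
      t0 <- t0 + script$stay_ms[i]
    }
    if (i < k) {
      dur <- script$transition_ms[i]
      rows[[length(rows) + 1]] <- data.frame(
        type = "transition", t0 = t0, t1 = t0 + dur,
        x0 = wp$x[i], y0 = wp$y[i], x1 = wp$x[i + 1], y1 = wp$y[i + 1]
      )
      t0 <- t0 + dur
    }
  }
  do.call(rbind, rows)
}

# pursuit-able target speed bound (deg/s); faster legs induce saccades
.PURSUIT_SPEED_MAX <- 30

#' Per-sample stimulus signal
#'
#' Expands a script onto the sampling grid of a recording: every sample gets
#' the intended behavior (`fixation` during stays, `pursuit` for transition
#' legs at target speed <= 30 deg/s, `transition` for faster legs), the
#' target position, and the target velocity vector.
#'
#' @param script A `stimulus_script`.
#' @param rate_hz Sampling rate in Hz.
#' @return A data.frame of class `stimulus_signal` with columns `t`, `type`,
#'   `x`, `y`, `vx`, `vy`.
#' @export
script_to_stimulus_signal <- function(script, rate_hz) {
  phases <- .script_phases(script)
  total <- script_duration_ms(script)
  dt <- 1000 / rate_hz
  t <- seq(0, total - 1e-9, by = dt)
  idx <- findInterval(t, phases$t0)
  idx[idx < 1] <- 1
  ph <- phases[idx, ]
  frac <- ifelse(ph$t1 > ph$t0, (t - ph$t0) / (ph$t1 - ph$t0), 0)
  x <- ph$x0 + frac * (ph$x1 - ph$x0)
  y <- ph$y0 + frac * (ph$y1 - ph$y0)
  leg_len <- sqrt((ph$x1 - ph$x0)^2 + (ph$y1 - ph$y0)^2)
  speed <- ifelse(ph$type == "transition",
                  leg_len / (ph$t1 - ph$t0) * 1000, 0)
  type <- ifelse(ph$type == "stay", "fixation",
                 ifelse(speed <= .PURSUIT_SPEED_MAX * (1 + 1e-9),
                        "pursuit", "transition"))
  vx <- ifelse(type == "fixation", 0,
               (ph$x1 - ph$x0) / leg_len * speed)
  vy <- ifelse(type == "fixation", 0,
               (ph$y1 - ph$y0) / leg_len * speed)
  out <- data.frame(t = t, type = type, x = x, y = y, vx = vx, vy = vy)
  rownames(out) <- NULL
  class(out) <- c("stimulus_signal", "data.frame")
  attr(out, "phases") <- phases
  attr(out, "phase_index") <- idx
  out
}

#' Default screen geometry used by the simulator
#'
#' A 1920 x 1080 monitor, 510 x 287 mm, viewed at 600 mm — wide enough that
#' all built-in stimulus patterns fit on screen.
#' @export
default_geometry <- function() {
  screen_geometry(1920, 1080, 510, 287, 600)
}

#' Simulate an eye-tracking recording of a stimulus script
#'
#' Generates a gaze recording, in degrees, of an idealized observer
#' performing the task described by `script`, with per-sample ground-truth
#' labels. During stays the eye fixates the target with tremor, drift, and
#' return-biased microsaccades; during slow target motion (<= 30 deg/s) it
#' pursues at `pursuit_gain`, clearing accumulated lag with catch-up saccades;
#' fast repositionings are executed as main-sequence saccades with a
#' symmetric velocity profile. Binocular dropouts are injected at
#' `dropout_rate`. The simulation is deterministic given `ocul$seed`.
#'
#' @param script A `stimulus_script`.
#' @param rate_hz Sampling rate in Hz (40 and 500 are the intended settings;
#'   any positive rate works).
#' @param ocul An [oculomotor_params()] object.
#' @param geometry Screen geometry attached to the recording.
#' @return A list with `recording` (a `gaze_recording` in degrees), `truth`
#'   (character vector of per-sample labels `fixation` / `smooth_pursuit` /
#'   `saccade`), and `stimulus` (the [script_to_stimulus_signal()] table).
#' @export
simulate_gaze <- function(script, rate_hz = 40, ocul = oculomotor_params(),
                          geometry = default_geometry()) {
  if (!inherits(script, "stimulus_script") || nrow(script$waypoints) < 1) {
    stop("empty or invalid script")
  }
  stim <- script_to_stimulus_signal(script, rate_hz)
  phases <- attr(stim, "phases")
  pidx <- attr(stim, "phase_index")
  n <- nrow(stim)
  dt <- 1000 / rate_hz  # ms per sample
  .with_seed(ocul$seed, {
    # fixational noise state
    drift_angle <- stats::runif(1, 0, 2 * pi)
    off <- c(0, 0)             # slow drift + microsaccade offset
    ms_step <- c(0, 0)         # per-sample microsaccade displacement
    ms_left <- 0L
    tremor_phase <- stats::runif(2, 0, 2 * pi)
    # behavior state
    lag <- 0                   # pursuit positional lag (deg)
    catch_left <- 0L           # remaining catch-up saccade samples
    catch_step <- 0

    ex <- numeric(n)
    ey <- numeric(n)
    truth <- character(n)
    prev_type <- "fixation"

    for (i in seq_len(n)) {
      type <- stim$type[i]
      tx <- stim$x[i]; ty <- stim$y[i]
      label <- NA_character_
      if (type == "fixation") {
        if (prev_type != "fixation") lag <- 0
        base <- c(tx, ty)
        label <- "fixation"
        fixating <- TRUE
      } else if (type == "pursuit") {
        speed <- sqrt(stim$vx[i]^2 + stim$vy[i]^2)
        u <- c(stim$vx[i], stim$vy[i]) / speed
        if (catch_left > 0L) {
          lag <- max(0, lag - catch_step)
          catch_left <- catch_left - 1L
          label <- "saccade"
        } else {
          lag <- lag + (1 - ocul$pursuit_gain) * speed * dt / 1000
          if (lag >= ocul$catchup_lag_deg) {
            d_ms <- 2.2 * lag + 21
            nc <- max(1L, as.integer(round(d_ms / dt)))
            catch_step <- lag / nc
            lag <- max(0, lag - catch_step)
            catch_left <- nc - 1L
            label <- "saccade"
          } else {
            label <- "smooth_pursuit"
          }
        }
        base <- c(tx, ty) - lag * u
        fixating <- FALSE
      } else { # fast transition: one main-sequence saccade, then hold at goal
        ph <- phases[pidx[i], ]
        p0 <- c(ph$x0, ph$y0)
        p1 <- c(ph$x1, ph$y1)
        amp <- sqrt(sum((p1 - p0)^2))
        # clamp to the leg duration so the eye lands before the target does
        d_ms <- min(2.2 * amp + 21, ph$t1 - ph$t0)
        tau <- (stim$t[i] - ph$t0) / d_ms
        if (tau < 1) {
          s <- if (tau < 0.5) 2 * tau^2 else 1 - 2 * (1 - tau)^2
          base <- p0 + s * (p1 - p0)
        } else {
          base <- p1
        }
        # a sample is a saccade only if the ballistic flight covers at
        # least half of its sampling interval (t - dt, t]; samples whose
        # interval lies mostly before take-off or after landing are
        # fixation samples on the old/new target
        flight <- c(ph$t0, ph$t0 + d_ms)
        overlap <- min(stim$t[i], flight[2]) -
          max(stim$t[i] - dt, flight[1])
        label <- if (overlap >= dt / 2) "saccade" else "fixation"
        lag <- 0
        fixating <- label == "fixation"
      }

      # fixational noise: drift (mean-reverting wander) + microsaccades,
      # active while fixating or pursuing; tremor always present
      if (fixating || type == "pursuit") {
        drift_angle <- drift_angle + stats::rnorm(1, 0, 0.5)
        off <- off + ocul$drift_speed * dt / 1000 *
          c(cos(drift_angle), sin(drift_angle))
        off <- off * exp(-dt / 1000)  # spring back toward center, tau = 1 s
        if (ms_left > 0L) {
          off <- off + ms_step
          ms_left <- ms_left - 1L
        } else if (stats::runif(1) < ocul$microsaccade_rate * dt / 1000) {
          dir <- if (stats::runif(1) < ocul$return_bias && sum(off^2) > 0) {
            -off / sqrt(sum(off^2))
          } else {
            a <- stats::runif(1, 0, 2 * pi)
            c(cos(a), sin(a))
          }
          nms <- max(1L, as.integer(round(20 / dt)))  # ~20 ms micro-jump
          ms_step <- ocul$microsaccade_amplitude * dir / nms
          off <- off + ms_step
          ms_left <- nms - 1L
        }
      }
      tremor <- ocul$tremor_amplitude *
        sin(2 * pi * ocul$tremor_frequency * stim$t[i] / 1000 + tremor_phase)
      pos <- base + off + tremor
      ex[i] <- pos[1]
      ey[i] <- pos[2]
      truth[i] <- label
      prev_type <- type
    }

    dropout <- stats::runif(n) < ocul$dropout_rate
    samples <- data.frame(
      t = stim$t, x = ex, y = ey,
      valid_l = !dropout, valid_r = !dropout
    )
    rec <- gaze_recording(samples, geometry, "degrees", rate_hz)
    list(recording = rec, truth = truth, stimulus = stim)
  })
}
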