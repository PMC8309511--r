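# shared fixtures: tiny hand-built recordings and default geometry

test_geometry <- function() screen_geometry(1920, 1080, 510, 287, 600)

# recording straight from coordinate vectors (degrees, 40 Hz grid unless
# timestamps given)
tiny_rec <- function(x, y, t = NULL, rate = 40) {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) * 1000 / rate
  gaze_recording(data.frame(t = t, x = x, y = y), test_geometry(),
                 "degrees", rate)
}

# noise-free hold -> ramp -> hold trace (pursuit-like middle section)
hold_ramp_hold <- function(hold_s = 1, ramp_s = 1.5, speed = 20, rate = 40) {
  dt <- 1 / rate
  t1 <- seq(0, hold_s - dt, by = dt)
  t2 <- seq(hold_s, hold_s + ramp_s - dt, by = dt)
  t3 <- seq(hold_s + ramp_s, 2 * hold_s + ramp_s - dt, by = dt)
  x <- c(rep(0, length(t1)), (t2 - hold_s) * speed,
         rep(ramp_s * speed, length(t3)))
  tiny_rec(x, rep(0, length(x)), t = c(t1, t2, t3) * 1000, rate = rate)
}

# pseudo-random gaze-like trace: random walk with occasional jumps
random_trace <- function(n, seed) {
  set.seed(seed)
  dx <- stats::rnorm(n, 0, 0.15)
  jump <- stats::runif(n) < 0.12
  dx[jump] <- dx[jump] + stats::rnorm(sum(jump), 0, 6)
  dy <- stats::rnorm(n, 0, 0.15)
  dy[jump] <- dy[jump] + stats::rnorm(sum(jump), 0, 6)
  t <- cumsum(stats::runif(n, 15, 40))
  tiny_rec(cumsum(dx), cumsum(dy), t = t)
}
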