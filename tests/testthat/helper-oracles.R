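# Independent brute-force oracles for the four detectors. These deliberately
# re-derive everything from first principles (scalar loops, from-scratch
# dispersion and distance computations) so they share no code path with the
# package implementations.

oracle_velocities <- function(rec) {
  s <- rec$samples
  v <- numeric(nrow(s))
  for (i in seq_len(nrow(s))[-1]) {
    v[i] <- sqrt((s$x[i] - s$x[i - 1])^2 + (s$y[i] - s$y[i - 1])^2) /
      ((s$t[i] - s$t[i - 1]) / 1000)
  }
  v
}

# run grouping by scalar scan
oracle_runs <- function(labels) {
  out <- list()
  start <- 1
  for (i in seq_along(labels)[-1]) {
    if (labels[i] != labels[i - 1]) {
      out[[length(out) + 1]] <- c(start, i - 1)
      start <- i
    }
  }
  out[[length(out) + 1]] <- c(start, length(labels))
  out
}

oracle_ivt_labels <- function(rec, v_T) {
  v <- oracle_velocities(rec)
  ifelse(v < v_T, "fixation", "saccade")
}

oracle_disp <- function(rec, i, j) {
  xs <- rec$samples$x[i:j]
  ys <- rec$samples$y[i:j]
  (max(xs) - min(xs)) + (max(ys) - min(ys))
}

oracle_idt_labels <- function(rec, D_T, dur_T) {
  n <- nrow(rec$samples)
  t <- rec$samples$t
  labels <- rep("saccade", n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && t[j] - t[i] < dur_T) j <- j + 1
    if (t[j] - t[i] < dur_T) break
    if (oracle_disp(rec, i, j) <= D_T) {
      while (j < n && oracle_disp(rec, i, j + 1) <= D_T) j <- j + 1
      labels[i:j] <- "fixation"
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  labels
}

# quadratic-time reference DBSCAN over (x, y, weighted scaled time)
oracle_dbscan_assign <- function(rec, min_points, time_weight, eps) {
  s <- rec$samples
  n <- nrow(s)
  extent <- max(max(s$x) - min(s$x), max(s$y) - min(s$y))
  z <- if (max(s$t) > min(s$t) && extent > 0) {
    time_weight * (s$t - min(s$t)) / (max(s$t) - min(s$t)) * extent
  } else {
    rep(0, n)
  }
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d[i, j] <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 +
                      (z[i] - z[j])^2)
  }
  core <- rowSums(d <= eps) >= min_points
  assign <- rep(NA_integer_, n)
  cluster <- 0L
  for (i in 1:n) {
    if (!core[i] || !is.na(assign[i])) next
    cluster <- cluster + 1L
    queue <- i
    assign[i] <- cluster
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      nb <- which(d[p, ] <= eps & core)
      new <- nb[is.na(assign[nb])]
      assign[new] <- cluster
      queue <- c(queue, new)
    }
  }
  for (i in 1:n) {
    if (core[i] || !is.na(assign[i])) next
    cn <- which(d[i, ] <= eps & core)
    if (length(cn) > 0) assign[i] <- assign[min(cn)]
  }
  assign
}

oracle_ivdt_labels <- function(rec, v_T, D_T, min_fix_ms = 100) {
  n <- nrow(rec$samples)
  t <- rec$samples$t
  v <- oracle_velocities(rec)
  labels <- rep("saccade", n)
  i <- 1
  while (i <= n) {
    if (v[i] >= v_T) { i <- i + 1; next }
    b <- i
    while (b < n && v[b + 1] < v_T) b <- b + 1
    a <- i
    while (a <= b) {
      j <- a
      while (j < b && t[j] - t[a] < min_fix_ms) j <- j + 1
      if (oracle_disp(rec, a, j) <= D_T) {
        while (j < b && oracle_disp(rec, a, j + 1) <= D_T) j <- j + 1
        labels[a:j] <- "fixation"
        a <- j + 1
      } else {
        labels[a] <- "smooth_pursuit"
        a <- a + 1
      }
    }
    i <- b + 1
  }
  # absorb single-sample fixation/pursuit runs into a non-saccade neighbor
  runs <- oracle_runs(labels)
  vals <- vapply(runs, function(r) labels[r[1]], "")
  lens <- vapply(runs, function(r) r[2] - r[1] + 1, 1)
  soft <- c("fixation", "smooth_pursuit")
  for (q in seq_along(runs)) {
    if (lens[q] == 1 && vals[q] %in% soft) {
      if (q > 1 && vals[q - 1] %in% soft) {
        vals[q] <- vals[q - 1]
      } else if (q < length(runs) && vals[q + 1] %in% soft) {
        vals[q] <- vals[q + 1]
      }
    }
  }
  out <- character(n)
  for (q in seq_along(runs)) out[runs[[q]][1]:runs[[q]][2]] <- vals[q]
  out
}
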