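#' Drawing canvas for gaze visualizations
#'
#' Defines the raster size, the degree-space region it covers, an optional
#' background, and the color scale used for time/density encoding. All
#' renderers return an RGBA array (`height x width x 4`, values in `[0, 1]`)
#' that can be written with [write_raster_png()].
#'
#' @param width_px,height_px Raster size in pixels.
#' @param xlim,ylim Degree-space extents mapped onto the raster.
#' @param background `NULL` for a transparent background, a color string for
#'   a solid fill, or an RGB(A) array to underlay (e.g. a stimulus image read
#'   with [png::readPNG()]; it is stretched to the canvas size).
#' @param colormap Character vector of at least 2 color stops, interpolated
#'   over density or time order. Defaults to a perceptually ordered
#'   sequential scale.
#' @return A list of class `gaze_canvas`.
#' @export
gaze_canvas <- function(width_px = 480, height_px = 360,
                        xlim = c(-20, 20), ylim = c(-15, 15),
                        background = NULL,
                        colormap = grDevices::hcl.colors(7, "Viridis")) {
  stopifnot(width_px > 0, height_px > 0, length(colormap) >= 2,
            diff(xlim) > 0, diff(ylim) > 0)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         xlim = xlim, ylim = ylim, background = background,
         colormap = colormap),
    class = "gaze_canvas"
  )
}

# degree -> continuous pixel coordinates (1..W / 1..H pixel centers)
.cv_px <- function(canvas, x, y) {
  list(
    x = (x - canvas$xlim[1]) / diff(canvas$xlim) * canvas$width_px + 0.5,
    y = (y - canvas$ylim[1]) / diff(canvas$ylim) * canvas$height_px + 0.5
  )
}

.blank_rgba <- function(canvas) {
  arr <- array(0, dim = c(canvas$height_px, canvas$width_px, 4))
  bg <- canvas$background
  if (is.character(bg)) {
    rgb <- grDevices::col2rgb(bg)[, 1] / 255
    arr[, , 1] <- rgb[1]; arr[, , 2] <- rgb[2]; arr[, , 3] <- rgb[3]
    arr[, , 4] <- 1
  } else if (is.array(bg)) {
    # nearest-neighbor stretch of an image underlay
    ry <- ceiling(seq_len(canvas$height_px) / canvas$height_px * dim(bg)[1])
    rx <- ceiling(seq_len(canvas$width_px) / canvas$width_px * dim(bg)[2])
    for (ch in 1:3) {
      src <- if (length(dim(bg)) == 3) bg[ry, rx, min(ch, dim(bg)[3])] else bg[ry, rx]
      arr[, , ch] <- src
    }
    arr[, , 4] <- 1
  }
  arr
}

# src-over compositing of two RGBA arrays
.comp_over <- function(dst, src) {
  sa <- src[, , 4]
  da <- dst[, , 4]
  oa <- sa + da * (1 - sa)
  safe <- ifelse(oa > 0, oa, 1)
  for (ch in 1:3) {
    dst[, , ch] <- (src[, , ch] * sa + dst[, , ch] * da * (1 - sa)) / safe
  }
  dst[, , 4] <- oa
  dst
}

# separable Gaussian blur of a matrix by shifted accumulation
.gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  shift_add <- function(mat, along) {
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      if (along == 1) {
        src_rows <- max(1, 1 - off):min(nrow(mat), nrow(mat) - off)
        out[src_rows + off, ] <- out[src_rows + off, ] +
          k[j] * mat[src_rows, ]
      } else {
        src_cols <- max(1, 1 - off):min(ncol(mat), ncol(mat) - off)
        out[, src_cols + off] <- out[, src_cols + off] +
          k[j] * mat[, src_cols]
      }
    }
    out
  }
  shift_add(shift_add(m, 1), 2)
}

.ramp <- function(colors) {
  f <- grDevices::colorRamp(colors)
  function(s) f(pmin(pmax(s, 0), 1)) / 255
}

# accumulate unit counts at sample positions into a canvas-sized matrix;
# returns the count matrix (mass = number of samples landing on canvas)
.accumulate_counts <- function(canvas, x, y) {
  p <- .cv_px(canvas, x, y)
  cx <- floor(p$x); cy <- floor(p$y)
  keep <- cx >= 1 & cx <= canvas$width_px & cy >= 1 & cy <= canvas$height_px
  m <- matrix(0, canvas$height_px, canvas$width_px)
  if (any(keep)) {
    tab <- table(factor(cy[keep], levels = 1:canvas$height_px),
                 factor(cx[keep], levels = 1:canvas$width_px))
    m <- m + as.numeric(tab)
  }
  m
}

#' Fixation-count heatmap
#'
#' High-abstraction view of a parsed recording: the member samples of every
#' fixation (or stare) segment are counted per pixel, smoothed with a
#' Gaussian kernel, and mapped through the canvas colormap. Saccade samples
#' contribute nothing. Pixels with zero density stay fully transparent. The
#' returned raster carries the pre-smoothing count matrix in attribute
#' `counts` (its total equals the number of on-canvas fixation samples).
#'
#' @param events A `gaze_events` data.frame.
#' @param rec The `gaze_recording` the events refer to (degrees).
#' @param canvas A [gaze_canvas()].
#' @param sigma_deg Gaussian smoothing bandwidth in degrees (default 1, the
#'   foveal scale).
#' @param labels Segment labels treated as fixation-like.
#' @return RGBA array `height x width x 4`.
#' @export
render_heatmap <- function(events, rec, canvas = gaze_canvas(),
                           sigma_deg = 1, labels = c("fixation", "stare")) {
  arr <- .blank_rgba(canvas)
  fx <- events[events$label %in% labels, , drop = FALSE]
  if (nrow(fx) == 0) {
    warning("no fixation segments; returning blank raster")
    attr(arr, "counts") <- matrix(0, canvas$height_px, canvas$width_px)
    return(arr)
  }
  idx <- unlist(mapply(seq, fx$start_index, fx$end_index, SIMPLIFY = FALSE))
  counts <- .accumulate_counts(canvas, rec$samples$x[idx], rec$samples$y[idx])
  sigma_px <- sigma_deg / diff(canvas$xlim) * canvas$width_px
  dens <- .gauss_blur(counts, sigma_px)
  peak <- max(dens)
  layer <- array(0, dim = dim(arr))
  if (peak > 0) {
    s <- dens / peak
    ramp <- .ramp(canvas$colormap)
    cols <- ramp(as.vector(s))
    layer[, , 1] <- cols[, 1]
    layer[, , 2] <- cols[, 2]
    layer[, , 3] <- cols[, 3]
    layer[, , 4] <- ifelse(s > 0, pmin(1, 0.25 + 0.75 * s), 0)
  }
  out <- .comp_over(arr, layer)
  attr(out, "counts") <- counts
  out
}

# draw an anti-alias-free disc into an RGBA layer (in place)
.draw_disc <- function(layer, cx, cy, r, col_rgb, alpha = 1) {
  h <- dim(layer)[1]; w <- dim(layer)[2]
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  if (length(xs) == 0 || length(ys) == 0) return(layer)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  inside <- d2 <= r^2
  for (ch in 1:3) {
    m <- layer[ys, xs, ch]
    m[inside] <- col_rgb[ch]
    layer[ys, xs, ch] <- m
  }
  a <- layer[ys, xs, 4]
  a[inside] <- pmax(a[inside], alpha)
  layer[ys, xs, 4] <- a
  layer
}

# tapered, color-graded stroke from (x0,y0) to (x1,y1); widths in px at the
# two ends, colors as rgb vectors; returns the modified layer
.draw_stroke <- function(layer, x0, y0, x1, y1, w0, w1, col0, col1) {
  h <- dim(layer)[1]; w <- dim(layer)[2]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len == 0) return(layer)
  ux <- (x1 - x0) / len; uy <- (y1 - y0) / len
  pad <- max(w0, w1) / 2 + 1
  xs <- max(1, floor(min(x0, x1) - pad)):min(w, ceiling(max(x0, x1) + pad))
  ys <- max(1, floor(min(y0, y1) - pad)):min(h, ceiling(max(y0, y1) + pad))
  if (length(xs) == 0 || length(ys) == 0) return(layer)
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  s <- ((px - x0) * ux + (py - y0) * uy) / len
  s_cl <- pmin(pmax(s, 0), 1)
  qx <- x0 + s_cl * len * ux
  qy <- y0 + s_cl * len * uy
  dist <- sqrt((px - qx)^2 + (py - qy)^2)
  width_at <- w0 + (w1 - w0) * s_cl
  inside <- dist <= width_at / 2 & s >= 0 & s <= 1
  if (!any(inside)) return(layer)
  for (ch in 1:3) {
    m <- layer[ys, xs, ch]
    m[inside] <- col0[ch] + (col1[ch] - col0[ch]) * s_cl[inside]
    layer[ys, xs, ch] <- m
  }
  a <- layer[ys, xs, 4]
  a[inside] <- 1
  layer[ys, xs, 4] <- a
  layer
}

#' Scanpath visualization
#'
#' Low-abstraction view: fixation (or stare) centroids drawn as red dots
#' whose radius grows with the square root of segment duration, connected by
#' straight links in time order; the raw gaze samples can be underlaid as
#' small black dots.
#'
#' @param events A `gaze_events` data.frame in chronological order.
#' @param rec Optional `gaze_recording` whose raw samples are underlaid.
#' @param canvas A [gaze_canvas()].
#' @param labels Segment labels drawn as scanpath nodes.
#' @param link_width_px Width of the connecting links.
#' @return RGBA array; attribute `n_links` records the number of links drawn.
#' @export
render_scanpath <- function(events, rec = NULL, canvas = gaze_canvas(),
                            labels = c("fixation", "stare"),
                            link_width_px = 2) {
  arr <- .blank_rgba(canvas)
  layer <- array(0, dim = dim(arr))
  if (!is.null(rec)) {
    p <- .cv_px(canvas, rec$samples$x, rec$samples$y)
    for (i in seq_along(p$x)) {
      layer <- .draw_disc(layer, p$x[i], p$y[i], 1, c(0, 0, 0))
    }
  }
  fx <- events[events$label %in% labels, , drop = FALSE]
  red <- c(0.85, 0.1, 0.1)
  n_links <- 0L
  if (nrow(fx) >= 1) {
    p <- .cv_px(canvas, fx$centroid_x, fx$centroid_y)
    if (nrow(fx) >= 2) {
      for (k in seq_len(nrow(fx) - 1)) {
        layer <- .draw_stroke(layer, p$x[k], p$y[k], p$x[k + 1], p$y[k + 1],
                              link_width_px, link_width_px, red, red)
        n_links <- n_links + 1L
      }
    }
    r <- 3 + 4 * sqrt(fx$duration_ms / max(fx$duration_ms, 1))
    for (k in seq_len(nrow(fx))) {
      layer <- .draw_disc(layer, p$x[k], p$y[k], r[k], red)
    }
  }
  out <- .comp_over(arr, layer)
  attr(out, "n_links") <- n_links
  out
}

#' Abstract gaze-movement visualization
#'
#' Mid-abstraction view between heatmap and scanpath: each stare segment
#' becomes its own heatmap layer colored by time order, composited
#' oldest-first, and consecutive layers are joined by movement links. A link
#' is a straight tapered stroke — wide at the source, narrow at the
#' destination, so the taper encodes direction — whose color is interpolated
#' from the source layer color to the destination layer color. Its
#' attachment points are pulled one smoothing bandwidth outward from the two
#' layer centroids along the movement direction, so links stay visible where
#' layers overlap.
#'
#' @param events A `gaze_events` data.frame; segments with a label in
#'   `labels` become layers.
#' @param rec The `gaze_recording` the events refer to.
#' @param canvas A [gaze_canvas()].
#' @param sigma_deg Per-layer Gaussian bandwidth in degrees.
#' @param labels Stare-like labels.
#' @param taper_px Stroke width in pixels at the source and destination ends
#'   (length 2, decreasing). `c(w, w)` reproduces the legacy constant-width
#'   link style.
#' @return RGBA array; attributes `n_links` and `layer_colors` (hex colors
#'   per layer, time-ordered).
#' @export
render_abstract_movement <- function(events, rec, canvas = gaze_canvas(),
                                     sigma_deg = 1,
                                     labels = c("fixation", "stare"),
                                     taper_px = c(6, 2)) {
  arr <- .blank_rgba(canvas)
  fx <- events[events$label %in% labels, , drop = FALSE]
  attr(arr, "n_links") <- 0L
  attr(arr, "layer_colors") <- character(0)
  if (nrow(fx) == 0) return(arr)
  k <- nrow(fx)
  ramp <- .ramp(canvas$colormap)
  ord_cols <- ramp(if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1))
  sigma_px <- sigma_deg / diff(canvas$xlim) * canvas$width_px
  cpx <- .cv_px(canvas, fx$centroid_x, fx$centroid_y)
  out <- arr
  # heatmap layers first, oldest to newest
  for (q in seq_len(k)) {
    idx <- fx$start_index[q]:fx$end_index[q]
    counts <- .accumulate_counts(canvas, rec$samples$x[idx],
                                 rec$samples$y[idx])
    dens <- .gauss_blur(counts, sigma_px)
    peak <- max(dens)
    layer <- array(0, dim = dim(arr))
    if (peak > 0) {
      s <- dens / peak
      for (ch in 1:3) layer[, , ch] <- ord_cols[q, ch]
      layer[, , 4] <- ifelse(s > 0, pmin(1, 0.3 + 0.7 * s), 0)
    }
    out <- .comp_over(out, layer)
  }
  # movement links on top so direction stays readable over the layers
  if (k >= 2) {
    link <- array(0, dim = dim(arr))
    for (q in seq_len(k - 1)) {
      dx <- cpx$x[q + 1] - cpx$x[q]
      dy <- cpx$y[q + 1] - cpx$y[q]
      len <- sqrt(dx^2 + dy^2)
      if (len == 0) next
      # anchors pulled one bandwidth outward from the density cores
      ux <- dx / len; uy <- dy / len
      a0 <- c(cpx$x[q] + ux * sigma_px, cpx$y[q] + uy * sigma_px)
      a1 <- c(cpx$x[q + 1] - ux * sigma_px, cpx$y[q + 1] - uy * sigma_px)
      link <- .draw_stroke(link, a0[1], a0[2], a1[1], a1[2],
                           taper_px[1], taper_px[2],
                           ord_cols[q, 1:3], ord_cols[q + 1, 1:3])
    }
    out <- .comp_over(out, link)
  }
  attr(out, "n_links") <- k - 1L
  attr(out, "layer_colors") <- grDevices::rgb(ord_cols[, 1], ord_cols[, 2],
                                              ord_cols[, 3])
  out
}

#' Write an RGBA raster to a PNG file
#'
#' @param raster RGBA array from one of the renderers.
#' @param path Output path.
#' @export
write_raster_png <- function(raster, path) {
  a <- raster
  attributes(a) <- list(dim = dim(raster))
  png::writePNG(a, path)
  invisible(path)
}
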