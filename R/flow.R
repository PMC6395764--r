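# Dense optical flow between consecutive frames via local quadratic
# polynomial expansion (Farneback), with coarse-to-fine pyramidal
# refinement, plus per-element motion summaries, divergence/curl, and
# lognormal speed-distribution fits.

conv1_replicate <- function(v, k) {
  # correlation (stats::filter flips the kernel, so pre-reverse it)
  r <- (length(k) - 1) / 2
  n <- length(v)
  vp <- c(rep(v[1], r), v, rep(v[n], r))
  as.numeric(stats::filter(vp, rev(k), sides = 2))[(r + 1):(r + n)]
}
sep_correlate <- function(m, ky, kx) {
  m2 <- apply(m, 2, conv1_replicate, k = ky)
  t(apply(t(m2), 2, conv1_replicate, k = kx))
}

# Quadratic polynomial expansion f(p + o) ~ c + b'o + o'Ao with Gaussian
# applicability; returns per-pixel coefficient fields.
poly_expansion <- function(f, n = 5L, sigma = 1.5) {
  xw <- -n:n
  a <- exp(-xw^2 / (2 * sigma^2))
  pows <- list(one = a, x = a * xw, x2 = a * xw^2)
  # G: inner products of the basis {1, x, y, x2, y2, xy} under a(x)a(y)
  s0 <- sum(a); s2 <- sum(a * xw^2); s4 <- sum(a * xw^4)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[1, 4] <- G[4, 1] <- s2 * s0
  G[1, 5] <- G[5, 1] <- s0 * s2
  G[2, 2] <- s2 * s0
  G[3, 3] <- s0 * s2
  G[4, 4] <- s4 * s0
  G[5, 5] <- s0 * s4
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Ginv <- solve(G)
  # correlations (applicability is symmetric so correlation = convolution)
  v1 <- sep_correlate(f, pows$one, pows$one)
  vx <- sep_correlate(f, pows$one, pows$x)
  vy <- sep_correlate(f, pows$x, pows$one)
  vx2 <- sep_correlate(f, pows$one, pows$x2)
  vy2 <- sep_correlate(f, pows$x2, pows$one)
  vxy <- sep_correlate(f, pows$x, pows$x)
  co <- function(w) Ginv[w, 1] * v1 + Ginv[w, 2] * vx + Ginv[w, 3] * vy +
    Ginv[w, 4] * vx2 + Ginv[w, 5] * vy2 + Ginv[w, 6] * vxy
  list(c = co(1), bx = co(2), by = co(3),
       axx = co(4), ayy = co(5), axy = co(6))
}

warp_field <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  yy <- matrix(rep(seq_len(ny), nx), ny) + dy
  xx <- matrix(rep(seq_len(nx), each = ny), ny) + dx
  matrix(bilinear_sample(m, as.vector(yy), as.vector(xx)), ny, nx)
}

downsample2 <- function(m) {
  s <- gauss_blur(m, 1)
  s[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}
upsample2_to <- function(m, ny, nx) {
  yy <- (seq_len(ny) + 0.5) / 2
  xx <- (seq_len(nx) + 0.5) / 2
  matrix(bilinear_sample(m, rep(yy, nx), rep(xx, each = ny)), ny, nx)
}

flow_step <- function(p1, p2, dy, dx, smooth_r) {
  axx2 <- warp_field(p2$axx, dy, dx); ayy2 <- warp_field(p2$ayy, dy, dx)
  axy2 <- warp_field(p2$axy, dy, dx)
  bx2 <- warp_field(p2$bx, dy, dx); by2 <- warp_field(p2$by, dy, dx)
  A11 <- (p1$axx + axx2) / 2
  A22 <- (p1$ayy + ayy2) / 2
  A12 <- (p1$axy + axy2) / 4   # off-diagonal of A is axy/2
  dbx <- -0.5 * (bx2 - p1$bx) + A11 * dx + A12 * dy
  dby <- -0.5 * (by2 - p1$by) + A12 * dx + A22 * dy
  G11 <- A11^2 + A12^2
  G12 <- A12 * (A11 + A22)
  G22 <- A22^2 + A12^2
  h1 <- A11 * dbx + A12 * dby
  h2 <- A12 * dbx + A22 * dby
  G11 <- box_mean(G11, smooth_r); G12 <- box_mean(G12, smooth_r)
  G22 <- box_mean(G22, smooth_r)
  h1 <- box_mean(h1, smooth_r); h2 <- box_mean(h2, smooth_r)
  det <- G11 * G22 - G12^2
  det[abs(det) < 1e-12] <- 1e-12
  list(dx = (G22 * h1 - G12 * h2) / det,
       dy = (G11 * h2 - G12 * h1) / det)
}

#' Dense optical flow between two frames (Farneback)
#'
#' Local quadratic polynomial expansions over a Gaussian-weighted
#' neighbourhood approximate both frames; the displacement field follows
#' from the change in the linear coefficients, refined over a coarse-to-
#' fine image pyramid. The resulting per-pixel velocities are averaged
#' over a 15-pixel region and converted to micron/s.
#'
#' @param frame_t,frame_t1 Consecutive intensity frames (same shape).
#' @param pixel_size_nm Pixel size in nm.
#' @param frame_interval_s Frame interval in seconds.
#' @param poly_n Neighbourhood half-size of the polynomial expansion
#'   (default 5).
#' @param poly_sigma Gaussian applicability sigma (default 1.5).
#' @param pyramid_levels Pyramid levels (default 3).
#' @param iterations Refinement iterations per level (default 3).
#' @param avg_window_px Final averaging window (default 15).
#' @return Object of class `er_flow`: `vy`, `vx` (micron/s matrices,
#'   positive y downwards), and the parameter set.
#' @export
farneback_flow <- function(frame_t, frame_t1, pixel_size_nm,
                           frame_interval_s, poly_n = 5L, poly_sigma = 1.5,
                           pyramid_levels = 3L, iterations = 3L,
                           avg_window_px = 15L) {
  stopifnot(all(dim(frame_t) == dim(frame_t1)))
  if (is.na(frame_interval_s) || frame_interval_s <= 0)
    stop("farneback_flow: frame_interval_s required (single frame?)")
  pyr1 <- list(frame_t); pyr2 <- list(frame_t1)
  for (l in seq_len(pyramid_levels - 1)) {
    if (min(dim(pyr1[[l]])) < 4 * poly_n) break
    pyr1[[l + 1]] <- downsample2(pyr1[[l]])
    pyr2[[l + 1]] <- downsample2(pyr2[[l]])
  }
  nl <- length(pyr1)
  dy <- dx <- matrix(0, nrow(pyr1[[nl]]), ncol(pyr1[[nl]]))
  for (l in nl:1) {
    f1 <- pyr1[[l]]; f2 <- pyr2[[l]]
    if (any(dim(dy) != dim(f1))) {
      dy <- upsample2_to(dy, nrow(f1), ncol(f1)) * 2
      dx <- upsample2_to(dx, nrow(f1), ncol(f1)) * 2
    }
    # averaging window follows the pyramid scale so coarse levels are not
    # over-smoothed relative to their extent
    smooth_r <- max(2L, round(avg_window_px / 2 / 2^(l - 1)))
    p1 <- poly_expansion(f1, poly_n, poly_sigma)
    p2 <- poly_expansion(f2, poly_n, poly_sigma)
    for (it in seq_len(iterations)) {
      st <- flow_step(p1, p2, dy, dx, smooth_r)
      dy <- st$dy; dx <- st$dx
    }
  }
  r <- max(1L, floor(avg_window_px / 2))
  dy <- box_mean(dy, r); dx <- box_mean(dx, r)
  scale <- pixel_size_nm / 1000 / frame_interval_s
  structure(list(vy = dy * scale, vx = dx * scale,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 params = list(poly_n = poly_n, poly_sigma = poly_sigma,
                               pyramid_levels = pyramid_levels,
                               iterations = iterations,
                               avg_window_px = avg_window_px)),
            class = "er_flow")
}

#' Motion summary over an element's pixels
#'
#' Scalar mean (mean speed irrespective of direction), vector mean (net
#' directed speed), maximum speed, flow coherence (vector mean / scalar
#' mean, 1 for parallel flow and 0 for no net movement) and circular
#' direction statistics.
#'
#' @param flow An `er_flow` (or list with `vy`, `vx`).
#' @param element_pixels Logical matrix or 2-column `(y, x)` index matrix.
#' @return One-row data frame: `scalar_mean`, `vector_mean`, `max_speed`
#'   (micron/s), `coherence`, `mean_direction_deg`, `resultant_length`,
#'   `n_px`.
#' @export
summarize_flow <- function(flow, element_pixels) {
  idx <- if (is.logical(element_pixels)) which(element_pixels)
  else (element_pixels[, 2] - 1) * nrow(flow$vy) + element_pixels[, 1]
  if (!length(idx)) stop("summarize_flow: empty element")
  vy <- flow$vy[idx]; vx <- flow$vx[idx]
  sp <- sqrt(vy^2 + vx^2)
  scalar <- mean(sp)
  vec <- sqrt(mean(vy)^2 + mean(vx)^2)
  coh <- if (scalar > 0) vec / scalar else NA_real_
  dirs <- (atan2(-vy, vx) * 180 / pi) %% 360
  cs <- circ_mean_deg(dirs[sp > 0])
  data.frame(scalar_mean = scalar, vector_mean = vec, max_speed = max(sp),
             coherence = coh,
             mean_direction_deg = if (any(sp > 0)) cs$mean_deg else NA_real_,
             resultant_length = if (any(sp > 0)) cs$resultant else NA_real_,
             n_px = length(idx))
}

#' Divergence and curl of a flow field
#'
#' Central differences of the velocity field, in 1/s; the outermost pixel
#' ring (one-sided differences) is `NA`.
#'
#' @param flow An `er_flow`.
#' @return List of matrices `div` and `curl` (1/s).
#' @export
divergence_curl <- function(flow) {
  stopifnot(nrow(flow$vy) >= 3, ncol(flow$vy) >= 3)
  px_um <- flow$pixel_size_nm / 1000
  ddx <- function(m) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    out[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / (2 * px_um)
    out
  }
  ddy <- function(m) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    out[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / (2 * px_um)
    out
  }
  list(div = ddx(flow$vx) + ddy(flow$vy),
       curl = ddx(flow$vy) - ddy(flow$vx))
}

#' Lognormal fit to a speed distribution
#'
#' Gaussian fit to the log speeds with the back-transformed (geometric)
#' mean; zero speeds are excluded and counted.
#'
#' @param speeds Numeric vector of per-element mean speeds (micron/s).
#' @return List `mu`, `sigma` (log scale), `back_transformed_mean`
#'   (`exp(mu)`), `n`, `n_zero_excluded`.
#' @export
fit_speed_distribution <- function(speeds) {
  zero <- speeds <= 0
  v <- speeds[!zero]
  if (length(v) < 10)
    stop("fit_speed_distribution: need at least 10 positive speeds")
  lg <- log(v)
  mu <- mean(lg); sigma <- stats::sd(lg)
  list(mu = mu, sigma = sigma, back_transformed_mean = exp(mu),
       n = length(v), n_zero_excluded = sum(zero))
}
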