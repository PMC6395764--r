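# Intensity-independent ridge enhancement via phase congruency.
#
# A log-Gabor quadrature filter bank is applied over several spatial scales
# and orientations. At each pixel the local weighted mean phase angle
# ("feature type") is computed from the summed even (real) and odd
# (imaginary) responses: bright ridges sit at +pi/2, step edges at 0, dark
# ridges at -pi/2. Because the angle is a ratio of filter responses it is
# independent of linear intensity rescaling, which is what makes the
# segmentation robust to dim tubules.

log_gabor_bank <- function(ny, nx, n_scales, n_orients,
                           min_wavelength = 3, mult = 2.1,
                           sigma_onf = 0.55, dtheta_sigma = 1.2) {
  fy <- (seq_len(ny) - 1) / ny; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(nx) - 1) / nx; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  u <- matrix(rep(fx, each = ny), ny)
  v <- matrix(rep(fy, times = nx), ny)
  radius <- sqrt(u^2 + v^2); radius[1, 1] <- 1
  theta <- atan2(-v, u)
  sintheta <- sin(theta); costheta <- cos(theta)
  filters <- vector("list", n_scales * n_orients)
  k <- 1L
  for (o in seq_len(n_orients)) {
    angl <- (o - 1) * pi / n_orients
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * (dtheta_sigma * pi / n_orients)^2))
    for (s in seq_len(n_scales)) {
      wl <- min_wavelength * mult^(s - 1)
      f0 <- 1 / wl
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2))
      lg[1, 1] <- 0
      filters[[k]] <- lg * spread
      k <- k + 1L
    }
  }
  filters
}

#' Phase-congruency feature-type image
#'
#' Computes the normalised local weighted mean phase angle over a log-Gabor
#' filter bank. Bright ridge-like features (tubules) map near 1, step edges
#' near 0.5 and dark ridges near 0. Pixels whose total filter amplitude
#' falls below a noise floor (`noise_k` times the median amplitude) are set
#' to zero.
#'
#' @param frame Intensity matrix (non-constant).
#' @param n_scales Number of filter scales (3--5 typical).
#' @param n_orients Number of orientations (4--6 typical).
#' @param noise_k Noise-compensation factor for the amplitude floor.
#' @param min_wavelength,mult Smallest filter wavelength (px) and scale
#'   multiplier of the log-Gabor bank.
#' @return Object of class `er_feature_type`: `ft` in `[0, 1]`, the raw
#'   `amplitude` sum, and the bank geometry.
#' @export
phase_congruency_ft <- function(frame, n_scales = 4, n_orients = 6,
                                noise_k = 2, min_wavelength = 3,
                                mult = 2.1) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (diff(range(frame)) == 0) {
    warning("phase_congruency_ft: constant frame, returning all-zero image")
    return(structure(list(ft = matrix(0, ny, nx),
                          amplitude = matrix(0, ny, nx),
                          scales_used = n_scales, orientations_used = n_orients),
                     class = "er_feature_type"))
  }
  FT <- stats::fft(frame)
  filters <- log_gabor_bank(ny, nx, n_scales, n_orients,
                            min_wavelength = min_wavelength, mult = mult)
  sumE <- matrix(0, ny, nx)   # even (real) responses over all filters
  sumAbsO <- matrix(0, ny, nx)  # magnitude of per-orientation odd sums
  amp <- matrix(0, ny, nx)
  amp_finest <- matrix(0, ny, nx)
  k <- 1L
  for (o in seq_len(n_orients)) {
    Eo <- matrix(0, ny, nx); Oo <- matrix(0, ny, nx)
    for (s in seq_len(n_scales)) {
      resp <- stats::fft(FT * filters[[k]], inverse = TRUE) / (ny * nx)
      e <- Re(resp); od <- Im(resp)
      Eo <- Eo + e; Oo <- Oo + od
      a <- sqrt(e^2 + od^2)
      amp <- amp + a
      if (s == 1) amp_finest <- amp_finest + a
      k <- k + 1L
    }
    sumE <- sumE + Eo
    sumAbsO <- sumAbsO + abs(Oo)
  }
  theta <- atan2(sumE, sumAbsO)          # [-pi/2, pi/2]
  ft <- (theta + pi / 2) / pi            # bright ridges -> ~1
  # Noise floor from the finest-scale amplitude: for pure Gaussian noise the
  # finest-scale amplitudes are Rayleigh-distributed, so their median over
  # the (mostly background) image estimates the noise amplitude; scaled by
  # the number of scales to approximate its contribution to the summed
  # amplitude. The 1e-3 relative term handles noise-free images.
  tau <- stats::median(amp_finest) / sqrt(log(4))
  floor_amp <- max(noise_k * tau * n_scales / 2, 1e-3 * max(amp))
  ft[amp < floor_amp] <- 0
  structure(list(ft = ft, amplitude = amp,
                 scales_used = n_scales, orientations_used = n_orients),
            class = "er_feature_type")
}

#' Hysteresis thresholding and thinning of the feature-type image
#'
#' Shallow local minima (depth at most `hmin`) are zeroed first so closely
#' appressed tubules separated by a faint valley are not merged; pixels at
#' or above `lo` that are 8-connected to a pixel at or above `hi` are kept;
#' the result is thinned to a single-pixel-wide skeleton (Zhang-Suen).
#'
#' @param ft An `er_feature_type` (or matrix in `[0, 1]`).
#' @param lo,hi Lower and upper hysteresis thresholds (`lo < hi`).
#' @param hmin Depth of minima suppressed before thresholding.
#' @return Object of class `er_skeleton` with logical matrix `pixels`.
#' @export
hysteresis_skeleton <- function(ft, lo = 0.3, hi = 0.5, hmin = 0.05) {
  stopifnot(lo < hi)
  z <- if (inherits(ft, "er_feature_type")) ft$ft else ft
  if (hmin > 0 && diff(range(z)) > 0) {
    sm <- shallow_minima_mask(z, hmin)
    z[sm] <- 0
  }
  lab <- label8(z >= lo)
  keep_labels <- unique(lab[z >= hi & lab > 0])
  bin <- matrix(lab %in% keep_labels & lab > 0, nrow(z), ncol(z))
  sk <- thin_connected(bin)
  structure(list(pixels = sk, binary = bin), class = "er_skeleton")
}

#' @export
print.er_skeleton <- function(x, ...) {
  cat(sprintf("ER pixel skeleton: %d skeleton pixels on a %d x %d grid\n",
              sum(x$pixels), nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}
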