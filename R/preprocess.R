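# Resolution standardisation, background removal, edge-preserving smoothing
# and analysis-mask construction.

#' Up-sample a stack so the thinnest tubules span about 5 pixels
#'
#' Linear (bilinear) interpolation by a half-integer factor
#' `f = ceil(5 / fwhm_min_px * 2) / 2`; the pixel size is divided by `f`.
#' `f = 1` returns the stack untouched.
#'
#' @param stack An [er_stack].
#' @param fwhm_min_px FWHM of the thinnest tubules measured on the *input*
#'   grid, in pixels.
#' @return The resampled [er_stack], with an attribute `upsample_factor`.
#' @export
upsample_to_min_fwhm <- function(stack, fwhm_min_px) {
  stopifnot(fwhm_min_px > 0)
  f <- ceiling(5 / fwhm_min_px * 2) / 2
  if (f <= 1) {
    attr(stack, "upsample_factor") <- 1
    return(stack)
  }
  d <- dim(stack$data)
  ny2 <- round(d[1] * f); nx2 <- round(d[2] * f)
  yy <- ( seq_len(ny2) - 0.5) / f + 0.5
  xx <- ( seq_len(nx2) - 0.5) / f + 0.5
  grid_y <- rep(yy, times = nx2); grid_x <- rep(xx, each = ny2)
  out <- array(0, c(ny2, nx2, d[3], d[4]))
  for (t in seq_len(d[4])) for (ch in seq_len(d[3])) {
    out[, , ch, t] <- matrix(bilinear_sample(stack$data[, , ch, t],
                                             grid_y, grid_x), ny2, nx2)
  }
  res <- er_stack(out, pixel_size_nm = stack$pixel_size_nm / f,
                  frame_interval_s = stack$frame_interval_s,
                  bit_depth = stack$bit_depth, max_value = stack$max_value)
  attr(res, "upsample_factor") <- f
  res
}

#' Subtract a background level estimated from a region of interest
#'
#' The mean intensity within the rectangle is computed per channel (pooled
#' over frames) and subtracted, clamping at zero: later stages assume
#' non-negative intensities.
#'
#' @param stack An [er_stack].
#' @param roi Rectangle `c(y, x, h, w)` in 1-based pixels.
#' @return The background-subtracted [er_stack]. The per-channel levels are
#'   attached as attribute `background`.
#' @export
subtract_background <- function(stack, roi) {
  d <- dim(stack$data)
  y <- roi[1]; x <- roi[2]; h <- roi[3]; w <- roi[4]
  if (h < 1 || w < 1) stop("subtract_background: empty roi")
  if (y < 1 || x < 1 || y + h - 1 > d[1] || x + w - 1 > d[2])
    stop("subtract_background: roi outside image")
  bg <- numeric(d[3])
  out <- stack$data
  for (ch in seq_len(d[3])) {
    bg[ch] <- mean(stack$data[y:(y + h - 1), x:(x + w - 1), ch, ])
    out[, , ch, ] <- pmax(stack$data[, , ch, ] - bg[ch], 0)
  }
  res <- stack
  res$data <- out
  attr(res, "background") <- bg
  res
}

#' Edge-preserving guided smoothing
#'
#' A guided filter with the image as its own guide (He et al. box-filter
#' formulation). The kernel size is normally set to the minimum tubule FWHM
#' so smoothing does not blur across tubule edges. The regularisation
#' defaults to `(0.01 x intensity range)^2`.
#'
#' @param stack An [er_stack] (or a plain matrix).
#' @param kernel_px Filter window width in pixels (>= 1).
#' @param eps Regularisation; larger values smooth more aggressively.
#' @return Object of the same type as the input.
#' @export
guided_smooth <- function(stack, kernel_px, eps = NULL) {
  stopifnot(kernel_px >= 1)
  r <- max(1L, floor(kernel_px / 2))
  smooth1 <- function(m) {
    rng <- diff(range(m))
    if (rng == 0) return(m)
    e <- if (is.null(eps)) (0.01 * rng)^2 else eps
    mu <- box_mean(m, r)
    var_m <- box_mean(m * m, r) - mu^2
    a <- var_m / (var_m + e)
    b <- (1 - a) * mu
    box_mean(a, r) * m + box_mean(b, r)
  }
  if (is.matrix(stack)) return(smooth1(stack))
  d <- dim(stack$data)
  out <- stack
  for (t in seq_len(d[4])) for (ch in seq_len(d[3]))
    out$data[, , ch, t] <- smooth1(stack$data[, , ch, t])
  out
}

# Multi-level Otsu thresholds: exhaustive search over a binned histogram for
# the threshold set maximising the between-class variance.
multi_otsu <- function(values, n_partitions, n_bins = 64L) {
  stopifnot(n_partitions %in% 2:4)
  rng <- range(values)
  if (diff(rng) == 0) stop("multi_otsu: constant image")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  cw <- cumsum(p); cm <- cumsum(p * mids)
  between <- function(cuts) {
    # cuts: bin indices of upper class boundaries (exclusive)
    b <- c(0L, cuts, n_bins)
    s <- 0
    for (i in seq_len(length(b) - 1L)) {
      w <- cw[b[i + 1L]] - if (b[i] == 0L) 0 else cw[b[i]]
      if (w <= 0) next
      m <- (cm[b[i + 1L]] - if (b[i] == 0L) 0 else cm[b[i]]) / w
      s <- s + w * m^2
    }
    s
  }
  k <- n_partitions - 1L
  combs <- utils::combn(seq_len(n_bins - 1L), k)
  best <- -Inf; first_tie <- last_tie <- combs[, 1]
  eps <- 1e-12
  for (j in seq_len(ncol(combs))) {
    v <- between(combs[, j])
    if (v > best + eps) {
      best <- v; first_tie <- last_tie <- combs[, j]
    } else if (v > best - eps) {
      last_tie <- combs[, j]   # ties span empty histogram gaps
    }
  }
  best_cuts <- round((first_tie + last_tie) / 2)
  br[best_cuts + 1L]
}

# Fill the convex hull of a set of pixels as a mask (scanline fill of the
# hull polygon, with half-pixel outset so pixel extents are covered).
convex_hull_mask <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(mask)
  corners <- rbind(pts + rep(c(-0.5, -0.5), each = nrow(pts)),
                   pts + rep(c(-0.5,  0.5), each = nrow(pts)),
                   pts + rep(c( 0.5, -0.5), each = nrow(pts)),
                   pts + rep(c( 0.5,  0.5), each = nrow(pts)))
  hull <- corners[grDevices::chull(corners[, 2], corners[, 1]), , drop = FALSE]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- nrow(hull)
  ys <- hull[, 1]; xs <- hull[, 2]
  for (row in seq_len(nrow(mask))) {
    xcross <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- ys[i]; y2 <- ys[j]
      if ((y1 <= row && y2 > row) || (y2 <= row && y1 > row)) {
        xcross <- c(xcross, xs[i] + (row - y1) / (y2 - y1) * (xs[j] - xs[i]))
      }
    }
    if (length(xcross) >= 2) {
      xcross <- sort(xcross)
      for (i in seq(1, length(xcross) - 1, by = 2)) {
        a <- ceiling(xcross[i]); b <- floor(xcross[i + 1])
        if (b >= a) out[row, max(1, a):min(ncol(mask), b)] <- TRUE
      }
    }
  }
  out | mask
}

#' Build the analysis mask for one frame
#'
#' Thresholds the frame at the *lowest* level of a 2--4 level Otsu
#' partition of the intensity histogram, fills internal holes, fits a
#' contracted convex-hull boundary around the foreground, and erodes the
#' final boundary by a fixed number of pixels. The contraction keeps, inside
#' the convex hull, the pixels whose distance to the foreground is at most
#' `shrink` times the largest hull-to-foreground distance, so `shrink = 1`
#' returns the full convex hull and smaller values wrap the boundary onto
#' the irregular outline.
#'
#' @param frame Intensity matrix.
#' @param n_partitions Number of Otsu histogram classes (2, 3 or 4).
#' @param shrink Hull contraction factor in `[0, 1]`.
#' @param erode_px Final boundary erosion in pixels (typically 4--6).
#' @return An object of class `er_mask`: `region` (logical matrix of the
#'   analysed area, holes filled), `foreground` (thresholded pixels within
#'   the region), `threshold`, `area_um2` is computed by the caller via
#'   [mask_area_um2] once a pixel size is known.
#' @export
build_mask <- function(frame, n_partitions = 2, shrink = 0.7, erode_px = 4) {
  stopifnot(erode_px >= 0)
  thr <- multi_otsu(as.vector(frame), n_partitions)[1]
  fg <- frame >= thr
  if (!any(fg)) stop("build_mask: empty foreground at threshold ", signif(thr, 4))
  filled <- EBImage::fillHull(fg) > 0
  hull <- convex_hull_mask(filled)
  d_fg <- EBImage::distmap(!filled)       # distance of each px to foreground
  dmax <- max(d_fg[hull])
  region <- hull & (d_fg <= shrink * max(dmax, 1e-9))
  region <- filled | region
  if (erode_px > 0) region <- erode_disc(region, erode_px)
  region <- EBImage::fillHull(region) > 0
  structure(list(region = region, foreground = fg & region, threshold = thr,
                 holes = region & !fg),
            class = "er_mask")
}

#' Mask area in square microns
#' @param mask An `er_mask` (or logical matrix).
#' @param pixel_size_nm Pixel size in nm.
#' @export
mask_area_um2 <- function(mask, pixel_size_nm) {
  region <- if (inherits(mask, "er_mask")) mask$region else mask
  sum(region) * (pixel_size_nm / 1000)^2
}
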