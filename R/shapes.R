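# Region shape descriptors in physical units.

# Closed-contour perimeter: the 8-connected outer contour is traced by
# EBImage::ocontour and smoothed with a short circular moving average to
# remove pixelation staircase, so a rasterised disc approaches its true
# circumference (circularity -> 1).
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  total <- 0
  for (ct in oc) {
    if (nrow(ct) < 3) next
    n <- nrow(ct); w <- 2L
    sm <- ct
    for (k in 1:2) {
      idx <- function(off) ((seq_len(n) - 1 + off) %% n) + 1
      sm <- (sm[idx(-1), , drop = FALSE] + sm + sm[idx(1), , drop = FALSE]) / 3
    }
    d <- sqrt(rowSums((sm - sm[c(2:n, 1), , drop = FALSE])^2))
    total <- total + sum(d)
  }
  total
}

polygon_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}
polygon_perim <- function(pts) {
  n <- nrow(pts)
  sum(sqrt(rowSums((pts - pts[c(2:n, 1), , drop = FALSE])^2)))
}

# Convex hull of the pixel *corners* of a region, so a filled n x n square
# has hull area exactly n^2 px.
hull_of_pixels <- function(pts) {
  corners <- rbind(pts + rep(c(-0.5, -0.5), each = nrow(pts)),
                   pts + rep(c(-0.5,  0.5), each = nrow(pts)),
                   pts + rep(c( 0.5, -0.5), each = nrow(pts)),
                   pts + rep(c( 0.5,  0.5), each = nrow(pts)))
  corners[grDevices::chull(corners[, 2], corners[, 1]), , drop = FALSE]
}

#' Shape metrics of a labelled region
#'
#' Area, perimeter (smoothed polygonal contour length), major and minor
#' axis of the best-fit ellipse (from second moments), solidity
#' (area / convex area), elongation (`1 - minor/major`), circularity
#' (`4 pi area / perimeter^2`) and roughness (perimeter / convex
#' perimeter), all in physical units. Axis metrics of a single-pixel region
#' are undefined and returned as `NaN`.
#'
#' @param mask Logical matrix selecting the region pixels.
#' @param pixel_size_nm Pixel size in nm.
#' @param frame Optional intensity matrix for intensity statistics.
#' @return One-row data frame of metrics.
#' @export
shape_metrics <- function(mask, pixel_size_nm, frame = NULL) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("shape_metrics: empty region")
  um <- pixel_size_nm / 1000
  area_px <- nrow(pts)
  out <- data.frame(area_um2 = area_px * um^2,
                    centroid_y = mean(pts[, 1]), centroid_x = mean(pts[, 2]))
  if (area_px == 1) {
    out <- cbind(out, data.frame(
      perimeter_um = 4 * um, major_um = NaN, minor_um = NaN,
      solidity = 1, elongation = NaN, circularity = NaN, roughness = 1))
  } else {
    per_px <- contour_perimeter(mask)
    hull <- hull_of_pixels(pts)
    hull_area <- polygon_area(hull)
    hull_per <- polygon_perim(hull)
    cv <- stats::cov(pts) + diag(1 / 12, 2)  # pixel quantisation variance
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    major <- 4 * sqrt(max(ev[1], 0)); minor <- 4 * sqrt(max(ev[2], 0))
    out <- cbind(out, data.frame(
      perimeter_um = per_px * um,
      major_um = major * um, minor_um = minor * um,
      solidity = min(1, area_px / hull_area),
      elongation = 1 - minor / major,
      # capped at 1: contour smoothing can underestimate the perimeter of
      # small near-circular regions by a few percent
      circularity = min(1, 4 * pi * area_px / per_px^2),
      roughness = max(1, per_px / hull_per)))
  }
  if (!is.null(frame)) {
    v <- frame[mask]
    out$mean_intensity <- mean(v)
    out$sd_intensity <- stats::sd(v)
    out$max_intensity <- max(v)
  }
  out
}
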