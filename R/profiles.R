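# Variation in morphology along tubules: integrated-intensity traces,
# bulge/constriction detection, dual-channel ratios, and radial intensity
# profiles across cisternal boundaries.

#' Intensity trace along a tubule edge
#'
#' At each pixel of the edge's path the intensity is integrated along the
#' local normal (tangent estimated from a +/-2 px window of the path), for
#' each channel. Path pixels within the node-exclusion zones at either end
#' are removed.
#'
#' @param g An `er_graph`.
#' @param edge_id Edge to trace.
#' @param frames A matrix or list of matrices (one per channel).
#' @param normal_halfwidth_px Half-width of the normal integration window.
#' @param node_exclude_px Arc length excluded at each end (default the
#'   normal half-width).
#' @return Object of class `er_trace`: `position_um` (strictly increasing
#'   arc length), `intensity` (positions x channels matrix), `edge_id`,
#'   and the `(y, x)` sample coordinates.
#' @export
extract_trace <- function(g, edge_id, frames, normal_halfwidth_px = 5,
                          node_exclude_px = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  i <- match(edge_id, g$edges$id)
  path <- g$paths[[i]]
  if (is.null(path) || nrow(path) < 3)
    stop("extract_trace: edge path too short")
  if (is.null(node_exclude_px)) node_exclude_px <- normal_halfwidth_px
  steps <- sqrt(rowSums(diff(path)^2))
  arc <- c(0, cumsum(steps))
  keep <- arc > node_exclude_px & arc < max(arc) - node_exclude_px
  if (!any(keep)) keep <- rep(TRUE, nrow(path))
  path <- path[keep, , drop = FALSE]
  arc <- arc[keep]
  n <- nrow(path)
  offs <- seq(-normal_halfwidth_px, normal_halfwidth_px, by = 0.5)
  inten <- matrix(0, n, length(frames))
  for (j in seq_len(n)) {
    a <- max(1, j - 2); b <- min(n, j + 2)
    tang <- path[b, ] - path[a, ]
    nt <- sqrt(sum(tang^2))
    tang <- if (nt > 0) tang / nt else c(0, 1)
    nrm <- c(-tang[2], tang[1])
    ys <- path[j, 1] + offs * nrm[1]
    xs <- path[j, 2] + offs * nrm[2]
    for (ch in seq_along(frames))
      inten[j, ch] <- sum(bilinear_sample(frames[[ch]], ys, xs)) * 0.5
  }
  um <- g$pixel_size_nm / 1000
  structure(list(edge_id = edge_id, position_um = arc * um,
                 intensity = inten, path = path),
            class = "er_trace")
}

# Local maxima with height and prominence thresholds. Prominence of a peak
# is its height above the higher of the two deepest valleys separating it
# from larger peaks (standard topographic definition).
find_peaks_1d <- function(x, min_height = -Inf, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    left_min <- x[i]; j <- i
    while (j > 1 && x[j] <= x[i]) { left_min <- min(left_min, x[j]); j <- j - 1 }
    if (x[j] <= x[i]) left_min <- min(left_min, min(x[1:i]))
    right_min <- x[i]; j <- i
    while (j < n && x[j] <= x[i]) { right_min <- min(right_min, x[j]); j <- j + 1 }
    if (x[j] <= x[i]) right_min <- min(right_min, min(x[i:n]))
    prom <- x[i] - max(left_min, right_min)
    keep[k] <- prom >= min_prominence
  }
  cand[keep]
}

#' Detect bulges and constrictions along a trace
#'
#' Peaks must be at least `height_frac` of the trace maximum high and
#' `prominence_frac` of the maximum more intense than the signal on either
#' side; constrictions (troughs) are found by the same rule on the
#' inverted trace. Both thresholds are fractions of the maximum, so event
#' counts are invariant to uniform intensity scaling.
#'
#' @param trace An `er_trace`.
#' @param height_frac,prominence_frac Thresholds as fractions of the trace
#'   maximum (defaults 0.05 and 0.03).
#' @param channel Channel to analyse.
#' @param widthmap Optional `er_widthmap`; event tubule widths are sampled
#'   from the granulometry width image at the event positions.
#' @return Object of class `er_peaks`: data frame `events` (kind, index,
#'   `position_um`, height, prominence, `width_nm`), per-trace densities
#'   (events per micron) and mean spacings.
#' @export
find_peaks_troughs <- function(trace, height_frac = 0.05,
                               prominence_frac = 0.03, channel = 1L,
                               widthmap = NULL) {
  x <- trace$intensity[, channel]
  stopifnot(length(x) >= 3)
  mx <- max(x)
  events <- data.frame(kind = character(0), index = integer(0),
                       position_um = numeric(0), height = numeric(0),
                       prominence = numeric(0), width_nm = numeric(0))
  if (mx > 0) {
    wm_lookup <- function(idx) {
      if (is.null(widthmap)) return(rep(NA_real_, length(idx)))
      vapply(idx, function(i) {
        p <- trace$path[i, ]
        d2 <- (widthmap$table$y - p[1])^2 + (widthmap$table$x - p[2])^2
        j <- which.min(d2)
        if (length(j) && d2[j] <= 25) 2 * widthmap$table$calibrated_radius_nm[j]
        else NA_real_
      }, numeric(1))
    }
    prom_of <- function(x, i) {
      n <- length(x)
      left <- min(x[1:i]); right <- min(x[i:n])
      j <- i; lm <- x[i]
      while (j > 1 && x[j] <= x[i]) { lm <- min(lm, x[j]); j <- j - 1 }
      if (x[j] <= x[i]) lm <- left
      j <- i; rm <- x[i]
      while (j < n && x[j] <= x[i]) { rm <- min(rm, x[j]); j <- j + 1 }
      if (x[j] <= x[i]) rm <- right
      x[i] - max(lm, rm)
    }
    pk <- find_peaks_1d(x, min_height = height_frac * mx,
                        min_prominence = prominence_frac * mx)
    if (length(pk))
      events <- rbind(events, data.frame(
        kind = "peak", index = pk, position_um = trace$position_um[pk],
        height = x[pk], prominence = vapply(pk, function(i) prom_of(x, i),
                                            numeric(1)),
        width_nm = wm_lookup(pk)))
    inv <- mx - x
    tr <- find_peaks_1d(inv, min_height = height_frac * mx,
                        min_prominence = prominence_frac * mx)
    if (length(tr))
      events <- rbind(events, data.frame(
        kind = "trough", index = tr, position_um = trace$position_um[tr],
        height = x[tr], prominence = vapply(tr, function(i) prom_of(inv, i),
                                            numeric(1)),
        width_nm = wm_lookup(tr)))
  }
  events <- events[order(events$index), , drop = FALSE]
  rownames(events) <- NULL
  span <- diff(range(trace$position_um))
  dens <- function(kind) {
    k <- sum(events$kind == kind)
    if (span > 0) k / span else NA_real_
  }
  spacing <- function(kind) {
    p <- events$position_um[events$kind == kind]
    if (length(p) >= 2) mean(diff(p)) else NA_real_
  }
  structure(list(events = events,
                 peak_density_per_um = dens("peak"),
                 trough_density_per_um = dens("trough"),
                 peak_spacing_um = spacing("peak"),
                 trough_spacing_um = spacing("trough")),
            class = "er_peaks")
}

#' Dual-channel ratio and cross-channel correlation along an edge
#'
#' Reports the per-event intensity ratio (channel 1 / channel 2) and the
#' Pearson correlation between the two aligned traces; an anti-phase
#' relation between markers shows up as negative correlation.
#'
#' @param trace An `er_trace` with two channels.
#' @param events An `er_peaks` (events indexed into the trace).
#' @return List with `ratio` per event (`NaN` flagged on zero denominator)
#'   and `correlation`.
#' @export
dual_channel_ratio <- function(trace, events) {
  stopifnot(ncol(trace$intensity) >= 2)
  x1 <- trace$intensity[, 1]; x2 <- trace$intensity[, 2]
  idx <- events$events$index
  ratio <- x1[idx] / x2[idx]
  ratio[!is.finite(ratio)] <- NaN
  corr <- if (stats::sd(x1) > 0 && stats::sd(x2) > 0)
    stats::cor(x1, x2) else NA_real_
  list(ratio = ratio, correlation = corr)
}

#' Radial intensity profile across a cisternal boundary
#'
#' Mean intensity in signed integer distance bins from the region edge
#' (Euclidean distance transform): bin 0 is the innermost boundary ring,
#' negative bins are deeper interior rings and positive bins lie outside.
#'
#' @param region Logical matrix (one cisterna).
#' @param frame Intensity matrix.
#' @param n_bins Number of bins on each side.
#' @return Data frame `bin`, `mean_intensity`, `n_pixels`.
#' @export
boundary_profile <- function(region, frame, n_bins = 10L) {
  stopifnot(any(region))
  d_in <- EBImage::distmap(region)     # >= 1 inside, 0 outside
  d_out <- EBImage::distmap(!region)
  bins <- (-n_bins):n_bins
  out <- data.frame(bin = bins, mean_intensity = NA_real_, n_pixels = 0L)
  for (b in bins) {
    sel <- if (b <= 0) region & (ceiling(d_in) == 1 - b)
    else !region & (ceiling(d_out) == b)
    out$n_pixels[out$bin == b] <- sum(sel)
    if (any(sel)) out$mean_intensity[out$bin == b] <- mean(frame[sel])
  }
  out
}

#' Aggregate boundary profiles over a cisterna set
#'
#' @param cisternae An `er_cisternae`.
#' @param frame Intensity matrix.
#' @param n_bins Bins each side of the boundary.
#' @return Data frame `bin`, `mean_intensity`, `sd_intensity` across
#'   cisternae.
#' @export
boundary_profiles <- function(cisternae, frame, n_bins = 10L) {
  ids <- cisternae$table$id
  if (!length(ids)) stop("boundary_profiles: no cisternae")
  profs <- vapply(ids, function(id)
    boundary_profile(cisternae$labels == id, frame, n_bins)$mean_intensity,
    numeric(2 * n_bins + 1))
  profs <- matrix(profs, nrow = 2 * n_bins + 1)
  data.frame(bin = (-n_bins):n_bins,
             mean_intensity = rowMeans(profs, na.rm = TRUE),
             sd_intensity = apply(profs, 1, stats::sd, na.rm = TRUE))
}
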