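# Persistency mapping of static elements: intensity-based and
# structure-based per-pixel occupancy maps, persistent-node detection, and
# persistency distributions.

#' Intensity-based persistency map
#'
#' For each frame pair separated by `lag_frames`, the absolute intensity
#' difference is masked by the Boolean AND of the two thresholded binary
#' images; pixels with a low difference inside the AND mask count as
#' persistent. The per-pixel score is the fraction of frame pairs in which
#' the pixel was persistent, reported over the OR of the occupancy across
#' all frames (the total segmented area).
#'
#' @param stack An [er_stack].
#' @param lag_frames Lag between compared frames (must be < n frames).
#' @param channel Channel to analyse.
#' @param diff_tol Maximum intensity difference (fraction of the stack
#'   maximum) for a pixel to count as persistent.
#' @return Object of class `er_persistency`: `score` in `[0, 1]`,
#'   `seconds` (score times the lag duration), logical `occupancy` (OR
#'   mask), and the parameters.
#' @export
intensity_persistency <- function(stack, lag_frames = 12L, channel = 1L,
                                  diff_tol = 0.2) {
  nt <- n_frames(stack)
  if (lag_frames >= nt)
    stop("intensity_persistency: lag_frames must be < number of frames")
  frames <- lapply(seq_len(nt), function(t) get_frame(stack, t, channel))
  thr <- vapply(frames, function(f)
    tryCatch(multi_otsu(as.vector(f), 2)[1], error = function(e) Inf),
    numeric(1))
  bins <- lapply(seq_len(nt), function(t) frames[[t]] >= thr[t])
  occupancy <- Reduce(`|`, bins)
  mx <- max(vapply(frames, max, numeric(1)))
  count <- matrix(0, nrow(frames[[1]]), ncol(frames[[1]]))
  n_pairs <- nt - lag_frames
  for (t in seq_len(n_pairs)) {
    m_and <- bins[[t]] & bins[[t + lag_frames]]
    d <- abs(frames[[t]] - frames[[t + lag_frames]])
    count <- count + (m_and & (d <= diff_tol * mx))
  }
  score <- count / n_pairs
  score[!occupancy] <- 0
  lag_s <- lag_frames * stack$frame_interval_s
  structure(list(score = score, seconds = score * lag_s,
                 occupancy = occupancy, lag_frames = lag_frames,
                 lag_s = lag_s, mode = "intensity"),
            class = "er_persistency")
}

#' Structure-based persistency map
#'
#' Binary skeleton and cisterna masks per frame are dilated by
#' `FWHM_min / 2` and either summed over the time window (graded per-pixel
#' occupancy counts) or differenced between the start and end of the
#' window (binary estimate: present at both endpoints).
#'
#' @param skeletons List of logical skeleton masks (one per frame), or
#'   `er_skeleton` objects.
#' @param cisterna_masks Optional list of logical cisterna masks.
#' @param dilate_px Dilation radius (default `round(fwhm_min / 2)`).
#' @param window Number of frames analysed (default all).
#' @param mode `"sum"` or `"diff"`.
#' @param frame_interval_s Frame interval for the seconds conversion.
#' @return Object of class `er_persistency` with `tubule` and `cisterna`
#'   occupancy maps (counts for `"sum"`, logical for `"diff"`), and
#'   `tubule_s` / `cisterna_s` in seconds.
#' @export
structure_persistency <- function(skeletons, cisterna_masks = NULL,
                                  dilate_px = 2.5, window = NULL,
                                  mode = c("sum", "diff"),
                                  frame_interval_s = 0.41) {
  mode <- match.arg(mode)
  skeletons <- lapply(skeletons, function(s)
    if (inherits(s, "er_skeleton")) s$pixels else s)
  nt <- length(skeletons)
  if (is.null(window)) window <- nt
  stopifnot(window <= nt, window >= 1)
  dil <- function(m) dilate_disc(m, dilate_px)
  sks <- lapply(skeletons[seq_len(window)], dil)
  cms <- if (!is.null(cisterna_masks))
    lapply(cisterna_masks[seq_len(window)], dil) else NULL
  agg <- function(masks) {
    if (mode == "sum") Reduce(`+`, lapply(masks, `+`, 0))
    else masks[[1]] & masks[[length(masks)]]
  }
  tub <- agg(sks)
  cis <- if (!is.null(cms)) agg(cms) else NULL
  to_s <- function(m) {
    if (is.null(m)) return(NULL)
    if (mode == "sum") m * frame_interval_s
    else (m + 0) * window * frame_interval_s
  }
  structure(list(tubule = tub, cisterna = cis,
                 tubule_s = to_s(tub), cisterna_s = to_s(cis),
                 mode = mode, window = window, dilate_px = dilate_px,
                 frame_interval_s = frame_interval_s),
            class = "er_persistency")
}

#' Detect persistent nodes over a time course
#'
#' A 1-D median filter in time over the whole time course suppresses
#' transient structures; the temporal median image is then smoothed in xy
#' with a Gaussian of `sigma_px` (FWHM_min / 2), normalised to `[0, 1]`,
#' and the positions of local maxima above `threshold` (0.3--0.5)
#' returned with their scores.
#'
#' @param stack An [er_stack] with >= 3 frames.
#' @param sigma_px Spatial smoothing sigma in pixels.
#' @param threshold Normalised intensity threshold.
#' @param channel Channel to analyse.
#' @return Data frame `y`, `x` (px), `score`, sorted by decreasing score.
#' @export
persistent_nodes <- function(stack, sigma_px = 2.5, threshold = 0.4,
                             channel = 1L) {
  nt <- n_frames(stack)
  if (nt < 3) stop("persistent_nodes: need at least 3 frames")
  arr <- stack$data[, , channel, ]
  med <- apply(arr, c(1, 2), stats::median)
  sm <- gauss_blur(med, sigma_px)
  rng <- range(sm)
  if (diff(rng) == 0) return(data.frame(y = numeric(0), x = numeric(0),
                                        score = numeric(0)))
  nm <- (sm - rng[1]) / diff(rng)
  is_max <- nm >= max3(nm) & nm >= threshold
  if (!any(is_max)) return(data.frame(y = numeric(0), x = numeric(0),
                                      score = numeric(0)))
  lab <- label8(is_max)
  out <- do.call(rbind, lapply(seq_len(max(lab)), function(l) {
    pts <- which(lab == l, arr.ind = TRUE)
    data.frame(y = mean(pts[, 1]), x = mean(pts[, 2]),
               score = max(nm[lab == l]))
  }))
  out[order(-out$score), , drop = FALSE]
}

#' Persistency distribution over elements
#'
#' Normalised probability density histogram of per-element mean
#' persistency (seconds); the density integrates to 1.
#'
#' @param values Per-element mean persistency values (seconds).
#' @param breaks Number of bins or break vector (as in [hist]).
#' @return Data frame `mid`, `density`, `counts`.
#' @export
persistency_histogram <- function(values, breaks = 20) {
  stopifnot(length(values) >= 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, counts = h$counts)
}

#' Mean persistency per graph element
#'
#' Samples a structure persistency map (sum mode, seconds) along edge
#' pixel paths, over node discs, or over cisterna labels.
#'
#' @param g An `er_graph`.
#' @param pers An `er_persistency` from [structure_persistency].
#' @param node_radius_px Sampling disc radius for nodes.
#' @return `g` with `persistency_s` columns on edges and nodes.
#' @export
graph_persistency <- function(g, pers, node_radius_px = 2.5) {
  m <- pers$tubule_s
  ne <- nrow(g$edges)
  g$edges$persistency_s <- vapply(seq_len(ne), function(i) {
    p <- g$paths[[i]]
    if (!nrow(p)) return(NA_real_)
    mean(m[cbind(pmin(p[, 1], nrow(m)), pmin(p[, 2], ncol(m)))])
  }, numeric(1))
  nn <- nrow(g$nodes)
  g$nodes$persistency_s <- vapply(seq_len(nn), function(i) {
    y0 <- round(g$nodes$y[i]); x0 <- round(g$nodes$x[i])
    ys <- max(1, y0 - node_radius_px):min(nrow(m), y0 + node_radius_px)
    xs <- max(1, x0 - node_radius_px):min(ncol(m), x0 + node_radius_px)
    mean(m[ys, xs])
  }, numeric(1))
  g
}
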