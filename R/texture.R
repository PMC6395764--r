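# Grey-level co-occurrence texture metrics for cisternal sub-structure.

glcm_offsets <- function(d) {
  rbind(c(0, d),    # E
        c(-d, 0),   # N
        c(-d, d),   # NE
        c(-d, -d))  # NW
}

#' Build a grey-level co-occurrence matrix over a region
#'
#' Pixel pairs at the given offset distance are accumulated over four
#' directions (NW, N, NE, E) and their symmetric counterparts, so the
#' result is orientation-invariant and symmetric. Intensities are grouped
#' into `n_bins` fixed bins spanning the full intensity range of the study
#' (`intensity_range`), not the per-region range, to keep metrics
#' comparable across images collected under identical conditions. Pairs
#' with either member outside the region are dropped.
#'
#' @param region Logical matrix selecting the region (>= 2 pixels).
#' @param frame Intensity matrix.
#' @param distance_px Offset distance in pixels (set to the minimum tubule
#'   radius to reveal texture from appressed tubules).
#' @param n_bins Number of intensity bins (default 32).
#' @param intensity_range Full-scale range, default `c(0, max-value of the
#'   bit depth)`; pass the stack's `max_value`.
#' @return Object of class `er_glcm`: `p` (n_bins x n_bins probabilities),
#'   `n_pairs`, `n_bins`, `distance_px`.
#' @export
build_glcm <- function(region, frame, distance_px = 1L, n_bins = 32L,
                       intensity_range = c(0, 1)) {
  stopifnot(sum(region) >= 2, n_bins >= 2, distance_px >= 1)
  rng <- diff(intensity_range)
  if (rng <= 0) stop("build_glcm: invalid intensity range")
  bin <- pmin(pmax(floor((frame - intensity_range[1]) / rng * n_bins), 0),
              n_bins - 1) + 1L
  acc <- matrix(0, n_bins, n_bins)
  n_pairs <- 0
  for (k in seq_len(nrow(glcm_offsets(distance_px)))) {
    off <- glcm_offsets(distance_px)[k, ]
    reg2 <- mat_shift(region, -off[1], -off[2], FALSE)
    sel <- region & reg2
    if (!any(sel)) next
    i <- bin[sel]
    b2 <- mat_shift(bin, -off[1], -off[2], 0L)
    j <- b2[sel]
    tab <- table(factor(i, levels = 1:n_bins), factor(j, levels = 1:n_bins))
    acc <- acc + tab + t(tab)   # symmetric counterpart
    n_pairs <- n_pairs + 2 * sum(tab)
  }
  if (n_pairs == 0) stop("build_glcm: no valid pixel pairs in region")
  structure(list(p = acc / sum(acc), n_pairs = n_pairs, n_bins = n_bins,
                 distance_px = distance_px, symmetric = TRUE),
            class = "er_glcm")
}

#' Texture metrics of a co-occurrence matrix
#'
#' Contrast `sum |i-j|^2 p(i,j)` (normalised by `(n_bins - 1)^2` so it lies
#' in `[0, 1]`), correlation `sum (i - mu_i)(j - mu_j) p(i,j) / (s_i s_j)`,
#' energy `sum p(i,j)^2` and homogeneity `sum p(i,j) / (1 + |i-j|)`.
#' Correlation is undefined (`NaN`) for a constant region (`s_i = 0`).
#'
#' @param glcm An `er_glcm`.
#' @return Data frame with `contrast_norm`, `correlation`, `energy`,
#'   `homogeneity`, `n_pairs`.
#' @export
glcm_metrics <- function(glcm) {
  p <- glcm$p
  nb <- glcm$n_bins
  i <- matrix(rep(seq_len(nb), nb), nb)
  j <- t(i)
  contrast <- sum(abs(i - j)^2 * p) / (nb - 1)^2
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  correlation <- if (s_i > 0 && s_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else NaN
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  data.frame(contrast_norm = contrast, correlation = correlation,
             energy = energy, homogeneity = homogeneity,
             n_pairs = glcm$n_pairs)
}

#' Aggregate texture metrics over a cisterna set
#'
#' `per_cisterna_mean` computes the metrics per cisterna and averages them;
#' `pooled` accumulates a single GLCM over all cisternae, which weights
#' each cisterna by its number of pixel pairs.
#'
#' @param cisternae An `er_cisternae` (>= 1 region).
#' @param frame Intensity matrix.
#' @param mode `"per_cisterna_mean"` or `"pooled"`.
#' @param distance_px Offset distance (minimum tubule radius, px).
#' @param n_bins Intensity bins.
#' @param intensity_range Full-scale intensity range.
#' @return One-row data frame of metrics (plus `per_cisterna` attribute for
#'   the per-region table in mean mode).
#' @export
aggregate_textures <- function(cisternae, frame,
                               mode = c("per_cisterna_mean", "pooled"),
                               distance_px = 1L, n_bins = 32L,
                               intensity_range = c(0, 1)) {
  mode <- match.arg(mode)
  ids <- cisternae$table$id
  if (!length(ids)) stop("aggregate_textures: no cisternae")
  gs <- lapply(ids, function(id)
    build_glcm(cisternae$labels == id, frame, distance_px, n_bins,
               intensity_range))
  if (mode == "pooled") {
    tot_pairs <- sum(vapply(gs, `[[`, numeric(1), "n_pairs"))
    pooled_p <- Reduce(`+`, lapply(gs, function(g) g$p * g$n_pairs)) / tot_pairs
    pooled <- structure(list(p = pooled_p, n_pairs = tot_pairs,
                             n_bins = n_bins, distance_px = distance_px,
                             symmetric = TRUE), class = "er_glcm")
    return(glcm_metrics(pooled))
  }
  per <- do.call(rbind, lapply(gs, glcm_metrics))
  out <- data.frame(contrast_norm = mean(per$contrast_norm),
                    correlation = mean(per$correlation, na.rm = TRUE),
                    energy = mean(per$energy),
                    homogeneity = mean(per$homogeneity),
                    n_pairs = sum(per$n_pairs))
  attr(out, "per_cisterna") <- cbind(data.frame(id = ids), per)
  out
}
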