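# Segmentation of sheet-like cisternae and of the polygonal regions
# enclosed by the network.

# Contract a candidate region boundary onto the intensity profile: boundary
# pixels whose intensity falls below half the region's bright reference
# level are peeled iteratively (edge-based active contour with a
# contraction bias), until the boundary is stable or `max_iter` is reached.
refine_region_contour <- function(region, frame, max_iter = 100L) {
  core <- erode_disc(region, 2)
  ref <- if (any(core)) stats::quantile(frame[core], 0.9) else max(frame[region])
  level <- 0.5 * ref
  cur <- region
  for (i in seq_len(max_iter)) {
    interior <- erode_disc(cur, 1)
    boundary <- cur & !interior
    drop <- boundary & (frame < level)
    if (!any(drop)) break
    cur <- cur & !drop
    if (!any(cur)) break
  }
  cur
}

#' Segment cisternae from an intensity frame
#'
#' Morphological opening with a disc of diameter `fwhm_max_px` removes all
#' tubular structures; the remaining sheet-like candidates are thresholded
#' (Otsu), their boundaries shrunk back onto the intensity profile by an
#' edge-based active contour, and regions smaller than `min_area_um2`
#' discarded. Sub-threshold bright regions between one junction and the
#' area cut-off are returned as candidate puncta for the network graph.
#'
#' @param frame Background-subtracted intensity matrix.
#' @param skeleton Optional `er_skeleton` (only used to exclude puncta that
#'   sit directly on the skeleton from double counting; may be `NULL`).
#' @param fwhm_max_px Maximum tubule FWHM in pixels (opening diameter).
#' @param min_area_um2 Minimum cisterna area in square microns.
#' @param pixel_size_nm Pixel size in nm.
#' @param mask Optional `er_mask` restricting the analysis.
#' @return Object of class `er_cisternae`: integer `labels` matrix
#'   (0 = background), per-cisterna `table` of shape and intensity metrics,
#'   and a `puncta` data frame of centroids.
#' @export
segment_cisternae <- function(frame, skeleton = NULL, fwhm_max_px = 10,
                              min_area_um2 = 0.3, pixel_size_nm = 40,
                              mask = NULL) {
  um <- pixel_size_nm / 1000
  ny <- nrow(frame); nx <- ncol(frame)
  empty <- function() structure(
    list(labels = matrix(0L, ny, nx),
         table = cisterna_table_schema(),
         puncta = data.frame(y = numeric(0), x = numeric(0),
                             area_um2 = numeric(0))),
    class = "er_cisternae")
  opened <- gray_open(frame, disc_brush(fwhm_max_px / 2))
  if (!is.null(mask)) opened[!mask$region] <- 0
  if (max(opened) < 0.08 * max(frame)) return(empty())
  thr <- tryCatch(multi_otsu(as.vector(opened), 2), error = function(e) Inf)[1]
  cand <- opened >= max(thr, 0.08 * max(frame))
  if (!any(cand)) return(empty())
  lab0 <- label8(dilate_disc(cand, 1))
  labels <- matrix(0L, ny, nx)
  rows <- list(); puncta <- list()
  next_id <- 1L
  for (l in seq_len(max(lab0))) {
    reg <- lab0 == l
    reg <- refine_region_contour(reg, frame)
    if (!any(reg)) next
    area <- sum(reg) * um^2
    if (area >= min_area_um2) {
      labels[reg] <- next_id
      m <- shape_metrics(reg, pixel_size_nm, frame)
      m <- cbind(data.frame(id = next_id), m)
      rows[[length(rows) + 1]] <- m
      next_id <- next_id + 1L
    } else if (sum(reg) >= 4) {
      pts <- which(reg, arr.ind = TRUE)
      puncta[[length(puncta) + 1]] <-
        data.frame(y = mean(pts[, 1]), x = mean(pts[, 2]), area_um2 = area)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else cisterna_table_schema()
  pc <- if (length(puncta)) do.call(rbind, puncta) else
    data.frame(y = numeric(0), x = numeric(0), area_um2 = numeric(0))
  structure(list(labels = labels, table = tab, puncta = pc),
            class = "er_cisternae")
}

cisterna_table_schema <- function() {
  data.frame(id = integer(0), area_um2 = numeric(0), centroid_y = numeric(0),
             centroid_x = numeric(0), perimeter_um = numeric(0),
             major_um = numeric(0), minor_um = numeric(0),
             solidity = numeric(0), elongation = numeric(0),
             circularity = numeric(0), roughness = numeric(0),
             mean_intensity = numeric(0), sd_intensity = numeric(0),
             max_intensity = numeric(0))
}

#' @export
print.er_cisternae <- function(x, ...) {
  cat(sprintf("ER cisterna set: %d cisternae, %d puncta\n",
              nrow(x$table), nrow(x$puncta)))
  invisible(x)
}

#' Segment enclosed polygonal regions
#'
#' Polygonal regions are the connected components (4-connectivity, the
#' complement of the 8-connected skeleton) of the analysis mask minus the
#' skeleton and the cisternae, excluding any component that touches the
#' mask boundary (those are not fully enclosed by the network).
#'
#' @param skeleton An `er_skeleton`.
#' @param cisternae An `er_cisternae` (or `NULL`).
#' @param mask An `er_mask` (or logical matrix).
#' @param pixel_size_nm Pixel size in nm.
#' @return Object of class `er_polygons`: integer `labels` matrix and a
#'   per-polygon `table` of shape metrics.
#' @export
segment_polygons <- function(skeleton, cisternae, mask, pixel_size_nm = 40) {
  region <- if (inherits(mask, "er_mask")) mask$region else mask
  occ <- skeleton$pixels
  if (!is.null(cisternae)) occ <- occ | (cisternae$labels > 0)
  open_space <- region & !occ
  lab <- EBImage::bwlabel(open_space)
  # components touching the region boundary are not enclosed
  outside <- !region
  touch <- mat_shift(outside, 1, 0, TRUE) | mat_shift(outside, -1, 0, TRUE) |
    mat_shift(outside, 0, 1, TRUE) | mat_shift(outside, 0, -1, TRUE)
  bad <- unique(lab[lab > 0 & (touch | outside)])
  labels <- matrix(0L, nrow(region), ncol(region))
  rows <- list(); next_id <- 1L
  for (l in setdiff(seq_len(max(lab)), bad)) {
    reg <- lab == l
    if (!any(reg)) next
    labels[reg] <- next_id
    m <- shape_metrics(reg, pixel_size_nm)
    rows[[length(rows) + 1]] <- cbind(data.frame(id = next_id), m)
    next_id <- next_id + 1L
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    cisterna_table_schema()[, c("id", "area_um2", "centroid_y", "centroid_x",
                                "perimeter_um", "major_um", "minor_um",
                                "solidity", "elongation", "circularity",
                                "roughness")]
  structure(list(labels = labels, table = tab), class = "er_polygons")
}

#' @export
print.er_polygons <- function(x, ...) {
  cat(sprintf("ER polygonal regions: %d enclosed polygons\n", nrow(x$table)))
  invisible(x)
}
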