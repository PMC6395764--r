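# End-to-end per-movie analysis and batch comparison across movies.

#' Analyse one ER movie
#'
#' Runs the full pipeline: optional up-sampling to the working resolution,
#' optional background subtraction, guided smoothing, per-frame masking and
#' segmentation (phase congruency, hysteresis skeleton, cisternae,
#' polygons), width estimation and graph conversion on the reference
#' (middle) frame, bulge/constriction profiles, cisternal texture, optical
#' flow between the middle frame pair, and structure persistency over the
#' whole movie. Single-frame stacks get the full morphology with dynamics
#' and persistency skipped (with a notice).
#'
#' @param stack An [er_stack].
#' @param config An [er_config].
#' @param bg_roi Optional background rectangle `c(y, x, h, w)` passed to
#'   [subtract_background].
#' @param channel Channel used for segmentation.
#' @param verbose Emit per-stage messages.
#' @return Object of class `er_analysis`: the segmentation products of the
#'   reference frame (`mask`, `skeleton`, `cisternae`, `polygons`), the
#'   attributed `graph`, `widthmap`, `flow` and `persistency` maps,
#'   `persistent_nodes`, per-element `flow_summaries`, and a one-row
#'   `metrics` data frame of movie-level summary metrics.
#' @export
analyze_movie <- function(stack, config = er_config(), bg_roi = NULL,
                          channel = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("analyze_movie: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  if (config$fwhm_min_px < 5) {
    say("up-sampling to working resolution")
    stack <- stage("upsample", upsample_to_min_fwhm(stack, config$fwhm_min_px))
    f <- attr(stack, "upsample_factor")
    config$fwhm_min_px <- config$fwhm_min_px * f
    config$fwhm_max_px <- config$fwhm_max_px * f
  }
  if (!is.null(bg_roi)) stack <- stage("background", subtract_background(stack, bg_roi))
  stack <- stage("smooth", guided_smooth(stack, config$fwhm_min_px))
  px <- stack$pixel_size_nm
  nt <- n_frames(stack)
  t_ref <- ceiling(nt / 2)
  cal <- er_calibration(config$psf_xy_nm, config$sheet_thickness_nm,
                        config$sheet_ref_intensity)
  say("segmenting ", nt, " frame(s)")
  skeletons <- vector("list", nt)
  cis_masks <- vector("list", nt)
  seg_ref <- NULL
  for (t in seq_len(nt)) {
    frame <- get_frame(stack, t, channel)
    msk <- stage("mask", build_mask(frame, n_partitions = 2,
                                    shrink = config$boundary_shrink,
                                    erode_px = config$boundary_erode_px))
    ft <- stage("phase congruency",
                phase_congruency_ft(frame, config$n_scales, config$n_orients,
                                    config$noise_k))
    ftm <- ft$ft
    ftm[!msk$region] <- 0
    sk <- stage("skeleton", hysteresis_skeleton(ftm, config$hysteresis_lo,
                                                config$hysteresis_hi,
                                                config$hmin_depth))
    cis <- stage("cisternae",
                 segment_cisternae(frame, sk, config$fwhm_max_px,
                                   config$min_cisterna_area_um2, px,
                                   mask = msk))
    # skeleton pixels inside cisternae are flagged via the graph, but the
    # persistency skeleton keeps them out of tubule maps
    skeletons[[t]] <- sk$pixels & !(cis$labels > 0)
    cis_masks[[t]] <- cis$labels > 0
    if (t == t_ref) seg_ref <- list(frame = frame, mask = msk, ft = ft,
                                    skeleton = sk, cisternae = cis)
  }
  say("reference-frame morphology")
  frame <- seg_ref$frame
  sk <- seg_ref$skeleton
  cis <- seg_ref$cisternae
  polys <- stage("polygons", segment_polygons(sk, cis, seg_ref$mask, px))
  wm <- stage("widths", width_map(frame, sk, px, cal, cisternae = cis,
                                  max_radius_px = round(config$fwhm_max_px)))
  g <- stage("graph", skeleton_to_graph(sk, px,
                                        prune_spurs = config$prune_spurs,
                                        fwhm_min_px = config$fwhm_min_px))
  g <- stage("graph", resolve_duplicates(g))
  g <- stage("widths", centre_weighted_width(g, wm))
  g <- stage("graph", node_properties(g))
  g <- stage("graph", attach_cisternae(g, cis, frame))
  g <- stage("graph", attach_puncta(g, cis$puncta, config$fwhm_min_px))
  texture <- if (nrow(cis$table) > 0) {
    min_radius_px <- max(1L, round(min(wm$table$calibrated_radius_nm,
                                       na.rm = TRUE) / px))
    stage("texture", aggregate_textures(cis, frame, "per_cisterna_mean",
                                        distance_px = min_radius_px,
                                        n_bins = config$glcm_bins,
                                        intensity_range = c(0, stack$max_value)))
  } else NULL
  flow <- NULL; flow_summaries <- NULL; divcurl <- NULL
  pers <- NULL; pnodes <- NULL
  if (nt >= 2) {
    say("optical flow (middle frame pair)")
    t1 <- max(1, t_ref - 1)
    flow <- stage("flow", farneback_flow(get_frame(stack, t1, channel),
                                         get_frame(stack, t1 + 1, channel),
                                         px, stack$frame_interval_s))
    divcurl <- stage("flow", divergence_curl(flow))
    say("persistency")
    pers <- stage("persistency",
                  structure_persistency(skeletons, cis_masks,
                                        dilate_px = config$fwhm_min_px / 2,
                                        frame_interval_s = stack$frame_interval_s))
    g <- stage("persistency", graph_persistency(g, pers,
                                                node_radius_px = config$fwhm_min_px / 2))
    if (nt >= 3)
      pnodes <- stage("persistency",
                      persistent_nodes(stack, config$fwhm_min_px / 2,
                                       config$node_maxima_threshold, channel))
    tubule_edges <- which(!g$edges$is_cisterna_internal)
    flow_summaries <- do.call(rbind, c(
      lapply(tubule_edges, function(i) {
        p <- g$paths[[i]]
        if (!nrow(p)) return(NULL)
        cbind(data.frame(element = "tubule", id = g$edges$id[i]),
              summarize_flow(flow, p))
      }),
      lapply(seq_len(nrow(cis$table)), function(ci) {
        cbind(data.frame(element = "cisterna", id = cis$table$id[ci]),
              summarize_flow(flow, cis$labels == cis$table$id[ci]))
      })))
  } else {
    say("single frame: dynamics and persistency skipped")
  }
  metrics <- movie_metrics(g, cis, polys, texture, flow_summaries, pers,
                           divcurl, px)
  structure(list(stack_info = list(pixel_size_nm = px,
                                   frame_interval_s = stack$frame_interval_s,
                                   n_frames = nt, reference_frame = t_ref),
                 config = config, mask = seg_ref$mask,
                 feature_type = seg_ref$ft, skeleton = sk, cisternae = cis,
                 polygons = polys, widthmap = wm, graph = g,
                 texture = texture, flow = flow, div_curl = divcurl,
                 persistency = pers, persistent_nodes = pnodes,
                 flow_summaries = flow_summaries, metrics = metrics),
            class = "er_analysis")
}

movie_metrics <- function(g, cis, polys, texture, flow_summaries, pers,
                          divcurl, px) {
  tub <- g$edges[!g$edges$is_cisterna_internal, , drop = FALSE]
  m <- data.frame(
    tubule_length_um = mean_or_na(tub$length_um),
    tubule_width_nm = mean_or_na(tub$centre_width_nm),
    tubule_count = nrow(tub),
    node_degree = mean_or_na(g$nodes$degree[g$nodes$type == "junction"]),
    cisterna_area_um2 = mean_or_na(cis$table$area_um2),
    cisterna_perimeter_um = mean_or_na(cis$table$perimeter_um),
    cisterna_circularity = mean_or_na(cis$table$circularity),
    cisterna_count = nrow(cis$table),
    polygon_area_um2 = mean_or_na(polys$table$area_um2),
    polygon_perimeter_um = mean_or_na(polys$table$perimeter_um),
    polygon_circularity = mean_or_na(polys$table$circularity),
    polygon_count = nrow(polys$table))
  if (!is.null(texture)) {
    m$cisterna_contrast <- texture$contrast_norm
    m$cisterna_correlation <- texture$correlation
    m$cisterna_energy <- texture$energy
    m$cisterna_homogeneity <- texture$homogeneity
  } else {
    m$cisterna_contrast <- m$cisterna_correlation <-
      m$cisterna_energy <- m$cisterna_homogeneity <- NA_real_
  }
  fs <- flow_summaries
  for (el in c("tubule", "cisterna")) {
    sel <- if (!is.null(fs)) fs[fs$element == el, , drop = FALSE] else NULL
    m[[paste0(el, "_mean_speed_um_s")]] <- mean_or_na(sel$scalar_mean)
    m[[paste0(el, "_max_speed_um_s")]] <- mean_or_na(sel$max_speed)
    m[[paste0(el, "_coherence")]] <- mean_or_na(sel$coherence)
  }
  m$tubule_persistency_s <- mean_or_na(g$edges$persistency_s[
    !g$edges$is_cisterna_internal])
  m$cisterna_persistency_s <- if (!is.null(pers) && !is.null(pers$cisterna_s) &&
                                  nrow(cis$table) > 0)
    mean(vapply(cis$table$id, function(id)
      mean_or_na(pers$cisterna_s[cis$labels == id]), numeric(1)))
  else NA_real_
  m$divergence_sd <- if (!is.null(divcurl))
    stats::sd(divcurl$div[is.finite(divcurl$div)]) else NA_real_
  m$curl_sd <- if (!is.null(divcurl))
    stats::sd(divcurl$curl[is.finite(divcurl$curl)]) else NA_real_
  m
}

mean_or_na <- function(x) {
  if (is.null(x) || !length(x) || all(!is.finite(x))) return(NA_real_)
  mean(x[is.finite(x)])
}

#' @export
print.er_analysis <- function(x, ...) {
  cat("ER movie analysis\n")
  cat(sprintf("  %d frame(s), pixel %.0f nm, reference frame %d\n",
              x$stack_info$n_frames, x$stack_info$pixel_size_nm,
              x$stack_info$reference_frame))
  print(x$graph)
  print(x$cisternae)
  print(x$polygons)
  if (!is.null(x$flow_summaries))
    cat(sprintf("  mean tubule speed %.3f um/s, coherence %.2f\n",
                x$metrics$tubule_mean_speed_um_s, x$metrics$tubule_coherence))
  invisible(x)
}

#' @export
summary.er_analysis <- function(object, ...) {
  cat("Movie-level metrics:\n")
  m <- object$metrics
  for (cl in names(m)) cat(sprintf("  %-28s %s\n", cl, format(m[[cl]], digits = 4)))
  invisible(object$metrics)
}

#' @export
plot.er_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  img <- x$feature_type$ft
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(64),
                  axes = FALSE, main = "feature type", ...)
  overlay <- matrix(0, nrow(img), ncol(img))
  overlay[x$skeleton$pixels] <- 1
  overlay[x$cisternae$labels > 0] <- 0.5
  graphics::image(t(overlay)[, nrow(overlay):1],
                  col = c("black", "magenta", "green"),
                  axes = FALSE, main = "skeleton + cisternae")
  invisible(x)
}

#' Default normality transforms for the movie metric table
#'
#' Bounded `[0, 1]` metrics get the arcsin transform, wide-range positive
#' metrics (lengths, areas, speeds) the log transform, persistency the
#' square root (it includes zeros).
#'
#' @param metrics Metric column names.
#' @return Named character vector of transforms.
#' @export
default_transforms <- function(metrics) {
  tr <- vapply(metrics, function(m) {
    if (grepl("coherence|contrast|correlation|energy|homogeneity|solidity|circularity",
              m)) "arcsin"
    else if (grepl("persistency|divergence|curl", m)) "sqrt"
    else if (grepl("length|area|perimeter|speed|width|count|degree", m)) "log"
    else "none"
  }, character(1))
  names(tr) <- metrics
  tr
}

#' Batch analysis of several movies with group comparison
#'
#' Analyses each movie, assembles the per-movie metric rows into one
#' table, and when at least two groups with two movies each are present
#' runs [compare_groups] on the transformed metrics.
#'
#' @param stacks List of [er_stack] objects (or `er_analysis` objects to
#'   reuse existing results).
#' @param groups Character vector of group labels, one per movie.
#' @param config An [er_config].
#' @param control_label Control group (default: first level).
#' @param metrics Metric subset for the MANOVA (default: all complete
#'   columns).
#' @param ... Passed to [analyze_movie].
#' @return List with `table` (per-movie metric rows + `group`) and
#'   `report` (an `er_group_report` or `NULL`); failed movies are recorded
#'   in `failures`.
#' @export
batch_movies <- function(stacks, groups, config = er_config(),
                         control_label = NULL, metrics = NULL, ...) {
  stopifnot(length(stacks) == length(groups))
  rows <- list(); failures <- list()
  for (i in seq_along(stacks)) {
    res <- tryCatch({
      an <- if (inherits(stacks[[i]], "er_analysis")) stacks[[i]]
      else analyze_movie(stacks[[i]], config, ...)
      an$metrics
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(index = i,
                                               message = conditionMessage(res))
    } else {
      res$group <- groups[i]
      rows[[length(rows) + 1]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  report <- NULL
  if (!is.null(tab) && length(unique(tab$group)) >= 2 &&
      all(table(tab$group) >= 2)) {
    if (is.null(metrics)) {
      num <- names(tab)[vapply(tab, is.numeric, logical(1))]
      metrics <- num[colSums(!is.finite(as.matrix(tab[, num]))) == 0]
    }
    # MANOVA needs more residual df than metrics; keep the leading subset
    max_m <- nrow(tab) - length(unique(tab$group)) - 1
    if (length(metrics) > max_m) {
      warning("batch_movies: reducing metric subset from ", length(metrics),
              " to ", max_m, " to keep the MANOVA non-singular")
      metrics <- metrics[seq_len(max(1, max_m))]
    }
    ttab <- transform_metrics(tab, default_transforms(metrics))
    ctrl <- if (is.null(control_label)) sort(unique(tab$group))[1]
    else control_label
    report <- tryCatch(compare_groups(ttab, ctrl, metrics),
                       error = function(e) {
                         warning("batch_movies: group comparison failed: ",
                                 conditionMessage(e))
                         NULL
                       })
  }
  list(table = tab, report = report, failures = failures)
}
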