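#' Analysis configuration
#'
#' Bundles every acquisition- and analysis-dependent parameter of the ER
#' quantification pipeline. Scale parameters are expressed in pixels of the
#' working (possibly up-sampled) grid; physical parameters in nanometres.
#'
#' @param fwhm_min_px Full-width-half-maximum of the thinnest tubules, in
#'   pixels. The working grid is up-sampled until this is around 5 px; it
#'   sets the guided-filter kernel, the skeleton matching tolerance
#'   (`fwhm_min_px / 2`) and the persistency dilation radius.
#' @param fwhm_max_px FWHM of the widest junctions/tubules in pixels; the
#'   opening diameter used to remove tubules before cisterna segmentation
#'   and the maximum granulometry radius.
#' @param psf_xy_nm Lateral extent of the microscope point-spread function
#'   in nm (default 140).
#' @param sheet_thickness_nm Assumed thickness of a cisternal sheet in nm
#'   (default 40), from electron-microscopy calibration.
#' @param sheet_ref_intensity Reference fluorescence intensity of a
#'   cisternal sheet as a fraction of the image maximum (default 0.35);
#'   used when no cisterna is available to estimate it from the image.
#' @param hysteresis_lo,hysteresis_hi Lower/upper hysteresis thresholds on
#'   the normalised feature-type image (defaults 0.3 and 0.5).
#' @param hmin_depth Depth of shallow intensity minima that are zeroed
#'   before thresholding, so appressed tubules are not merged (default 0.05).
#' @param min_cisterna_area_um2 Minimum cisterna area in square microns
#'   (default 0.3); smaller bright regions are treated as puncta nodes.
#' @param boundary_shrink Contraction factor of the convex hull towards the
#'   foreground when building the analysis mask; 1 keeps the full hull.
#' @param boundary_erode_px Final erosion of the mask boundary in pixels
#'   (typically 4--6).
#' @param peak_height_frac,peak_prominence_frac Minimum peak height and
#'   prominence for bulge/constriction detection, as fractions of the trace
#'   maximum (defaults 0.05 and 0.03).
#' @param persistency_lag_frames Lag used for intensity persistency
#'   (default 12 frames, about 5 s at 0.41 s frame intervals).
#' @param glcm_bins Number of fixed intensity bins for co-occurrence
#'   matrices (default 32).
#' @param node_maxima_threshold Threshold on the normalised temporal-median
#'   image for persistent-node detection (0.3--0.5; default 0.4).
#' @param n_scales,n_orients Number of log-Gabor scales and orientations for
#'   phase congruency (defaults 4 and 6).
#' @param noise_k Noise-compensation factor for the phase-congruency
#'   amplitude floor (default 2).
#' @param prune_spurs Prune free-end edges shorter than `fwhm_min_px`
#'   during graph extraction (default TRUE).
#'
#' @return An object of class `er_config` (a validated list).
#' @export
er_config <- function(fwhm_min_px = 5,
                      fwhm_max_px = 10,
                      psf_xy_nm = 140,
                      sheet_thickness_nm = 40,
                      sheet_ref_intensity = 0.35,
                      hysteresis_lo = 0.3,
                      hysteresis_hi = 0.5,
                      hmin_depth = 0.05,
                      min_cisterna_area_um2 = 0.3,
                      boundary_shrink = 0.7,
                      boundary_erode_px = 4,
                      peak_height_frac = 0.05,
                      peak_prominence_frac = 0.03,
                      persistency_lag_frames = 12,
                      glcm_bins = 32,
                      node_maxima_threshold = 0.4,
                      n_scales = 4,
                      n_orients = 6,
                      noise_k = 2,
                      prune_spurs = TRUE) {
  cfg <- list(
    fwhm_min_px = fwhm_min_px, fwhm_max_px = fwhm_max_px,
    psf_xy_nm = psf_xy_nm, sheet_thickness_nm = sheet_thickness_nm,
    sheet_ref_intensity = sheet_ref_intensity,
    hysteresis_lo = hysteresis_lo, hysteresis_hi = hysteresis_hi,
    hmin_depth = hmin_depth,
    min_cisterna_area_um2 = min_cisterna_area_um2,
    boundary_shrink = boundary_shrink, boundary_erode_px = boundary_erode_px,
    peak_height_frac = peak_height_frac,
    peak_prominence_frac = peak_prominence_frac,
    persistency_lag_frames = persistency_lag_frames,
    glcm_bins = glcm_bins, node_maxima_threshold = node_maxima_threshold,
    n_scales = n_scales, n_orients = n_orients, noise_k = noise_k,
    prune_spurs = prune_spurs)
  validate_er_config(cfg)
  structure(cfg, class = "er_config")
}

validate_er_config <- function(cfg) {
  stopifnot(
    cfg$fwhm_min_px >= 3,
    cfg$fwhm_max_px >= cfg$fwhm_min_px,
    cfg$psf_xy_nm > 0, cfg$sheet_thickness_nm > 0,
    cfg$sheet_ref_intensity > 0, cfg$sheet_ref_intensity <= 1,
    cfg$hysteresis_lo < cfg$hysteresis_hi,
    cfg$hysteresis_lo >= 0, cfg$hysteresis_hi <= 1,
    cfg$hmin_depth >= 0, cfg$hmin_depth <= 1,
    cfg$min_cisterna_area_um2 >= 0,
    cfg$boundary_shrink >= 0, cfg$boundary_shrink <= 1,
    cfg$boundary_erode_px >= 0,
    cfg$peak_height_frac >= 0, cfg$peak_height_frac <= 1,
    cfg$peak_prominence_frac >= 0, cfg$peak_prominence_frac <= 1,
    cfg$persistency_lag_frames >= 1,
    cfg$glcm_bins >= 2,
    cfg$node_maxima_threshold >= 0, cfg$node_maxima_threshold <= 1)
  invisible(cfg)
}

#' @export
print.er_config <- function(x, ...) {
  cat("ER analysis configuration\n")
  cat(sprintf("  FWHM min/max: %.1f / %.1f px; psf %.0f nm; sheet %.0f nm (I_s = %.2f)\n",
              x$fwhm_min_px, x$fwhm_max_px, x$psf_xy_nm,
              x$sheet_thickness_nm, x$sheet_ref_intensity))
  cat(sprintf("  hysteresis %.2f/%.2f, h-min %.2f; min cisterna %.2f um^2\n",
              x$hysteresis_lo, x$hysteresis_hi, x$hmin_depth,
              x$min_cisterna_area_um2))
  cat(sprintf("  phase congruency: %d scales x %d orientations (k = %.1f)\n",
              x$n_scales, x$n_orients, x$noise_k))
  invisible(x)
}
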