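# Synthetic cortical-ER scene generator with full ground truth.
#
# Scenes are polygonal tubule networks built on a jittered rectangular
# lattice: vertices are lattice points perturbed by a fraction of the cell
# size, edges connect lattice neighbours, and faces of the lattice are the
# enclosed polygonal regions. This gives an exactly known planar truth graph
# (nodes, edges, faces) alongside the rendered image. Tubules are rendered
# as Gaussian line profiles whose *integrated* cross-section brightness is
# proportional to their cross-sectional area (lumen volume per unit
# length), so the psf-based radius calibration is exactly recoverable by
# construction; cisternae are uniform patches at the sheet reference
# intensity blurred by the psf.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Integrated cross-section brightness (intensity * px per px of length) of a
# tubule of radius r_nm, relative to a sheet rendered at `i_s`:
# measured I_t = lambda / psf_px must equal i_s * 4 r^2 / (psf * T_s).
tube_line_density <- function(r_nm, pixel_size_nm, psf_xy_nm,
                              sheet_thickness_nm, i_s) {
  psf_px <- psf_xy_nm / pixel_size_nm
  i_s * psf_px * 4 * r_nm^2 / (psf_xy_nm * sheet_thickness_nm)
}

# Splat a polyline (n x 2 matrix of (y, x), px) onto `img` as a Gaussian
# line integral with per-edge sigma and total line density lambda.
splat_polyline <- function(img, pts, sigma, lambda, step = 0.4) {
  seg <- diff(pts)
  lens <- sqrt(rowSums(seg^2))
  keep <- lens > 0
  if (!any(keep)) return(img)
  samples <- NULL
  for (i in which(keep)) {
    n <- max(2L, ceiling(lens[i] / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    p <- cbind(pts[i, 1] + tt * seg[i, 1], pts[i, 2] + tt * seg[i, 2])
    w <- rep(lens[i] / (n - 1), n); w[c(1, n)] <- w[1] / 2
    samples <- rbind(samples, cbind(p, w))
  }
  r <- ceiling(4 * sigma)
  off <- -r:r
  g1 <- dnorm(off, sd = sigma)
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(nrow(samples))) {
    cy <- samples[k, 1]; cx <- samples[k, 2]; w <- samples[k, 3]
    iy <- round(cy) + off; ix <- round(cx) + off
    gy <- dnorm(iy - cy, sd = sigma); gx <- dnorm(ix - cx, sd = sigma)
    selY <- iy >= 1 & iy <= nr; selX <- ix >= 1 & ix <= nc
    if (!any(selY) || !any(selX)) next
    img[iy[selY], ix[selX]] <- img[iy[selY], ix[selX]] +
      (lambda * w) * outer(gy[selY], gx[selX])
  }
  img
}

rasterise_polylines <- function(polylines, ny, nx, radii_nm = NULL) {
  mask <- matrix(FALSE, ny, nx)
  rad <- matrix(NA_real_, ny, nx)
  for (i in seq_along(polylines)) {
    pts <- polylines[[i]]
    seg <- diff(pts)
    lens <- sqrt(rowSums(seg^2))
    for (j in seq_len(nrow(seg))) {
      if (lens[j] == 0) next
      n <- max(2L, ceiling(lens[j] / 0.3) + 1L)
      tt <- seq(0, 1, length.out = n)
      yy <- round(pts[j, 1] + tt * seg[j, 1])
      xx <- round(pts[j, 2] + tt * seg[j, 2])
      ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
      idx <- cbind(yy[ok], xx[ok])
      mask[idx] <- TRUE
      if (!is.null(radii_nm)) rad[idx] <- radii_nm[i]
    }
  }
  sk <- thin_connected(mask)
  rad[!sk] <- NA_real_
  list(skeleton = sk, radius_nm = rad)
}

#' Generate a synthetic ER network scene with ground truth
#'
#' Builds a polygonal tubule network on a jittered lattice, optionally
#' converts a fraction of the enclosed faces into sheet-like cisternae, and
#' renders a single-frame image at the given pixel size under a Gaussian
#' psf, with additive Gaussian (and optional Poisson) noise.
#'
#' @param n_polygons Number of enclosed polygonal faces (>= 1).
#' @param width_range_nm Range of true tubule radii in nm (sampled
#'   uniformly per edge); must lie within (10, 200).
#' @param cisterna_fraction Fraction of faces turned into cisternae.
#' @param noise_sd SD of additive Gaussian noise (intensity units; the
#'   sheet reference intensity is `sheet_ref_intensity`).
#' @param psf_xy_nm Lateral psf FWHM in nm (default 140).
#' @param pixel_size_nm Pixel size in nm, in `[20, 80]` (default 40).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @param sheet_ref_intensity Rendered intensity of cisternal sheets
#'   (fraction of full scale, default 0.35).
#' @param sheet_thickness_nm Sheet thickness used in the brightness model
#'   (default 40 nm).
#' @param jitter_frac Vertex jitter as a fraction of the lattice cell.
#' @param cell_um Lattice cell size in microns (default 1.4).
#' @param poisson_noise Add Poisson shot noise scaled to an 8-bit signal.
#' @param frame_interval_s Frame interval recorded in the stack metadata.
#' @return A list with `stack` (an [er_stack]) and `truth` (class
#'   `er_truth`): single-pixel skeleton mask, per-pixel true radius (nm),
#'   cisterna mask, the planar truth graph (`nodes`, `edges`, `n_faces`)
#'   and the rendering geometry needed by [animate_scene].
#' @export
generate_network_scene <- function(n_polygons,
                                   width_range_nm = c(25, 50),
                                   cisterna_fraction = 0.15,
                                   noise_sd = 0.02,
                                   psf_xy_nm = 140,
                                   pixel_size_nm = 40,
                                   seed = 1L,
                                   sheet_ref_intensity = 0.35,
                                   sheet_thickness_nm = 40,
                                   jitter_frac = 0.22,
                                   cell_um = 1.4,
                                   poisson_noise = FALSE,
                                   frame_interval_s = 0.41) {
  if (n_polygons < 1 && cisterna_fraction <= 0)
    stop("generate_network_scene: n_polygons must be >= 1 for a non-empty scene")
  if (n_polygons < 1)
    stop("generate_network_scene: n_polygons must be >= 1")
  stopifnot(width_range_nm[1] > 10, width_range_nm[2] < 200,
            pixel_size_nm >= 20, pixel_size_nm <= 80)
  with_seed(seed, {
    cell_px <- cell_um * 1000 / pixel_size_nm
    k <- max(1L, ceiling(sqrt(n_polygons)))
    m <- max(1L, ceiling(n_polygons / k))
    margin <- 8
    ny <- ceiling(m * cell_px + 2 * margin)
    nx <- ceiling(k * cell_px + 2 * margin)
    # jittered lattice vertices, (m+1) x (k+1)
    vy <- outer(0:m, rep(1, k + 1)) * cell_px + margin
    vx <- outer(rep(1, m + 1), 0:k) * cell_px + margin
    vy <- vy + matrix(runif(length(vy), -jitter_frac, jitter_frac) * cell_px, m + 1)
    vx <- vx + matrix(runif(length(vx), -jitter_frac, jitter_frac) * cell_px, m + 1)
    vid <- matrix(seq_len((m + 1) * (k + 1)), m + 1, k + 1)
    nodes <- data.frame(id = as.vector(vid), y = as.vector(vy), x = as.vector(vx))
    edges <- NULL
    for (i in 1:(m + 1)) for (j in 1:(k + 1)) {
      if (j < k + 1) edges <- rbind(edges, c(vid[i, j], vid[i, j + 1]))
      if (i < m + 1) edges <- rbind(edges, c(vid[i, j], vid[i + 1, j]))
    }
    edges <- data.frame(from = edges[, 1], to = edges[, 2])
    edges$radius_nm <- runif(nrow(edges), width_range_nm[1], width_range_nm[2])
    p1 <- cbind(nodes$y[edges$from], nodes$x[edges$from])
    p2 <- cbind(nodes$y[edges$to], nodes$x[edges$to])
    edges$length_um <- sqrt(rowSums((p2 - p1)^2)) * pixel_size_nm / 1000
    # cisterna faces
    n_faces <- m * k
    n_cis <- round(cisterna_fraction * n_faces)
    cis_faces <- if (n_cis > 0) sample.int(n_faces, n_cis) else integer(0)
    cis <- list()
    for (f in cis_faces) {
      fi <- (f - 1) %% m + 1; fj <- (f - 1) %/% m + 1
      corn <- rbind(c(vy[fi, fj], vx[fi, fj]), c(vy[fi, fj + 1], vx[fi, fj + 1]),
                    c(vy[fi + 1, fj], vx[fi + 1, fj]), c(vy[fi + 1, fj + 1], vx[fi + 1, fj + 1]))
    ctr <- colMeans(corn)
      ax <- runif(2, 0.28, 0.38) * cell_px
      cis[[length(cis) + 1]] <- list(cy = ctr[1], cx = ctr[2],
                                     ay = ax[1], axx = ax[2],
                                     theta = runif(1, 0, pi))
    }
    geom <- list(nodes = nodes, edges = edges, cisternae = cis,
                 ny = ny, nx = nx,
                 pixel_size_nm = pixel_size_nm, psf_xy_nm = psf_xy_nm,
                 sheet_ref_intensity = sheet_ref_intensity,
                 sheet_thickness_nm = sheet_thickness_nm,
                 noise_sd = noise_sd, poisson_noise = poisson_noise,
                 frame_interval_s = frame_interval_s)
    rend <- render_geometry(geom, noise_seed = seed + 1000L)
    truth <- structure(list(
      skeleton_px = list(rend$skeleton), tubule_radius_nm = list(rend$radius_nm),
      cisterna_mask = list(rend$cisterna_mask),
      graph = list(nodes = nodes, edges = edges, n_faces = n_faces),
      anchor_px = NULL, flow_um_s = NULL, geometry = geom), class = "er_truth")
    stack <- er_stack(rend$image, pixel_size_nm = pixel_size_nm,
                      frame_interval_s = frame_interval_s, max_value = 1)
    list(stack = stack, truth = truth)
  })
}

# Render one frame from a geometry description (optionally with per-point
# displacement function `displace(pts)` applied to all coordinates).
render_geometry <- function(geom, displace = NULL, noise_seed = NULL) {
  ny <- geom$ny; nx <- geom$nx
  px <- geom$pixel_size_nm
  psf_px <- geom$psf_xy_nm / px
  sigma_psf <- psf_px / 2.3548
  img <- matrix(0, ny, nx)
  move <- function(pts) if (is.null(displace)) pts else displace(pts)
  polylines <- list(); radii <- numeric(0)
  for (e in seq_len(nrow(geom$edges))) {
    a <- geom$edges$from[e]; b <- geom$edges$to[e]
    p <- rbind(c(geom$nodes$y[a], geom$nodes$x[a]),
               c(geom$nodes$y[b], geom$nodes$x[b]))
    # densify so displacement fields bend the tubule smoothly
    n <- max(2L, ceiling(sqrt(sum((p[2, ] - p[1, ])^2)) / 2))
    tt <- seq(0, 1, length.out = n)
    pts <- cbind(p[1, 1] + tt * (p[2, 1] - p[1, 1]),
                 p[1, 2] + tt * (p[2, 2] - p[1, 2]))
    pts <- move(pts)
    r_nm <- geom$edges$radius_nm[e]
    sigma_r <- max(0.2, (r_nm / px) / 2)
    sigma <- sqrt(sigma_psf^2 + sigma_r^2)
    lambda <- tube_line_density(r_nm, px, geom$psf_xy_nm,
                                geom$sheet_thickness_nm,
                                geom$sheet_ref_intensity)
    img <- splat_polyline(img, pts, sigma, lambda)
    polylines[[e]] <- pts; radii[e] <- r_nm
  }
  cis_mask <- matrix(FALSE, ny, nx)
  if (length(geom$cisternae)) {
    yy <- matrix(rep(seq_len(ny), nx), ny)
    xx <- matrix(rep(seq_len(nx), each = ny), ny)
    for (cs in geom$cisternae) {
      ctr <- move(matrix(c(cs$cy, cs$cx), 1))
      dy <- yy - ctr[1, 1]; dx <- xx - ctr[1, 2]
      u <- cos(cs$theta) * dx + sin(cs$theta) * dy
      v <- -sin(cs$theta) * dx + cos(cs$theta) * dy
      cis_mask <- cis_mask | ((u / cs$axx)^2 + (v / cs$ay)^2 <= 1)
    }
    layer <- gauss_blur(cis_mask * geom$sheet_ref_intensity, sigma_psf)
    img <- pmax(img, layer)
  }
  if (!is.null(noise_seed) &&
      (geom$noise_sd > 0 || isTRUE(geom$poisson_noise))) {
    with_seed(noise_seed, {
      if (isTRUE(geom$poisson_noise))
        img <- rpois(length(img), pmax(img, 0) * 255) / 255
      if (geom$noise_sd > 0)
        img <- img + rnorm(length(img), sd = geom$noise_sd)
      img <- matrix(pmax(img, 0), ny, nx)
    })
  }
  ras <- rasterise_polylines(polylines, ny, nx, radii)
  list(image = img, skeleton = ras$skeleton, radius_nm = ras$radius_nm,
       cisterna_mask = cis_mask)
}

#' Animate a synthetic scene into a movie with known flow
#'
#' Re-renders the scene geometry frame by frame under a bulk translation
#' plus optional frame-to-frame jitter. Geometry within one psf width
#' (FWHM) of an anchor point is held static, with a smooth ramp to full
#' displacement at three psf widths, emulating ER-plasma-membrane contact
#' sites pinning the network.
#'
#' @param truth An `er_truth` from [generate_network_scene].
#' @param n_frames Number of frames (>= 2).
#' @param translation_um_s Bulk velocity, `c(vy, vx)` in micron/s.
#' @param jitter_sd_px Per-frame SD of random global jitter (px).
#' @param anchor_px Optional matrix of anchor positions, columns `(y, x)`.
#'   Anchors are rendered as punctate contact-site signal (a psf-sized spot
#'   at twice the sheet reference intensity, the locally accumulated
#'   membrane signal) present in every frame, emulating the bright
#'   persistent puncta at ER-plasma-membrane contact sites.
#' @param seed Integer seed for the jitter sequence.
#' @return A list with `stack` (the movie) and `truth`: per-frame skeleton
#'   masks, radius maps and cisterna masks, per-frame-pair true flow fields
#'   (`flow_um_s`, arrays `[y, x, 2]` with planes vy, vx in micron/s), and
#'   the anchor list.
#' @export
animate_scene <- function(truth, n_frames, translation_um_s = c(0, 0),
                          jitter_sd_px = 0, anchor_px = NULL, seed = 1L) {
  stopifnot(inherits(truth, "er_truth"), n_frames >= 2)
  geom <- truth$geometry
  px <- geom$pixel_size_nm
  dt <- geom$frame_interval_s
  shift_per_frame <- translation_um_s * 1000 / px * dt  # px/frame, (dy, dx)
  if (any(abs(shift_per_frame) > c(geom$ny, geom$nx) / 2))
    stop("animate_scene: translation exceeds half the field per frame")
  psf_px <- geom$psf_xy_nm / px
  weight_fun <- function(pts) {
    if (is.null(anchor_px) || nrow(anchor_px) == 0) return(rep(1, nrow(pts)))
    d2 <- matrix(Inf, nrow(pts), 1)
    for (a in seq_len(nrow(anchor_px))) {
      da <- (pts[, 1] - anchor_px[a, 1])^2 + (pts[, 2] - anchor_px[a, 2])^2
      d2 <- pmin(d2, da)
    }
    d <- sqrt(d2)
    pmin(1, pmax(0, (d - psf_px) / (2 * psf_px)))
  }
  offsets <- with_seed(seed, {
    jit <- matrix(0, n_frames, 2)
    if (jitter_sd_px > 0)
      jit[-1, ] <- matrix(rnorm(2 * (n_frames - 1), sd = jitter_sd_px),
                          n_frames - 1)
    base <- outer(0:(n_frames - 1), shift_per_frame)
    base + apply(jit, 2, cumsum)
  })
  frames <- vector("list", n_frames)
  skels <- vector("list", n_frames)
  rads <- vector("list", n_frames)
  cmasks <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    disp <- offsets[f, ]
    displace <- function(pts) {
      w <- weight_fun(pts)
      cbind(pts[, 1] + disp[1] * w, pts[, 2] + disp[2] * w)
    }
    rend <- render_geometry(geom, displace = displace,
                            noise_seed = seed + 7L * f)
    if (!is.null(anchor_px) && nrow(anchor_px) > 0) {
      sigma_psf <- psf_px / 2.3548
      r <- ceiling(3 * sigma_psf)
      for (a in seq_len(nrow(anchor_px))) {
        ys <- round(anchor_px[a, 1]) + (-r:r)
        xs <- round(anchor_px[a, 2]) + (-r:r)
        ok_y <- ys >= 1 & ys <= geom$ny; ok_x <- xs >= 1 & xs <= geom$nx
        spot <- 2 * geom$sheet_ref_intensity *   # accumulated signal at EPCS
          outer(exp(-(ys[ok_y] - anchor_px[a, 1])^2 / (2 * sigma_psf^2)),
                exp(-(xs[ok_x] - anchor_px[a, 2])^2 / (2 * sigma_psf^2)))
        rend$image[ys[ok_y], xs[ok_x]] <-
          pmax(rend$image[ys[ok_y], xs[ok_x]], spot)
      }
    }
    frames[[f]] <- rend$image
    skels[[f]] <- rend$skeleton
    rads[[f]] <- rend$radius_nm
    cmasks[[f]] <- rend$cisterna_mask
  }
  yy <- matrix(rep(seq_len(geom$ny), geom$nx), geom$ny)
  xx <- matrix(rep(seq_len(geom$nx), each = geom$ny), geom$ny)
  w_px <- matrix(weight_fun(cbind(as.vector(yy), as.vector(xx))), geom$ny)
  flow <- vector("list", n_frames - 1)
  for (f in seq_len(n_frames - 1)) {
    dpf <- offsets[f + 1, ] - offsets[f, ]
    flow[[f]] <- array(c(w_px * dpf[1], w_px * dpf[2]) * px / 1000 / dt,
                       c(geom$ny, geom$nx, 2))
  }
  arr <- array(0, c(geom$ny, geom$nx, 1, n_frames))
  for (f in seq_len(n_frames)) arr[, , 1, f] <- frames[[f]]
  stack <- er_stack(arr, pixel_size_nm = px, frame_interval_s = dt,
                    max_value = 1)
  out_truth <- structure(list(
    skeleton_px = skels, tubule_radius_nm = rads, cisterna_mask = cmasks,
    graph = truth$graph, anchor_px = anchor_px, flow_um_s = flow,
    geometry = geom), class = "er_truth")
  list(stack = stack, truth = out_truth)
}

#' Render an isolated straight tubule of known radius
#'
#' A minimal fixture for width-calibration work: one horizontal tubule of
#' known true radius through the image centre, plus (optionally) a uniform
#' reference sheet patch at the sheet reference intensity so the internal
#' intensity standard `I_s` can be estimated from the same image.
#'
#' @param radius_nm True tubule radius (nm).
#' @param length_px Tubule length in pixels.
#' @param pixel_size_nm,psf_xy_nm,sheet_thickness_nm,sheet_ref_intensity
#'   Rendering calibration, as in [generate_network_scene].
#' @param with_sheet Include the reference sheet patch.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Seed for the noise.
#' @return List with `image`, logical `skeleton` (the true centreline),
#'   logical `sheet_mask`, and the rendering parameters.
#' @export
simulate_tubule <- function(radius_nm, length_px = 60, pixel_size_nm = 40,
                            psf_xy_nm = 140, sheet_thickness_nm = 40,
                            sheet_ref_intensity = 0.35, with_sheet = TRUE,
                            noise_sd = 0, seed = 1L) {
  psf_px <- psf_xy_nm / pixel_size_nm
  sigma_psf <- psf_px / 2.3548
  pad <- 14
  ny <- 2 * pad + (if (with_sheet) 30 else 0) + 11
  nx <- length_px + 2 * pad
  img <- matrix(0, ny, nx)
  y0 <- pad + 5
  pts <- cbind(c(y0, y0), c(pad + 1, pad + length_px))
  sigma_r <- max(0.2, (radius_nm / pixel_size_nm) / 2)
  lambda <- tube_line_density(radius_nm, pixel_size_nm, psf_xy_nm,
                              sheet_thickness_nm, sheet_ref_intensity)
  img <- splat_polyline(img, pts, sqrt(sigma_psf^2 + sigma_r^2), lambda)
  sheet <- matrix(FALSE, ny, nx)
  if (with_sheet) {
    sheet[(y0 + 14):(ny - 5), pad:(nx - pad)] <- TRUE
    img <- pmax(img, gauss_blur(sheet * sheet_ref_intensity, sigma_psf))
  }
  if (noise_sd > 0)
    img <- with_seed(seed, matrix(pmax(img + rnorm(length(img), sd = noise_sd), 0), ny, nx))
  skel <- matrix(FALSE, ny, nx)
  skel[y0, (pad + 1):(pad + length_px)] <- TRUE
  list(image = img, skeleton = skel, sheet_mask = sheet,
       pixel_size_nm = pixel_size_nm, psf_xy_nm = psf_xy_nm,
       sheet_thickness_nm = sheet_thickness_nm,
       sheet_ref_intensity = sheet_ref_intensity)
}
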