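# Shared fixture builders (all generated in code; no stored data).

# Filled disc of radius r (px) centred in a square image.
make_disc <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  yy <- matrix(rep(seq_len(n), n), n)
  xx <- t(yy)
  (yy - ctr)^2 + (xx - ctr)^2 <= r^2
}

# Filled axis-aligned ellipse with semi-axes (a, b).
make_ellipse <- function(a, b, pad = 4) {
  ny <- 2 * (b + pad) + 1; nx <- 2 * (a + pad) + 1
  cy <- b + pad + 1; cx <- a + pad + 1
  yy <- matrix(rep(seq_len(ny), nx), ny)
  xx <- matrix(rep(seq_len(nx), each = ny), ny)
  ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
}

# Horizontal Gaussian ridge of sigma px through the image centre, with an
# optional amplitude modulation A(x).
make_ridge <- function(ny = 41, nx = 81, sigma = 2, amp = NULL) {
  y0 <- (ny + 1) / 2
  prof <- exp(-(seq_len(ny) - y0)^2 / (2 * sigma^2))
  a <- if (is.null(amp)) rep(1, nx) else amp
  outer(prof, a)
}

# Pixel-mask skeleton of a square loop (closed) for polygon tests.
make_square_loop <- function(side = 20, pad = 6) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  i <- pad + 1; j <- pad + side
  m[i:j, i] <- TRUE; m[i:j, j] <- TRUE
  m[i, i:j] <- TRUE; m[j, i:j] <- TRUE
  m
}

# The pipeline's own skeleton for a synthetic frame: guided smoothing,
# phase congruency, hysteresis + thinning, spur pruning via the graph.
pipeline_skeleton <- function(img, pixel_size_nm = 40, fwhm_min_px = 5) {
  img <- guided_smooth(img, fwhm_min_px)
  sk <- hysteresis_skeleton(phase_congruency_ft(img))
  g <- skeleton_to_graph(sk, pixel_size_nm, fwhm_min_px = fwhm_min_px)
  out <- matrix(FALSE, nrow(img), ncol(img))
  for (p in g$paths) if (nrow(p)) out[p] <- TRUE
  for (np in g$node_pixels) out[np] <- TRUE
  out
}

# Shift a matrix with zero fill (test-local mirror of the internal utility).
mat_shift_test <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Interior of a region beyond a given depth (px).
make_disc_inner <- function(disc, erode_px) {
  EBImage::distmap(disc) > erode_px
}

# Cisterna-exclusion mask for skeleton scoring (the comparison protocol
# drops cisternae and their psf-blurred halo from both skeletons).
cisterna_exclusion <- function(cis_mask, grow_px = 5) {
  cis_mask | (EBImage::distmap(!cis_mask) <= grow_px)
}
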