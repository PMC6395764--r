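# Low-level image utilities shared across the pipeline. Images are plain
# numeric matrices indexed [row = y, col = x]; masks are logical matrices.

# Shift a matrix by (dy, dx), padding with `fill`.
mat_shift <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ys) == 0L || length(xs) == 0L) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# 3x3 minimum / maximum filters (8-neighbourhood plus centre).
min3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmin(out, mat_shift(m, dy, dx, fill = Inf))
  }
  out
}
max3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, mat_shift(m, dy, dx, fill = -Inf))
  }
  out
}

# Disc structuring element of given radius (pixels). radius 0 is a single
# pixel. Uses an exact Euclidean disc, matching the granulometry contract
# that successive elements are nested.
disc_brush <- function(radius) {
  r <- max(0L, as.integer(round(radius)))
  if (r == 0L) return(matrix(1, 1, 1))
  d <- 2L * r + 1L
  yy <- matrix(rep(-r:r, d), d, d)
  xx <- t(yy)
  (yy^2 + xx^2 <= r^2 + 1e-9) + 0
}

# EBImage treats intensities as [0, 1]; rescale so min/max filtering is
# exact for any non-negative range.
gray_erode <- function(m, brush) {
  if (length(brush) == 1L) return(m)
  s <- max(m, 1)
  EBImage::erode(m / s, brush) * s
}
gray_dilate <- function(m, brush) {
  if (length(brush) == 1L) return(m)
  s <- max(m, 1)
  EBImage::dilate(m / s, brush) * s
}
gray_open <- function(m, brush) gray_dilate(gray_erode(m, brush), brush)
gray_close <- function(m, brush) gray_erode(gray_dilate(m, brush), brush)

# Binary dilation by an exact Euclidean disc of (possibly fractional) radius,
# via the distance transform of the complement.
dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- EBImage::distmap(!mask)
  mask | (d <= radius)
}
erode_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- EBImage::distmap(mask)
  mask & (d > radius)
}

# 8-connected labelling of a logical mask. EBImage::bwlabel is 4-connected;
# diagonal touches are merged here with a union-find pass over label pairs.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  pairs <- NULL
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab
    b <- mat_shift(lab, sh[1], sh[2], fill = 0)
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(as.integer(pairs[k, 1])); rb <- find(as.integer(pairs[k, 2]))
    if (ra != rb) parent[max(ra, rb)] <- as.integer(min(ra, rb))
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Count of 8-neighbours that are TRUE, per pixel.
neighbour_count8 <- function(mask) {
  m <- mask + 0
  s <- matrix(0, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- s + mat_shift(m, dy, dx, fill = 0)
  }
  s
}

# Morphological reconstruction by erosion: lower `marker` towards `mask`
# (marker >= mask everywhere) by geodesic erosion until stability.
reconstruct_erode <- function(marker, mask, max_iter = 2000L) {
  cur <- pmax(marker, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmax(min3(cur), mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# Pixels belonging to basins of regional minima with depth <= h. Used to
# keep appressed tubules separate before hysteresis thresholding: shallow
# inter-tubule valleys are forced to zero. Shallow basins are exactly the
# pixels raised by the h-minima transform whose fill level no longer rises
# when h is increased slightly.
shallow_minima_mask <- function(m, h, delta = NULL) {
  if (is.null(delta)) delta <- max(h * 0.1, 1e-6)
  h1 <- reconstruct_erode(m + h, m)
  h2 <- reconstruct_erode(m + h + delta, m)
  (h1 > m + 1e-12) & (abs(h2 - h1) < delta / 2)
}

# Zhang-Suen thinning of a binary mask to a single-pixel-wide, 8-connected
# skeleton. Vectorised over the whole image per sub-iteration.
thin_zhang_suen <- function(mask) {
  m <- mask & TRUE
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- mat_shift(m, -1,  0, FALSE); p3 <- mat_shift(m, -1,  1, FALSE)
      p4 <- mat_shift(m,  0,  1, FALSE); p5 <- mat_shift(m,  1,  1, FALSE)
      p6 <- mat_shift(m,  1,  0, FALSE); p7 <- mat_shift(m,  1, -1, FALSE)
      p8 <- mat_shift(m,  0, -1, FALSE); p9 <- mat_shift(m, -1, -1, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Parallel thinning can, in rare pixel configurations, split one connected
# structure into components ending a pixel or two apart. Bridge pixels are
# reinstated at the midpoint of any cross-component pixel pair within two
# chebyshev steps, provided the bridge lies inside the original mask.
repair_breaks <- function(sk, orig, max_pass = 4L) {
  for (pass in seq_len(max_pass)) {
    lab <- label8(sk)
    if (max(lab) <= 1) return(sk)
    added <- FALSE
    for (dy in -2:2) for (dx in -2:2) {
      if (dy == 0 && dx == 0) next
      b <- mat_shift(lab, dy, dx, 0)
      sel <- which(lab > 0 & b > 0 & lab != b)
      if (!length(sel)) next
      pos <- arrayInd(sel, dim(lab))
      for (k in seq_len(nrow(pos))) {
        y <- pos[k, 1]; x <- pos[k, 2]
        my <- y - round(dy / 2); mx <- x - round(dx / 2)
        if (my >= 1 && my <= nrow(sk) && mx >= 1 && mx <= ncol(sk) &&
            !sk[my, mx] && orig[my, mx]) {
          sk[my, mx] <- TRUE
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  sk
}

# Thin to a single-pixel skeleton while preserving the connectivity of the
# input mask (thinning, break repair, 2x2 cleanup).
thin_connected <- function(mask) {
  sk <- thin_zhang_suen(mask)
  sk <- repair_breaks(sk, mask)
  despur_2x2(sk)
}

# Remove staircase redundancy left by thinning so that no 2x2 block is fully
# set: a pixel may be dropped if it sits in a full 2x2 block and removing it
# keeps its remaining neighbours 8-connected locally.
despur_2x2 <- function(mask) {
  m <- mask & TRUE
  repeat {
    blk <- m & mat_shift(m, 0, 1, FALSE) & mat_shift(m, 1, 0, FALSE) &
      mat_shift(m, 1, 1, FALSE)
    if (!any(blk)) break
    idx <- which(blk, arr.ind = TRUE)
    removed <- FALSE
    for (k in seq_len(nrow(idx))) {
      y <- idx[k, 1]; x <- idx[k, 2]
      for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        yy <- y + off[1]; xx <- x + off[2]
        if (!m[yy, xx]) next
        m[yy, xx] <- FALSE
        if (local_connected8(m, yy, xx)) { removed <- TRUE; break }
        m[yy, xx] <- TRUE
      }
      if (removed) break
    }
    if (!removed) break
  }
  m
}

# Check that the TRUE neighbours of (y, x) remain mutually 8-connected
# within the 3x3 neighbourhood after (y, x) was cleared.
local_connected8 <- function(m, y, x) {
  ys <- max(1, y - 1):min(nrow(m), y + 1)
  xs <- max(1, x - 1):min(ncol(m), x + 1)
  sub <- m[ys, xs, drop = FALSE]
  pts <- which(sub, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 1) return(TRUE)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(!seen & abs(pts[, 1] - pts[i, 1]) <= 1 & abs(pts[, 2] - pts[i, 2]) <= 1)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Box mean filter with half-width r (window 2r+1), edge-renormalised, via
# integral images.
box_mean <- function(m, r) {
  if (r <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  cs <- function(x) apply(x, 2, cumsum)
  sum_win <- function(x) {
    S <- cs(t(cs(x)))
    S <- t(S)
    pad <- matrix(0, nr + 1, nc + 1)
    pad[-1, -1] <- S
    y2 <- pmin(seq_len(nr) + r, nr); y1 <- pmax(seq_len(nr) - r, 1) - 1L
    x2 <- pmin(seq_len(nc) + r, nc); x1 <- pmax(seq_len(nc) - r, 1) - 1L
    pad[y2 + 1, x2 + 1, drop = FALSE] - pad[y1 + 1, x2 + 1, drop = FALSE] -
      pad[y2 + 1, x1 + 1, drop = FALSE] + pad[y1 + 1, x1 + 1, drop = FALSE]
  }
  sum_win(m) / sum_win(matrix(1, nr, nc))
}

# Bilinear sampling of matrix `m` at fractional (y, x) positions.
bilinear_sample <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y <- pmin(pmax(y, 1), nr); x <- pmin(pmax(x, 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fy) * (1 - fx) + m[i10] * fy * (1 - fx) +
    m[i01] * (1 - fy) * fx + m[i11] * fy * fx
}

# Separable Gaussian blur with replicated borders.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}
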