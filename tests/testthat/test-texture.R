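# Grey-level co-occurrence matrices and texture metrics.

# Exhaustive pair-enumeration oracle for the symmetric 4-direction GLCM.
glcm_brute <- function(region, frame, d, n_bins, rng = c(0, 1)) {
  bin <- pmin(pmax(floor((frame - rng[1]) / diff(rng) * n_bins), 0),
              n_bins - 1) + 1L
  acc <- matrix(0, n_bins, n_bins)
  offs <- rbind(c(0, d), c(-d, 0), c(-d, d), c(-d, -d))
  pts <- which(region, arr.ind = TRUE)
  for (k in seq_len(nrow(pts))) for (o in seq_len(4)) {
    y2 <- pts[k, 1] + offs[o, 1]; x2 <- pts[k, 2] + offs[o, 2]
    if (y2 < 1 || y2 > nrow(region) || x2 < 1 || x2 > ncol(region)) next
    if (!region[y2, x2]) next
    i <- bin[pts[k, 1], pts[k, 2]]; j <- bin[y2, x2]
    acc[i, j] <- acc[i, j] + 1
    acc[j, i] <- acc[j, i] + 1
  }
  acc / sum(acc)
}

test_that("constant regions give a single diagonal entry with the textbook metric values", {
  reg <- matrix(TRUE, 8, 8)
  frame <- matrix(0.5, 8, 8)
  g <- build_glcm(reg, frame, 1, n_bins = 32, intensity_range = c(0, 1))
  expect_equal(sum(g$p), 1)
  expect_equal(sum(g$p > 0), 1)
  expect_equal(g$p[17, 17], 1)                     # bin of 0.5 on [0,1] x 32
  m <- glcm_metrics(g)
  expect_equal(m$contrast_norm, 0)
  expect_equal(m$homogeneity, 1)
  expect_equal(m$energy, 1)
  expect_true(is.nan(m$correlation))
})

test_that("checkerboards and handmade matrices evaluate to closed-form metrics", {
  # 8x8 checkerboard of intensities 0.05 / 0.95 at distance 1. Hand
  # enumeration over the four directions: E and N pairs always cross
  # colours (8 x 7 = 56 pairs each); NE and NW pairs keep the colour
  # (7 x 7 = 49 each); symmetric doubling scales everything by 2.
  n <- 8
  frame <- matrix(((row(matrix(0, n, n)) + col(matrix(0, n, n))) %% 2) * 0.9 + 0.05, n)
  g <- build_glcm(matrix(TRUE, n, n), frame, 1, 32, c(0, 1))
  a <- floor(0.05 * 32) + 1          # bin 2
  b <- floor(0.95 * 32) + 1          # bin 31
  nz <- which(g$p > 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]),
                  c("2 2", "31 31", "2 31", "31 2"))
  total <- 2 * (56 + 56 + 49 + 49)
  p_cross <- 2 * (56 + 56) / total   # split over (a,b) and (b,a)
  p_same <- 2 * (49 + 49) / total
  m <- glcm_metrics(g)
  d <- abs(a - b)
  expect_equal(m$homogeneity, p_same + p_cross / (1 + d), tolerance = 1e-12)
  expect_equal(m$contrast_norm, p_cross * d^2 / 31^2, tolerance = 1e-12)
  expect_lt(m$correlation, 0)        # predominantly anti-correlated pairs
  # uniform p over all cells: energy = 1 / n_bins^2
  nb <- 8
  gu <- structure(list(p = matrix(1 / nb^2, nb, nb), n_pairs = 100,
                       n_bins = nb, distance_px = 1, symmetric = TRUE),
                  class = "er_glcm")
  expect_equal(glcm_metrics(gu)$energy, 1 / nb^2, tolerance = 1e-12)
})

test_that("the GLCM equals exhaustive pair enumeration on small random regions", {
  set.seed(42)
  for (trial in 1:5) {
    n <- sample(8:16, 1)
    frame <- matrix(runif(n * n), n)
    region <- matrix(runif(n * n) < 0.8, n)
    region[1, 1] <- TRUE; region[2, 1] <- TRUE
    d <- sample(1:2, 1)
    g <- build_glcm(region, frame, d, 16, c(0, 1))
    expect_equal(g$p, unclass(glcm_brute(region, frame, d, 16)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("metrics are invariant under 90-degree rotation of the region", {
  set.seed(7)
  frame <- matrix(runif(144), 12)
  region <- make_disc(5, pad = 1)[1:12, 1:12]
  m1 <- glcm_metrics(build_glcm(region, frame, 1, 16, c(0, 1)))
  frame_r <- t(frame)[, 12:1]                      # rotate 90 degrees
  region_r <- t(region)[, 12:1]
  m2 <- glcm_metrics(build_glcm(region_r, frame_r, 1, 16, c(0, 1)))
  expect_equal(m1$contrast_norm, m2$contrast_norm, tolerance = 1e-12)
  expect_equal(m1$energy, m2$energy, tolerance = 1e-12)
  expect_equal(m1$homogeneity, m2$homogeneity, tolerance = 1e-12)
})

test_that("aggregation modes agree on identical cisternae and pooled weights by size", {
  set.seed(9)
  labels <- matrix(0L, 20, 40)
  labels[4:16, 3:15] <- 1L
  labels[4:16, 22:34] <- 2L
  frame <- matrix(runif(800), 20)
  frame[labels == 2] <- frame[labels == 1]         # identical textures
  cis <- structure(list(labels = labels,
                        table = data.frame(id = 1:2)), class = "er_cisternae")
  m_mean <- aggregate_textures(cis, frame, "per_cisterna_mean", 1, 16, c(0, 1))
  m_pool <- aggregate_textures(cis, frame, "pooled", 1, 16, c(0, 1))
  expect_equal(m_mean$energy, m_pool$energy, tolerance = 1e-10)
  # one cisterna: both modes identical
  cis1 <- structure(list(labels = (labels == 1) + 0L,
                         table = data.frame(id = 1)), class = "er_cisternae")
  expect_equal(aggregate_textures(cis1, frame, "per_cisterna_mean", 1, 16)$homogeneity,
               aggregate_textures(cis1, frame, "pooled", 1, 16)$homogeneity,
               tolerance = 1e-12)
  # different textures and sizes: pooled lies between, nearer the larger
  labels2 <- matrix(0L, 30, 60)
  labels2[2:28, 2:40] <- 1L                        # large, smooth
  labels2[5:12, 45:56] <- 2L                       # small, rough
  f2 <- matrix(0.5, 30, 60)
  f2[labels2 == 2] <- runif(sum(labels2 == 2))
  cisL <- structure(list(labels = labels2, table = data.frame(id = 1:2)),
                    class = "er_cisternae")
  per <- attr(aggregate_textures(cisL, f2, "per_cisterna_mean", 1, 16), "per_cisterna")
  pool <- aggregate_textures(cisL, f2, "pooled", 1, 16)
  h <- sort(per$homogeneity)
  expect_gte(pool$homogeneity, h[1]); expect_lte(pool$homogeneity, h[2])
  ibig <- which.max(c(sum(labels2 == 1), sum(labels2 == 2)))
  expect_lt(abs(pool$homogeneity - per$homogeneity[ibig]),
            abs(pool$homogeneity - per$homogeneity[3 - ibig]))
  expect_error(build_glcm(matrix(FALSE, 4, 4), matrix(0, 4, 4), 1, 8))
})
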