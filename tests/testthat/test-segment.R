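# Phase-congruency enhancement, hysteresis skeleton, cisterna and polygon
# segmentation, shape metrics.

test_that("feature type is ridge-maximal, intensity independent, and lower on edges", {
  ridge <- make_ridge(41, 81, sigma = 2) + 1e-3
  ft1 <- phase_congruency_ft(ridge)
  crest <- ft1$ft[21, 20:60]
  flank <- ft1$ft[15, 20:60]
  expect_true(all(crest > flank))
  # doubling the input changes ft by < 1% away from the noise floor
  ft2 <- phase_congruency_ft(ridge * 2)
  on <- ft1$ft > 0 & ft2$ft > 0
  expect_lt(max(abs(ft1$ft[on] - ft2$ft[on])), 0.01)
  # a step edge responds at ~0.5, below a ridge crest (~1)
  step <- matrix(0, 41, 81); step[, 41:81] <- 1
  fts <- phase_congruency_ft(step)
  expect_lt(max(fts$ft[10:30, 41]), max(ft1$ft[21, 20:60]))
  expect_warning(phase_congruency_ft(matrix(1, 20, 20)), "constant")
})

test_that("hysteresis keeps lo-regions connected to hi seeds and thins to a centreline", {
  # uniform 0.4 field with an isolated 0.6 blob: only the blob's region
  ftm <- matrix(0.4, 30, 30)
  ftm[5:8, 5:8] <- 0.6
  ftm[20:23, 20:23] <- 0.45          # above lo but never reaches hi
  sk <- hysteresis_skeleton(ftm, lo = 0.3, hi = 0.5, hmin = 0)
  expect_true(any(sk$binary[5:8, 5:8]))
  expect_true(all(sk$binary))        # 0.4 field is 8-connected to the blob
  ftm2 <- matrix(0.1, 30, 30)
  ftm2[5:8, 5:8] <- 0.6
  ftm2[20:23, 20:23] <- 0.45
  sk2 <- hysteresis_skeleton(ftm2, 0.3, 0.5, hmin = 0)
  expect_true(any(sk2$binary[5:8, 5:8]))
  expect_false(any(sk2$binary[20:23, 20:23]))
  # 3-px-wide bar thins to its 1-px centreline
  bar <- matrix(0, 21, 40); bar[10:12, 5:35] <- 0.9
  sk3 <- hysteresis_skeleton(bar, 0.3, 0.5, hmin = 0)
  expect_true(all(which(sk3$pixels, arr.ind = TRUE)[, 1] == 11))
  nb <- sum(sk3$pixels)
  expect_gte(nb, 28); expect_lte(nb, 31)
})

test_that("shallow valleys are zeroed so appressed tubules stay separate", {
  # two parallel ridges merging at both ends; the enclosed valley is a
  # regional minimum of depth 0.04 < hmin = 0.05
  ftm <- matrix(0, 40, 60)
  ftm[15:25, 10:50] <- 0.76          # valley plateau
  ftm[15, 10:50] <- 0.8; ftm[25, 10:50] <- 0.8
  ftm[15:25, 10] <- 0.8; ftm[15:25, 50] <- 0.8
  with_h <- hysteresis_skeleton(ftm, 0.3, 0.5, hmin = 0.05)
  without_h <- hysteresis_skeleton(ftm, 0.3, 0.5, hmin = 0)
  # with suppression the binary region keeps the internal gap (a hole)
  holes_with <- sum((EBImage::fillHull(with_h$binary) > 0) & !with_h$binary)
  holes_without <- sum((EBImage::fillHull(without_h$binary) > 0) & !without_h$binary)
  expect_gt(holes_with, 50)
  expect_equal(holes_without, 0)
  # a deep valley (depth 0.46 > hmin) is untouched
  deep <- ftm; deep[16:24, 11:49] <- 0.34
  with_deep <- hysteresis_skeleton(deep, 0.3, 0.5, hmin = 0.05)
  expect_true(any(with_deep$binary[18:22, 20:40]))
})

test_that("skeletons are single-pixel wide and intensity invariant", {
  sc <- generate_network_scene(9, seed = 6)
  img <- guided_smooth(get_frame(sc$stack), 5)
  sk1 <- hysteresis_skeleton(phase_congruency_ft(img))
  m <- sk1$pixels
  blk <- m & rbind(m[-1, ], FALSE) & cbind(m[, -1], FALSE) &
    rbind(cbind(m[-1, -1], FALSE), FALSE)
  expect_false(any(blk))
  sk2 <- hysteresis_skeleton(phase_congruency_ft(img * 2))
  agree <- mean(sk1$pixels == sk2$pixels)
  expect_gt(agree, 0.999)
})

test_that("cisterna segmentation removes tubules, refines boundaries and filters by area", {
  # tubules only: empty set
  tb <- simulate_tubule(40, length_px = 50, with_sheet = FALSE, noise_sd = 0)
  cs <- segment_cisternae(tb$image, NULL, fwhm_max_px = 10,
                          min_area_um2 = 0.3, pixel_size_nm = 40)
  expect_equal(nrow(cs$table), 0)
  # a 2 x 2 um uniform square: one cisterna, area within 5%, square-like
  img <- matrix(0, 90, 90)
  img[21:70, 21:70] <- 0.35          # 50 px = 2 um at 40 nm
  img <- gauss_blur(img, 1.5)
  cs2 <- segment_cisternae(img, NULL, 10, 0.3, 40)
  expect_equal(nrow(cs2$table), 1)
  expect_lt(abs(cs2$table$area_um2 - 4) / 4, 0.05)
  expect_lt(abs(cs2$table$circularity - pi / 4), 0.12)
  expect_gt(cs2$table$solidity, 0.95)
  # a bright disc of ~0.2 um^2 (radius 6.3 px at 40 nm) is excluded
  dimg <- gauss_blur(make_disc(6, pad = 12) * 0.5, 1.5)
  cs3 <- segment_cisternae(dimg, NULL, 6, 0.3, 40)
  expect_equal(nrow(cs3$table), 0)
  expect_gte(nrow(cs3$puncta), 1)    # forwarded as a punctum candidate
})

test_that("polygonal regions are the enclosed complement components", {
  loop <- make_square_loop(20, pad = 6)
  msk <- matrix(TRUE, nrow(loop), ncol(loop))
  sk <- structure(list(pixels = loop), class = "er_skeleton")
  pg <- segment_polygons(sk, NULL, msk, pixel_size_nm = 1000)
  expect_equal(nrow(pg$table), 1)
  expect_equal(pg$table$area_um2, 18^2)   # interior of the 20-px loop
  # broken loop: region connects to the boundary, no polygon
  broken <- loop; broken[7, 10:14] <- FALSE
  pgb <- segment_polygons(structure(list(pixels = broken),
                                    class = "er_skeleton"), NULL, msk, 1000)
  expect_equal(nrow(pgb$table), 0)
})

test_that("shape metrics match analytic values for discs, ellipses and squares", {
  disc <- make_disc(15)
  m <- shape_metrics(disc, pixel_size_nm = 1000)
  expect_lt(abs(m$circularity - 1), 0.08)
  expect_lt(m$elongation, 0.05)
  expect_lt(m$roughness - 1, 0.08)
  ell <- make_ellipse(20, 10)
  me <- shape_metrics(ell, 1000)
  expect_lt(abs(me$elongation - 0.5), 0.05)
  expect_lt(abs(me$major_um / me$minor_um - 2), 0.15)
  sq <- matrix(FALSE, 30, 30); sq[8:23, 8:23] <- TRUE
  ms <- shape_metrics(sq, 1000)
  expect_equal(ms$solidity, 1, tolerance = 1e-6)
  expect_equal(ms$area_um2, 256)
  # single pixel: axis metrics flagged NaN
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  m1 <- shape_metrics(one, 1000)
  expect_true(is.nan(m1$major_um))
})
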