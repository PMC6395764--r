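# Optical flow estimation and motion summaries.

analytic_flow <- function(vy, vx, pixel_size_nm = 1000) {
  structure(list(vy = vy, vx = vx, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = 1), class = "er_flow")
}

test_that("identical frames give zero flow and swapped frames negate it", {
  set.seed(4)
  f1 <- gauss_blur(matrix(runif(96 * 96), 96), 2)
  z <- farneback_flow(f1, f1, 40, 0.41)
  expect_lt(max(abs(z$vx)), 1e-6)
  expect_lt(max(abs(z$vy)), 1e-6)
  f2 <- mat_shift_test(f1, 0, 2)
  a <- farneback_flow(f1, f2, 40, 0.41)
  b <- farneback_flow(f2, f1, 40, 0.41)
  inner <- 20:76
  expect_lt(median(abs(a$vx[inner, inner] + b$vx[inner, inner])),
            0.05 * median(abs(a$vx[inner, inner])))
  expect_error(farneback_flow(f1, f1, 40, NA), "frame_interval")
})

test_that("imposed uniform translations on fixtures are recovered within 10%", {
  sc <- generate_network_scene(9, seed = 5, noise_sd = 0.01)
  for (shift_px in c(0.5, 3)) {
    v <- shift_px * 40 / 1000 / 0.41
    an <- animate_scene(sc$truth, n_frames = 2, translation_um_s = c(0, v),
                        seed = 2)
    fl <- farneback_flow(get_frame(an$stack, 1), get_frame(an$stack, 2),
                         40, 0.41)
    sk <- an$truth$skeleton_px[[1]]
    tru <- an$truth$flow_um_s[[1]]
    sp_t <- sqrt(tru[, , 1][sk]^2 + tru[, , 2][sk]^2)
    sp_e <- sqrt(fl$vy[sk]^2 + fl$vx[sk]^2)
    expect_lt(median(abs(sp_e - sp_t) / sp_t), 0.10)
  }
})

test_that("flow summaries satisfy the coherence definitions and the triangle inequality", {
  n <- 10
  all_right <- analytic_flow(matrix(0, n, n), matrix(1, n, n))
  s <- summarize_flow(all_right, matrix(TRUE, n, n))
  expect_equal(s$scalar_mean, 1)
  expect_equal(s$vector_mean, 1)
  expect_equal(s$coherence, 1)
  half <- matrix(1, n, n); half[, 1:(n / 2)] <- -1
  opp <- summarize_flow(analytic_flow(matrix(0, n, n), half), matrix(TRUE, n, n))
  expect_equal(opp$scalar_mean, 1)
  expect_equal(opp$vector_mean, 0, tolerance = 1e-12)
  expect_equal(opp$coherence, 0, tolerance = 1e-12)
  single <- summarize_flow(all_right, cbind(3, 4))
  expect_equal(single$scalar_mean, single$vector_mean)
  expect_equal(single$max_speed, 1)
  expect_error(summarize_flow(all_right, matrix(FALSE, n, n)), "empty")
  # property: vector mean <= scalar mean on random fields
  set.seed(11)
  for (i in 1:20) {
    fl <- analytic_flow(matrix(rnorm(100), 10), matrix(rnorm(100), 10))
    sm <- summarize_flow(fl, matrix(TRUE, 10, 10))
    expect_lte(sm$vector_mean, sm$scalar_mean + 1e-12)
    expect_gte(sm$coherence, 0); expect_lte(sm$coherence, 1)
  }
})

test_that("divergence and curl match analytic fields", {
  n <- 21
  ctr <- (n + 1) / 2
  yy <- matrix(rep(seq_len(n), n), n) - ctr
  xx <- t(yy)
  px_um <- 1                        # pixel_size_nm = 1000
  c0 <- 0.1
  radial <- analytic_flow(vy = c0 * yy, vx = c0 * xx)
  dc <- divergence_curl(radial)
  inner <- 3:(n - 2)
  expect_equal(unique(round(as.vector(dc$div[inner, inner]), 10)), 2 * c0)
  expect_equal(unique(round(as.vector(dc$curl[inner, inner]), 10)), 0)
  omega <- 0.05
  rot <- analytic_flow(vy = omega * xx, vx = -omega * yy)
  dcr <- divergence_curl(rot)
  expect_equal(unique(round(as.vector(dcr$div[inner, inner]), 10)), 0)
  expect_equal(unique(round(as.vector(dcr$curl[inner, inner]), 10)), 2 * omega)
  uni <- analytic_flow(matrix(0.3, n, n), matrix(0.1, n, n))
  dcu <- divergence_curl(uni)
  expect_true(all(dcu$div[inner, inner] == 0))
  expect_true(all(dcu$curl[inner, inner] == 0))
})

test_that("lognormal speed fits recover parameters and handle zeros", {
  set.seed(21)
  mu <- -1; sigma <- 0.5; n <- 1e4
  sp <- exp(rnorm(n, mu, sigma))
  fit <- fit_speed_distribution(sp)
  se <- sigma / sqrt(n)
  expect_lt(abs(fit$mu - mu), 3 * se)
  expect_equal(fit$back_transformed_mean, exp(fit$mu))
  allsame <- fit_speed_distribution(rep(0.26, 50))
  expect_equal(allsame$sigma, 0)
  expect_equal(allsame$back_transformed_mean, 0.26, tolerance = 1e-12)
  withz <- fit_speed_distribution(c(rep(0, 5), sp[1:20]))
  expect_equal(withz$n_zero_excluded, 5)
  expect_error(fit_speed_distribution(rep(0.1, 5)), "at least 10")
})
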