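# Traces along tubules, bulge/constriction detection, boundary profiles.

make_trace <- function(x, position_um = NULL, ch2 = NULL) {
  n <- length(x)
  if (is.null(position_um)) position_um <- seq(0, by = 0.04, length.out = n)
  inten <- if (is.null(ch2)) matrix(x, ncol = 1) else cbind(x, ch2)
  structure(list(edge_id = 1L, position_um = position_um,
                 intensity = inten,
                 path = cbind(rep(5, n), seq_len(n))),
            class = "er_trace")
}

test_that("traces along straight tubes are flat and bulges create interior maxima", {
  img <- make_ridge(31, 71, sigma = 2)
  sk <- matrix(FALSE, 31, 71); sk[16, 6:66] <- TRUE
  g <- skeleton_to_graph(sk, 40, prune_spurs = FALSE)
  tr <- extract_trace(g, g$edges$id[1], img, normal_halfwidth_px = 5)
  expect_true(all(diff(tr$position_um) > 0))
  expect_lt(stats::sd(tr$intensity[, 1]) / mean(tr$intensity[, 1]), 0.02)
  # one Gaussian bulge: a single interior maximum
  amp <- 1 + 0.5 * exp(-(seq_len(71) - 36)^2 / (2 * 3^2))
  img2 <- make_ridge(31, 71, sigma = 2, amp = amp)
  tr2 <- extract_trace(g, g$edges$id[1], img2, normal_halfwidth_px = 5)
  pk <- find_peaks_troughs(tr2, 0.05, 0.03)
  expect_equal(sum(pk$events$kind == "peak"), 1)
  # two channels: aligned traces of equal length
  tr3 <- extract_trace(g, g$edges$id[1], list(img, img2), 5)
  expect_equal(ncol(tr3$intensity), 2)
  expect_equal(nrow(tr3$intensity), length(tr3$position_um))
})

test_that("a sinusoid of 10% amplitude yields alternating peaks and troughs at 1 um spacing", {
  pos <- seq(0, 5, by = 0.02)
  x <- 1 + 0.1 * sin(2 * pi * pos)          # period 1 um over 5 um
  tr <- make_trace(x, pos)
  pk <- find_peaks_troughs(tr, 0.05, 0.03)
  expect_equal(sum(pk$events$kind == "peak"), 5)
  expect_equal(sum(pk$events$kind == "trough"), 5)
  expect_equal(pk$peak_spacing_um, 1, tolerance = 0.03)
  # peaks and troughs alternate along the trace
  kinds <- pk$events$kind
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  # events are invariant to uniform intensity scaling
  pk2 <- find_peaks_troughs(make_trace(7 * x, pos), 0.05, 0.03)
  expect_equal(pk2$events$index, pk$events$index)
  # a bump of 2% prominence is rejected at the 3% threshold
  y <- rep(1, 200); y[100] <- 1.02 * 1      # 2% above its surroundings
  pk3 <- find_peaks_troughs(make_trace(y), 0.05, 0.03)
  expect_equal(nrow(pk3$events), 0)
  # flat trace: no events
  expect_equal(nrow(find_peaks_troughs(make_trace(rep(2, 50)))$events), 0)
})

test_that("k imposed bulges above threshold are recovered exactly", {
  for (k in c(2, 4)) {
    centers <- seq(15, 105, length.out = k)
    amp <- 1 + 0.4 * Reduce(`+`, lapply(centers, function(c0)
      exp(-(seq_len(121) - c0)^2 / (2 * 2.5^2))))
    img <- make_ridge(31, 121, sigma = 2, amp = amp)
    sk <- matrix(FALSE, 31, 121); sk[16, 4:118] <- TRUE
    g <- skeleton_to_graph(sk, 40, prune_spurs = FALSE)
    tr <- extract_trace(g, g$edges$id[1], img, 5)
    pk <- find_peaks_troughs(tr, 0.05, 0.03)
    expect_equal(sum(pk$events$kind == "peak"), k)
  }
})

test_that("dual-channel ratios and correlations capture in-phase and anti-phase markers", {
  pos <- seq(0, 5, by = 0.02)
  x <- 1 + 0.2 * sin(2 * pi * pos)
  tr_same <- make_trace(x, pos, ch2 = x)
  ev <- find_peaks_troughs(tr_same, 0.05, 0.03)
  dc <- dual_channel_ratio(tr_same, ev)
  expect_equal(dc$correlation, 1)
  expect_true(all(abs(dc$ratio - 1) < 1e-12))
  tr_anti <- make_trace(x, pos, ch2 = max(x) - x)
  expect_equal(dual_channel_ratio(tr_anti, ev)$correlation, -1)
  # reticulon-like anti-phase fixture: troughs of ch1 at peaks of ch2
  ch2 <- 1 + 0.2 * sin(2 * pi * pos + pi)
  expect_lt(dual_channel_ratio(make_trace(x, pos, ch2 = ch2), ev)$correlation,
            -0.9)
  # zero denominator flagged NaN
  tr0 <- make_trace(x, pos, ch2 = rep(0, length(x)))
  expect_true(all(is.nan(dual_channel_ratio(tr0, ev)$ratio)))
})

test_that("boundary profiles step at the edge and distinguish rim-enriched markers", {
  disc <- make_disc(12, pad = 8)
  flat <- disc * 0.8
  bp <- boundary_profile(disc, flat, n_bins = 5)
  inner <- bp$mean_intensity[bp$bin <= 0]
  outer <- bp$mean_intensity[bp$bin > 0]
  expect_true(all(abs(inner - 0.8) < 1e-9))
  expect_true(all(outer == 0))
  # bright rim: maximum in bins -1..0
  rim <- disc & !make_disc_inner(disc, 2)
  rim_img <- disc * 0.2 + rim * 0.6
  bpr <- boundary_profile(disc, rim_img, n_bins = 5)
  expect_true(which.max(bpr$mean_intensity) %in% which(bpr$bin %in% c(-1, 0)))
  # two co-localised markers give identical normalised profiles
  img1 <- disc * 0.5; img2 <- disc * 1.5
  b1 <- boundary_profile(disc, img1, 5)$mean_intensity
  b2 <- boundary_profile(disc, img2, 5)$mean_intensity
  expect_equal(b1 / max(b1), b2 / max(b2), tolerance = 1e-12)
})
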