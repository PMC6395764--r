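# Persistency mapping of static elements.

test_that("intensity persistency scores static structure at full and transient at zero", {
  frame <- gauss_blur(make_disc(4, pad = 8) * 0.8, 1)
  arr <- array(0, c(nrow(frame), ncol(frame), 1, 15))
  for (t in 1:15) arr[, , 1, t] <- frame
  st <- er_stack(arr, 40, frame_interval_s = 0.41)
  p <- intensity_persistency(st, lag_frames = 12)
  expect_true(all(p$score[p$occupancy] == 1))
  # structure present in one frame only: AND mask empty, not persistent
  arr2 <- array(0, c(nrow(frame), ncol(frame), 1, 15))
  arr2[, , 1, 7] <- frame
  arr2[5, 5, 1, ] <- 0.05             # keep frames non-constant
  st2 <- er_stack(arr2, 40, frame_interval_s = 0.41)
  p2 <- intensity_persistency(st2, lag_frames = 12)
  expect_true(all(p2$score[frame > 0.4] == 0))
  expect_error(intensity_persistency(st, lag_frames = 20), "lag")
})

test_that("structure persistency counts occupancy (sum) or endpoint presence (diff)", {
  base <- matrix(FALSE, 30, 30); base[15, 5:25] <- TRUE
  static <- replicate(12, base, simplify = FALSE)
  ps <- structure_persistency(static, dilate_px = 2, mode = "sum",
                              frame_interval_s = 0.41)
  expect_true(all(ps$tubule[base] == 12))
  expect_equal(max(ps$tubule_s), 12 * 0.41)
  # skeleton shifting perpendicular by more than twice the dilation each
  # frame: occupancy windows never overlap, counts <= 1
  moving <- lapply(0:11, function(k) {
    m <- matrix(FALSE, 70, 40); m[5 + 5 * k, 5:35] <- TRUE; m
  })
  pm <- structure_persistency(moving, dilate_px = 2, mode = "sum")
  expect_lte(max(pm$tubule), 1)
  # diff mode depends only on the endpoints
  blink <- static; blink[[6]] <- matrix(FALSE, 30, 30)
  pd <- structure_persistency(blink, dilate_px = 2, mode = "diff")
  expect_true(all(pd$tubule[base]))    # present at start and end
  # sum mode is invariant to frame order
  perm <- sample(length(static))
  ps2 <- structure_persistency(static[perm], dilate_px = 2, mode = "sum")
  expect_identical(ps$tubule, ps2$tubule)
  # occupancy counts never decrease with dilation radius
  p1 <- structure_persistency(moving, dilate_px = 1, mode = "sum")$tubule
  p3 <- structure_persistency(moving, dilate_px = 3, mode = "sum")$tubule
  expect_true(all(p3 >= p1))
})

test_that("persistent nodes are found at anchors and not at transient pixels", {
  sc <- generate_network_scene(6, seed = 31, cisterna_fraction = 0)
  nodes <- sc$truth$graph$nodes
  anchors <- cbind(nodes$y[5], nodes$x[5])
  an <- animate_scene(sc$truth, n_frames = 20,
                      translation_um_s = c(0.1, 0.1),
                      anchor_px = anchors, seed = 4)
  pn <- persistent_nodes(an$stack, sigma_px = 2.5, threshold = 0.4)
  expect_gt(nrow(pn), 0)
  d <- min(sqrt((pn$y - anchors[1, 1])^2 + (pn$x - anchors[1, 2])^2))
  expect_lte(d, 2)
  # a pixel occupied in fewer than half the frames has background median
  arr <- array(0.01, c(20, 20, 1, 9))
  arr[10, 10, 1, 1:4] <- 1
  arr[4, 4, 1, ] <- 0.9               # stable reference maximum
  st <- er_stack(arr, 40, frame_interval_s = 0.41)
  pn2 <- persistent_nodes(st, sigma_px = 1, threshold = 0.4)
  expect_true(all(sqrt((pn2$y - 10)^2 + (pn2$x - 10)^2) > 2))
  # threshold at 1 keeps only the global maximum
  pn3 <- persistent_nodes(st, sigma_px = 1, threshold = 1)
  expect_lte(nrow(pn3), 1)
  expect_error(persistent_nodes(er_stack(arr[, , , 1:2, drop = FALSE], 40,
                                         frame_interval_s = 0.41), 1, 0.4),
               "3 frames")
})

test_that("persistency histograms integrate to one", {
  vals <- c(rep(4.92, 30), runif(20, 0, 4.92))
  h <- persistency_histogram(vals, breaks = 12)
  widths <- diff(range(vals)) / 12
  expect_equal(sum(h$density * diff(h$mid)[1]), 1, tolerance = 0.01)
  # all elements fully persistent: unit mass at the window duration
  h2 <- persistency_histogram(rep(4.92, 25), breaks = c(0, 2.5, 4.92))
  expect_equal(h2$counts[2], 25)
})
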