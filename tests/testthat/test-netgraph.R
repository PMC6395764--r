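# Skeleton-to-graph conversion and graph attributes.

test_that("paths, junctions and free ends map to the expected graph", {
  sk <- matrix(FALSE, 12, 16); sk[6, 4:13] <- TRUE
  g <- skeleton_to_graph(sk, 40, prune_spurs = FALSE)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$nodes$type, "free_end")
  expect_equal(g$edges$length_um, 9 * 40 / 1000, tolerance = 1e-9)
  # symmetric Y: one junction, three edges, 120 degree branch angles
  sk <- matrix(FALSE, 41, 41)
  for (ang in c(90, 210, 330)) {
    th <- ang * pi / 180
    for (r in 0:16)
      sk[21 - round(r * sin(th)), 21 + round(r * cos(th))] <- TRUE
  }
  g <- node_properties(skeleton_to_graph(sk, 40, prune_spurs = FALSE))
  expect_equal(sum(g$nodes$type == "junction"), 1)
  expect_equal(nrow(g$edges), 3)
  ang <- g$nodes$branch_angles_deg[[which(g$nodes$type == "junction")]]
  expect_equal(length(ang), 3)
  expect_true(all(abs(ang - 120) <= 2))
  # two collinear arms across a degree-2 path: 180 degrees at a free end? no;
  # measure collinearity via a straight path with a forced midpoint node
  skl <- matrix(FALSE, 9, 31); skl[5, 3:29] <- TRUE
  gl <- node_properties(skeleton_to_graph(skl, 40, prune_spurs = FALSE))
  expect_true(all(vapply(gl$nodes$branch_angles_deg, length, integer(1)) == 0))
  # empty skeleton: empty graph
  g0 <- skeleton_to_graph(matrix(FALSE, 4, 4), 40)
  expect_equal(nrow(g0$nodes), 0); expect_equal(nrow(g0$edges), 0)
})

test_that("duplicate edges and self-loops resolve to a simple graph with resolver nodes", {
  loop <- make_square_loop(12, pad = 4)
  g <- skeleton_to_graph(loop, 40, prune_spurs = FALSE)
  g2 <- resolve_duplicates(g)
  key <- paste(pmin(g2$edges$from, g2$edges$to), pmax(g2$edges$from, g2$edges$to))
  expect_false(any(duplicated(key)))
  expect_false(any(g2$edges$from == g2$edges$to))
  expect_true(all(g2$nodes$degree[g2$nodes$type == "resolver"] == 2))
  expect_equal(sum(g2$nodes$degree), 2 * nrow(g2$edges))      # handshake
  # a simple graph passes through unchanged
  sk <- matrix(FALSE, 12, 16); sk[6, 4:13] <- TRUE
  gs <- skeleton_to_graph(sk, 40)
  expect_equal(nrow(resolve_duplicates(gs)$edges), nrow(gs$edges))
})

test_that("extracted topology matches the generator's planar truth graph", {
  contracted <- function(V, E, deg2) c(V - deg2, E - deg2)
  for (s in c(1, 3, 5, 6, 9, 10)) {
    sc <- generate_network_scene(9, seed = s, noise_sd = 0,
                                 cisterna_fraction = 0)
    sk <- sc$truth$skeleton_px[[1]]
    g <- resolve_duplicates(skeleton_to_graph(sk, 40))
    ex <- contracted(nrow(g$nodes), nrow(g$edges), sum(g$nodes$degree == 2))
    tg <- sc$truth$graph
    degt <- table(factor(c(tg$edges$from, tg$edges$to), levels = tg$nodes$id))
    tr <- contracted(nrow(tg$nodes), nrow(tg$edges), sum(degt == 2))
    # skeleton discretisation can split an X crossing into two T junctions,
    # so allow +/-2; the handshake lemma must hold exactly
    expect_lte(abs(ex[1] - tr[1]), 2)
    expect_lte(abs(ex[2] - tr[2]), 2)
    expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
    # every skeleton pixel belongs to an edge path or a node
    cov <- matrix(FALSE, nrow(sk), ncol(sk))
    for (p in g$paths) if (nrow(p)) cov[p] <- TRUE
    for (np in g$node_pixels) cov[np] <- TRUE
    expect_equal(sum(sk & !cov), 0)
    # length conservation within the node-clustering bound
    path_len <- sum(sk) * 40 / 1000
    tot <- sum(g$edges$length_um)
    expect_lt(abs(tot - path_len), nrow(g$nodes) * 5 * 40 / 1000)
  }
})

test_that("centre-weighted width excludes junction pixels and beats the naive mean", {
  # a cross of two tubes: junction widths are inflated by overlap
  img <- matrix(0, 61, 61)
  sk <- matrix(FALSE, 61, 61)
  tube <- function(img, horizontal) {
    for (i in 6:56) {
      pos <- if (horizontal) cbind(31 + (-8:8), i) else cbind(i, 31 + (-8:8))
      img[pos] <- img[pos] + exp(-(-8:8)^2 / (2 * 1.5^2))
    }
    img
  }
  img <- tube(img, TRUE); img <- tube(img, FALSE)
  sk[31, 6:56] <- TRUE; sk[6:56, 31] <- TRUE
  sk[31, 31] <- TRUE
  wm <- width_map(img, sk, 40, er_calibration())
  g <- skeleton_to_graph(sk, 40, prune_spurs = FALSE)
  g <- centre_weighted_width(g, wm)
  long <- which(g$edges$n_px > 10)
  # true single-tube intensity gives some radius r0; at the junction the
  # overlap doubles I_t so the naive mean is biased upward
  expect_true(all(g$edges$centre_width_nm[long] <=
                    g$edges$mean_width_nm[long] + 1e-9))
  expect_false(any(g$edges$centre_fallback[long]))
  # short spur falls back to the unweighted mean, flagged
  sk2 <- matrix(FALSE, 21, 21); sk2[11, 3:18] <- TRUE; sk2[8:10, 11] <- TRUE
  wm2 <- width_map(make_ridge(21, 21, 2), sk2, 40, er_calibration())
  g2 <- centre_weighted_width(skeleton_to_graph(sk2, 40, prune_spurs = FALSE), wm2)
  expect_true(any(g2$edges$centre_fallback))
})

test_that("cisternae attach as centroid nodes wired to boundary tubules", {
  sc <- generate_network_scene(9, seed = 13, noise_sd = 0,
                               cisterna_fraction = 0.3)
  img <- get_frame(sc$stack)
  sk <- structure(list(pixels = sc$truth$skeleton_px[[1]]),
                  class = "er_skeleton")
  cis <- segment_cisternae(img, sk, fwhm_max_px = 10, min_area_um2 = 0.3,
                           pixel_size_nm = 40)
  g <- skeleton_to_graph(sk, 40)
  g <- centre_weighted_width(g, width_map(img, sk, 40, er_calibration(),
                                          cisternae = cis))
  g1 <- attach_cisternae(g, cis, img)
  if (nrow(cis$table) > 0) {
    cn <- g1$nodes[g1$nodes$type == "cisterna", ]
    expect_equal(nrow(cn), nrow(cis$table))
    expect_true(all(g1$edges$is_cisterna_internal[
      g1$edges$from %in% cn$id | g1$edges$to %in% cn$id]))
    # uniform-intensity cisterna: centroid equals the geometric centroid
    id1 <- cis$table$id[1]
    flat <- matrix(1, nrow(img), ncol(img))
    g2 <- attach_cisternae(g, cis, flat)
    c2 <- g2$nodes[g2$nodes$type == "cisterna", ][1, ]
    pts <- which(cis$labels == id1, arr.ind = TRUE)
    expect_equal(c2$y, mean(pts[, 1]), tolerance = 1e-9)
    expect_equal(c2$x, mean(pts[, 2]), tolerance = 1e-9)
  }
  # no cisternae: unchanged
  empty <- segment_cisternae(matrix(0.01, 40, 40) + make_ridge(40, 40, 1.5),
                             NULL, 10, 0.3, 40)
  g3 <- attach_cisternae(g, empty, img)
  expect_equal(nrow(g3$edges), nrow(g$edges))
})
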