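# Synthetic scene generator and external formats.

test_that("scene generation is deterministic and validates its inputs", {
  a <- generate_network_scene(6, seed = 11)
  b <- generate_network_scene(6, seed = 11)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$skeleton_px, b$truth$skeleton_px)
  c <- generate_network_scene(6, seed = 12)
  expect_false(identical(a$stack$data, c$stack$data))
  expect_error(generate_network_scene(0, cisterna_fraction = 0), "n_polygons")
  expect_error(generate_network_scene(4, pixel_size_nm = 10))
})

test_that("a noise-free straight tubule renders symmetric about its axis with the peak on the truth skeleton", {
  tb <- simulate_tubule(30, length_px = 40, noise_sd = 0, with_sheet = FALSE)
  y0 <- which(rowSums(tb$skeleton) > 0)
  # row symmetry about the axis
  for (d in 1:5)
    expect_equal(tb$image[y0 + d, ], tb$image[y0 - d, ], tolerance = 1e-10)
  # intensity maximum of every interior cross-section within 1 px of truth
  xs <- which(colSums(tb$skeleton) > 0)
  xs <- xs[xs > min(xs) + 2 & xs < max(xs) - 2]
  peak_rows <- vapply(xs, function(x) which.max(tb$image[, x]), integer(1))
  expect_true(all(abs(peak_rows - y0) <= 1))
})

test_that("truth invariants hold: single-pixel skeleton, radii on skeleton only", {
  sc <- generate_network_scene(9, seed = 5)
  sk <- sc$truth$skeleton_px[[1]]
  blk <- sk & rbind(sk[-1, ], FALSE) & cbind(sk[, -1], FALSE) &
    rbind(cbind(sk[-1, -1], FALSE), FALSE)
  expect_false(any(blk))   # no 2x2 block fully set
  rad <- sc$truth$tubule_radius_nm[[1]]
  expect_true(all(is.na(rad[!sk])))
  expect_true(all(rad[sk] > 0, na.rm = TRUE))
})

test_that("animation imposes the stated displacement and honours anchors", {
  sc <- generate_network_scene(4, seed = 2, cisterna_fraction = 0,
                               frame_interval_s = 0.5)
  # 1 um/s at 0.5 s and 40 nm px = 12.5 px/frame
  an <- animate_scene(sc$truth, n_frames = 3, translation_um_s = c(0, 1),
                      seed = 1)
  fl <- an$truth$flow_um_s[[1]]
  expect_equal(unique(as.vector(fl[, , 2])), 1)   # vx = 1 um/s everywhere
  expect_equal(unique(as.vector(fl[, , 1])), 0)
  expect_equal(1 * 1000 / 40 * 0.5, 12.5)         # px/frame bookkeeping
  # zero translation, zero jitter (noise-free): identical frames, zero flow
  sc0 <- generate_network_scene(4, seed = 2, cisterna_fraction = 0,
                                noise_sd = 0, frame_interval_s = 0.5)
  an0 <- animate_scene(sc0$truth, n_frames = 3, translation_um_s = c(0, 0),
                       seed = 1)
  expect_identical(an0$stack$data[, , 1, 1], an0$stack$data[, , 1, 3])
  expect_true(all(an0$truth$flow_um_s[[1]] == 0))
  # anchors pin the flow to zero locally while the far field moves
  nodes <- sc$truth$graph$nodes
  ctr <- which.min((nodes$y - mean(nodes$y))^2 + (nodes$x - mean(nodes$x))^2)
  anchors <- matrix(c(nodes$y[ctr], nodes$x[ctr]), 1)
  ana <- animate_scene(sc$truth, n_frames = 3, translation_um_s = c(0, 0.5),
                       anchor_px = anchors, seed = 1)
  fl <- ana$truth$flow_um_s[[1]]
  ay <- round(anchors[1, 1]); ax <- round(anchors[1, 2])
  expect_equal(fl[ay, ax, 2], 0)
  expect_gt(fl[2, 2, 2], 0.4)   # far corner moves at full speed
  # excessive translation rejected
  expect_error(animate_scene(sc$truth, 2, translation_um_s = c(0, 50)),
               "half the field")
})

test_that("total truth skeleton length is conserved under pure translation", {
  sc <- generate_network_scene(6, seed = 8, cisterna_fraction = 0)
  an <- animate_scene(sc$truth, n_frames = 4, translation_um_s = c(0.05, 0.1),
                      seed = 3)
  counts <- vapply(an$truth$skeleton_px, sum, integer(1))
  expect_true(max(counts) - min(counts) <= 0.03 * max(counts))
})

test_that("TIFF stacks round-trip with metadata from config", {
  sc <- generate_network_scene(4, seed = 3)
  tf <- tempfile(fileext = ".tif")
  write_stack(sc$stack, tf)
  rd <- read_stack(tf, list(pixel_size_nm = 40, frame_interval_s = 0.41))
  expect_equal(dim(rd$data)[1:2], dim(sc$stack$data)[1:2])
  expect_equal(rd$data[, , 1, 1], sc$stack$data[, , 1, 1] / sc$stack$max_value,
               tolerance = 1e-4)  # 16-bit quantisation
  expect_error(read_stack(tempfile(), list(pixel_size_nm = 40)), "not found")
  expect_error(read_stack(tf, list()), "pixel_size_nm")
  # multi-page declared as t x c
  pages <- replicate(6, matrix(runif(64), 8), simplify = FALSE)
  tf2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, tf2, bits.per.sample = 16L)
  rd2 <- read_stack(tf2, list(pixel_size_nm = 40, n_channels = 2,
                              frame_interval_s = 0.41))
  expect_equal(dim(rd2$data), c(8L, 8L, 2L, 3L))
})

test_that("write_results produces stable, deterministic files and GraphML round-trips", {
  sc <- generate_network_scene(6, seed = 4, noise_sd = 0)
  g <- resolve_duplicates(skeleton_to_graph(sc$truth$skeleton_px[[1]], 40))
  d1 <- tempfile(); d2 <- tempfile()
  write_results(g, config = er_config(), out_dir = d1)
  write_results(g, config = er_config(), out_dir = d2)
  for (f in c("nodes.csv", "edges.csv", "cisternae.csv", "polygons.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ig <- read_graphml(file.path(d1, "graph.graphml"))
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  # empty graph: headers only
  g0 <- skeleton_to_graph(matrix(FALSE, 5, 5), 40)
  d0 <- tempfile()
  write_results(g0, out_dir = d0)
  expect_equal(length(readLines(file.path(d0, "edges.csv"))), 1L)
})
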