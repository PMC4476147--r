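test_that("two edges give one pair in exactly one bin", {
  e <- as_edge_list(data.frame(x = c(28, 36), y = c(30, 34),
                               theta = c(0.5, 1.1), scale_index = c(2, 3),
                               amplitude = c(1, 2), phase = 0),
                    image_shape = c(64L, 64L))
  h <- cooc_histogram(e)
  expect_equal(h$n_pairs, 1L)
  expect_equal(sum(h$w > 0), 1L)
  expect_equal(sum(h$w), 2)   # amplitude product weighting
  h_u <- cooc_histogram(e, weighting = "uniform")
  expect_equal(sum(h_u$w), 1)
})

test_that("fewer than two masked edges give an empty histogram, not an error", {
  e <- as_edge_list(data.frame(x = 30, y = 30, theta = 0, scale_index = 1,
                               amplitude = 1, phase = 0),
                    image_shape = c(64L, 64L))
  h <- cooc_histogram(e)
  expect_equal(h$n_pairs, 0L)
  expect_equal(sum(h$w), 0)
  expect_error(chevron_map(h), "no pairs")
})

test_that("collinear edges put all angular mass in the (0, 0) chevron cell", {
  h <- cooc_histogram(collinear_edges(n = 9))
  expect_gt(h$n_pairs, 0)
  cm <- chevron_map(h)
  expect_equal(sum(cm$map), 1)
  # zero is a bin edge, so values within rounding of 0 may land on either
  # side: all mass sits in the 2 x 2 block of cells adjacent to (0, 0)
  i0 <- findInterval(0, cm$psi_edges)
  j0 <- findInterval(0, cm$theta_edges)
  expect_equal(sum(cm$map[c(i0 - 1, i0), c(j0 - 1, j0)]), 1)
  amax <- as.integer(arrayInd(which.max(cm$map), dim(cm$map)))
  expect_true(amax[1] %in% c(i0 - 1, i0) && amax[2] %in% c(j0 - 1, j0))
})

test_that("circle tangents concentrate at psi = 0 across the theta axis", {
  # odd count: no antipodal (exactly parallel, psi = -pi/2) tangent pairs
  e <- circle_tangent_edges(n = 13, radius = 20)
  h <- cooc_histogram(e)
  expect_gt(h$n_pairs, 0)
  cm <- chevron_map(h)$map
  i0 <- findInterval(0, h$psi_edges)
  # all mass in the psi rows adjacent to 0
  expect_equal(sum(cm[c(i0 - 1, i0), ]), 1)
  # and spread over more than one theta bin (distinct tangent separations)
  expect_gt(sum(colSums(cm[c(i0 - 1, i0), ]) > 0), 1)
  # oracle: per-pair geometry says every binned pair has |psi| ~ 0
  idx <- t(utils::combn(nrow(e), 2))
  g <- pair_geometry(e[idx[, 1], ], e[idx[, 2], ])
  expect_lt(max(abs(g$psi)), 1e-9)
})

test_that("n_pairs equals m(m-1)/2 when every pair is in range", {
  # compact cluster, same scale: all distances within [2, mask_radius]
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  e <- as_edge_list(data.frame(
    x = 31.5 + 8 * cos(ang), y = 31.5 + 8 * sin(ang),
    theta = runif(8, 0, pi), scale_index = 2, amplitude = 1, phase = 0),
    image_shape = c(64L, 64L))
  h <- cooc_histogram(e, weighting = "uniform")
  expect_equal(h$n_pairs, 8L * 7L / 2L)
  expect_equal(h$n_dropped, 0L)
  expect_equal(sum(h$w), choose(8, 2))
})

test_that("the histogram is invariant to relabeling and rigid motions", {
  e <- random_edges(n = 50, seed = 3)
  h <- cooc_histogram(e)
  # reference symmetry / order independence: shuffle the rows
  set.seed(1)
  e2 <- e[sample(nrow(e)), ]
  attributes(e2)[c("image_shape", "mask_radius")] <-
    attributes(e)[c("image_shape", "mask_radius")]
  class(e2) <- class(e)
  h2 <- cooc_histogram(e2)
  expect_equal(h2$w, h$w)

  # translation (within the mask): shift positions and the mask center
  # equally by translating the whole frame
  sh <- attr(e, "image_shape")
  e3 <- e; e3$x <- e$x + 5; e3$y <- e$y + 4
  e3 <- as_edge_list(e3, image_shape = sh + c(10L, 10L))
  e3 <- mask_edges(e3, mask_radius = 1e6)  # no masking either side
  e0 <- mask_edges(e, mask_radius = 1e6)
  b <- cooc_binning(d_range = c(2, 28.8))
  expect_equal(cooc_histogram(e3, b)$w, cooc_histogram(e0, b)$w)

  # global rotation of positions and orientations (disc-limited so the
  # rotated frame stays inside the image)
  ed <- mask_edges(e, 24)
  phi0 <- 0.37
  cx <- 31.5; cy <- 31.5
  e4 <- data.frame(
    x = cx + cos(phi0) * (ed$x - cx) - sin(phi0) * (ed$y - cy),
    y = cy + sin(phi0) * (ed$x - cx) + cos(phi0) * (ed$y - cy),
    theta = (ed$theta + phi0) %% pi, scale_index = ed$scale_index,
    amplitude = ed$amplitude, phase = ed$phase)
  e4 <- mask_edges(as_edge_list(e4, image_shape = sh), mask_radius = 1e6)
  ed0 <- mask_edges(ed, mask_radius = 1e6)
  expect_equal(cooc_histogram(e4, b)$w, cooc_histogram(ed0, b)$w,
               tolerance = 1e-12)
})

test_that("scale-normalized distances make the histogram rescaling-invariant", {
  e <- random_edges(n = 40, seed = 6, scales = 1:3)
  b <- cooc_binning(d_range = c(0.25, 8), d_scale = "normalized")
  e0 <- mask_edges(e, mask_radius = 1e6)
  h0 <- cooc_histogram(e0, b)
  # double all positions and move every edge up one octave
  e2 <- data.frame(x = 2 * e$x, y = 2 * e$y, theta = e$theta,
                   scale_index = e$scale_index + 1,
                   amplitude = e$amplitude, phase = e$phase)
  e2 <- mask_edges(as_edge_list(e2, image_shape = c(128L, 128L)),
                   mask_radius = 1e6)
  h2 <- cooc_histogram(e2, b)
  expect_equal(h2$w, h0$w)
})

test_that("chevron maps are invariant to marginalized-axis permutations", {
  e <- random_edges(n = 45, seed = 8)
  h <- cooc_histogram(e)
  cm <- chevron_map(h)
  h_perm <- h
  h_perm$w <- h$w[c(3, 1, 6, 2, 5, 4), , , ]
  expect_equal(chevron_map(h_perm)$map, cm$map)
  # uniform 4-D table gives a uniform chevron map
  h_unif <- h
  h_unif$w <- array(1, dim(h$w))
  expect_equal(max(abs(chevron_map(h_unif)$map - 1 / 144)), 0)
})

test_that("ratio maps detect curvature enrichment against a reference", {
  h_ref <- cooc_histogram(collinear_edges(n = 9))
  expect_equal(max(abs(ratio_map(h_ref, h_ref)$map - 1)), 0)

  h_circ <- cooc_histogram(circle_tangent_edges(n = 13, radius = 20))
  rm_ <- ratio_map(h_circ, h_ref)
  i0 <- findInterval(0, rm_$psi_edges)
  j0 <- findInterval(0, rm_$theta_edges)
  coll <- rm_$map[c(i0 - 1, i0), c(j0 - 1, j0)]
  expect_lt(min(coll), 1)                  # collinear cell depleted
  off <- rm_$map[c(i0 - 1, i0), -c(j0 - 1, j0)]
  expect_gt(max(off), 1)                   # co-circular cells enriched
  expect_true(all(rm_$map > 0))
})

test_that("incompatible binnings are refused", {
  e <- random_edges(n = 20, seed = 2)
  h1 <- cooc_histogram(e)
  h2 <- cooc_histogram(e, cooc_binning(n_d = 4))
  expect_error(ratio_map(h1, h2), "binning")
  expect_error(pool_cooc(list(h1, h2)), "binning")
})

test_that("first-order orientation histograms behave as documented", {
  sh <- c(64L, 64L)
  e_h <- as_edge_list(data.frame(x = seq(20, 44, 4), y = 32, theta = 0,
                                 scale_index = 1, amplitude = 1, phase = 0),
                      image_shape = sh)
  fo <- first_order_histogram(e_h, n_bins = 12)
  expect_equal(sum(fo), 1)
  expect_equal(fo[1], 1)

  e <- random_edges(n = 5000, seed = 12, shape = c(256L, 256L))
  fo_u <- first_order_histogram(e, n_bins = 12, weighting = "uniform")
  expect_lt(max(abs(fo_u - 1 / 12)), 0.02)

  # rotating all edges by a whole number of bins shifts the histogram
  k <- 3
  e_rot <- e
  e_rot$theta <- (e$theta + k * pi / 12) %% pi
  fo1 <- first_order_histogram(mask_edges(e, 1e6), n_bins = 12)
  fo2 <- first_order_histogram(mask_edges(e_rot, 1e6), n_bins = 12)
  expect_equal(fo2, fo1[((seq_len(12) - 1 - k) %% 12) + 1],
               tolerance = 1e-12)

  e_none <- e[0, ]
  e_none <- as_edge_list(e_none, image_shape = c(256L, 256L))
  expect_error(first_order_histogram(e_none), "no edges")
})

test_that("histogram JSON container round-trips", {
  e <- random_edges(n = 30, seed = 4)
  h <- cooc_histogram(e)
  p <- file.path(tempdir(), "h.hist.json")
  write_cooc(h, p)
  h2 <- read_cooc(p)
  expect_equal(h2$w, h$w)
  expect_equal(h2$d_edges, h$d_edges)
  expect_equal(h2$n_pairs, h$n_pairs)
  expect_equal(h2$weighting, h$weighting)
  expect_equal(h2$mask_radius, h$mask_radius)
})
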