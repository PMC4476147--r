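test_that("a one-atom image is recovered exactly in one pursuit step", {
  bank <- bank64()
  truth <- as_edge_list(
    data.frame(x = 40, y = 22, theta = pi / 8, scale_index = 2,
               amplitude = 1.7, phase = 0.9),
    image_shape = c(64L, 64L))
  img <- reconstruct_image(truth, bank)
  fit <- extract_edges(img, bank, n_edges = 5)
  expect_equal(nrow(fit$edges), 1L)
  expect_equal(fit$edges$x, 40)
  expect_equal(fit$edges$y, 22)
  expect_equal(fit$edges$theta, pi / 8)
  expect_equal(fit$edges$scale_index, 2)
  expect_equal(fit$edges$amplitude, 1.7, tolerance = 1e-9)
  expect_equal(fit$edges$phase, 0.9, tolerance = 1e-9)
  expect_lt(fit$residual_energy / fit$initial_energy, 1e-12)
  # reconstruction round-trip
  rec <- reconstruct_image(fit$edges, bank)
  expect_lt(sum((img - rec)^2) / sum(img^2), 1e-6)
})

test_that("residual energy decays monotonically with exact bookkeeping", {
  bank <- bank64()
  fx <- planted_stroke_image(bank, n_strokes = 8, seed = 21,
                             background_rms = 0.3)
  fit <- extract_edges(fx$image, bank, n_edges = 60,
                       residual_target = 0.001)
  expect_false(is.unsorted(rev(fit$residual_trace)))
  drift <- abs(sum(coef(fit)^2) + fit$residual_energy -
                 fit$initial_energy) / fit$initial_energy
  expect_lt(drift, 1e-4)
  # on a clean planted image the greedy picks come out amplitude-sorted
  fx0 <- planted_stroke_image(bank, n_strokes = 8, seed = 22,
                              background_rms = 0, min_separation = 12)
  fit0 <- extract_edges(fx0$image, bank, n_edges = 8,
                        residual_target = 1e-6)
  expect_false(is.unsorted(rev(fit0$edges$amplitude)))
})

test_that("ten well-separated planted atoms are recovered exactly", {
  bank <- bank128()
  fx <- planted_stroke_image(bank, n_strokes = 10, seed = 3,
                             background_rms = 0, min_separation = 24,
                             scale_indices = 2)
  fit <- extract_edges(fx$image, bank, n_edges = 10,
                       residual_target = 1e-6)
  tr <- fx$truth; ex <- fit$edges
  matched <- vapply(seq_len(nrow(tr)), function(i) {
    any(abs(ex$x - tr$x[i]) <= 1 & abs(ex$y - tr$y[i]) <= 1 &
          ex$scale_index == tr$scale_index[i] &
          pmin(abs(ex$theta - tr$theta[i]),
               pi - abs(ex$theta - tr$theta[i])) <= pi / 8 + 1e-12)
  }, logical(1))
  expect_equal(sum(matched), 10L)
})

test_that("degenerate inputs are handled as specified", {
  bank <- bank64()
  fit <- extract_edges(matrix(0, 64, 64), bank)
  expect_equal(nrow(fit$edges), 0L)
  expect_equal(fit$residual_energy, 0)
  expect_false(fit$target_not_reached)
  expect_equal(reconstruct_image(fit$edges, bank), matrix(0, 64, 64))
  expect_equal(residual_energy(matrix(0, 64, 64), fit$edges, bank), 0)
  expect_error(extract_edges(matrix(1, 64, 64), bank, n_edges = 0),
               "n_edges")
  expect_error(extract_edges(matrix(1, 64, 64), bank,
                             residual_target = 1.5), "residual_target")
  # an empty edge list still round-trips through the CSV interchange
  p <- file.path(tempdir(), "empty-edges.csv")
  write_edges(fit$edges, p)
  back <- read_edges(p)
  expect_equal(nrow(back), 0L)
  expect_identical(attr(back, "image_shape"), c(64L, 64L))
})

test_that("the budget-exhausted flag is set when the target is missed", {
  bank <- bank64()
  set.seed(5)
  img <- matrix(rnorm(64 * 64), 64, 64)
  fit <- extract_edges(img, bank, n_edges = 3, residual_target = 0.01)
  expect_true(fit$target_not_reached)
  expect_equal(nrow(fit$edges), 3L)
})

test_that("residual energy decreases over successive edge-list prefixes", {
  bank <- bank64()
  fx <- planted_stroke_image(bank, n_strokes = 6, seed = 11,
                             background_rms = 0)
  fit <- extract_edges(fx$image, bank, n_edges = 6, residual_target = 1e-6)
  img <- fx$image
  fr <- vapply(0:nrow(fit$edges), function(k)
    residual_energy(img, fit$edges[seq_len(k), , drop = FALSE] |>
                      as_edge_list(image_shape = c(64L, 64L)), bank),
    numeric(1))
  expect_equal(fr[1], 1)
  expect_false(is.unsorted(rev(fr)))
  expect_lt(fr[length(fr)], 0.01)
})

test_that("extraction is deterministic", {
  bank <- bank64()
  fx <- planted_stroke_image(bank, n_strokes = 5, seed = 31,
                             background_rms = 0.5)
  f1 <- extract_edges(fx$image, bank, n_edges = 30)
  f2 <- extract_edges(fx$image, bank, n_edges = 30)
  expect_identical(f1$edges, f2$edges)
})

test_that("a natural-like synthetic image is coded to within 5% residual", {
  bank <- bank64()
  fx <- planted_stroke_image(bank, n_strokes = 12, seed = 8,
                             background_rms = 0.2)
  fit <- extract_edges(fx$image, bank, n_edges = 512)
  expect_false(fit$target_not_reached)
  expect_lte(residual_energy(fx$image, fit$edges, bank), 0.05)
})

test_that("edge CSV + sidecar round-trips exactly", {
  bank <- bank64()
  fx <- planted_stroke_image(bank, n_strokes = 5, seed = 13,
                             background_rms = 0.4)
  fit <- extract_edges(fx$image, bank, n_edges = 20, source_id = "img-13")
  edges <- mask_edges(fit$edges)
  path <- file.path(tempdir(), "edges-roundtrip.csv")
  write_edges(edges, path)
  back <- read_edges(path)
  expect_equal(as.data.frame(back), as.data.frame(edges),
               ignore_attr = TRUE)
  expect_identical(attr(back, "image_shape"), attr(edges, "image_shape"))
  expect_equal(attr(back, "mask_radius"), attr(edges, "mask_radius"))
  expect_identical(attr(back, "params_hash"), attr(edges, "params_hash"))
  expect_identical(attr(back, "source_id"), "img-13")
})
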