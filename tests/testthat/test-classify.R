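test_that("the F1 score follows its defining formula", {
  expect_equal(f1_score(tp = 8, fp = 2, fn = 2), 0.8)
  expect_equal(f1_score(tp = 10, fp = 0, fn = 0), 1)
  expect_equal(f1_score(tp = 0, fp = 5, fn = 5), 0)
})

test_that("feature vectors are normalized, shaped, and invertible", {
  edges <- lapply(1:5, function(s) random_edges(n = 50, seed = s))
  x_cm <- make_features(edges, mode = "CM")
  expect_equal(dim(x_cm), c(5L, 144L))
  expect_equal(unname(rowSums(x_cm)), rep(1, 5))

  x_so <- make_features(edges, mode = "SO")
  expect_equal(ncol(x_so), 6L * 12L * 12L * 5L)
  expect_equal(unname(rowSums(x_so)), rep(1, 5))
  # SO flattening round-trips to the 4-D table
  h <- cooc_histogram(edges[[1]])
  expect_equal(unflatten_so(x_so[1, ]), as_prob(h))

  x_fo <- make_features(edges, mode = "FO")
  expect_equal(ncol(x_fo), 12L)
  # all-horizontal edges give a one-hot first-order vector
  e_h <- as_edge_list(data.frame(x = seq(20, 44, 4), y = 32, theta = 0,
                                 scale_index = 1, amplitude = 1, phase = 0),
                      image_shape = c(64L, 64L))
  expect_equal(as.numeric(make_features(list(e_h), mode = "FO")),
               c(1, rep(0, 11)))
})

test_that("the SVM scores separable features near 1 and shuffled near chance", {
  set.seed(20)
  n <- 40
  x <- rbind(matrix(rnorm(n * 10, 0), n),
             matrix(rnorm(n * 10, 1.5), n))
  y <- rep(c("a", "b"), each = n)
  cv <- crossval_f1(x, y, n_resamples = 20, seed = 5)
  expect_gt(cv$mean_f1, 0.9)
  expect_equal(length(cv$f1), 20L)
  expect_true(all(cv$f1 >= 0 & cv$f1 <= 1))
  expect_equal(cv$sd_f1, sd(cv$f1))

  # label shuffling brings F1 to chance
  set.seed(21)
  cv0 <- crossval_f1(x, sample(y), n_resamples = 20, seed = 5)
  expect_gt(cv0$mean_f1, 0.4)
  expect_lt(cv0$mean_f1, 0.6)
})

test_that("cross-validation is reproducible and validates inputs", {
  set.seed(30)
  x <- matrix(rnorm(60 * 8), 60)
  y <- rep(c("a", "b"), 30)
  cv1 <- crossval_f1(x, y, n_resamples = 5, seed = 7)
  cv2 <- crossval_f1(x, y, n_resamples = 5, seed = 7)
  expect_identical(cv1$f1, cv2$f1)
  expect_error(crossval_f1(x, rep("a", 60)), "two classes")
  expect_error(crossval_f1(x[1:12, ], y[c(1:10, 31:32)]), "10 images")
})

test_that("noise injection hits the requested signal-to-noise ratio", {
  set.seed(40)
  img <- matrix(rnorm(256 * 256), 256, 256)
  noisy1 <- add_noise(img, snr_factor = 0.5, seed = 99)
  noisy2 <- add_noise(img, snr_factor = 0.5, seed = 99)
  expect_identical(noisy1, noisy2)
  expect_identical(add_noise(img, snr_factor = 1), img)
  expect_identical(add_noise(img, snr_factor = 100), img)

  # measured power ratio of signal to added noise within 5%
  p_sig <- mean((img - mean(img))^2)
  p_noise <- mean((noisy1 - img)^2)
  expect_equal(p_sig / p_noise, 1, tolerance = 0.05)  # snr 0.5 -> 1:1
  noisy3 <- add_noise(img, snr_factor = 0.25, seed = 1)
  expect_equal(p_sig / mean((noisy3 - img)^2), 1 / 3, tolerance = 0.05)
})

test_that("more planted separation never hurts F1 beyond resampling noise", {
  bank <- bank64()
  run_sep <- function(curv) {
    ds <- generate_dataset(list(s = fixture_spec(background_rms = 0),
                                c = fixture_spec(curvature_mean = curv,
                                                 background_rms = 0)),
                           n_per_class = 15, seed = 66)
    els <- lapply(names(ds$images), function(id)
      extract_edges(ds$images[[id]], bank, n_edges = 128,
                    source_id = id)$edges)
    crossval_f1(make_features(els, mode = "SO"), ds$manifest$label,
                n_resamples = 10, seed = 4)$mean_f1
  }
  f_weak <- run_sep(0.01)
  f_strong <- run_sep(0.05)
  expect_gte(f_strong, f_weak - 0.1)   # allow resampling noise
  expect_gt(f_strong, 0.8)
})

test_that("halved SNR degrades but preserves a separable benchmark", {
  bank <- bank64()
  ds <- generate_dataset(list(s = fixture_spec(background_rms = 0),
                              c = fixture_spec(curvature_mean = 0.05,
                                               background_rms = 0)),
                         n_per_class = 15, seed = 55)
  feats <- function(noise) {
    els <- lapply(names(ds$images), function(id) {
      img <- ds$images[[id]]
      if (noise) img <- add_noise(img, 0.5,
                                  seed = 5500 + match(id, names(ds$images)))
      extract_edges(img, bank, n_edges = 128, source_id = id)$edges
    })
    make_features(els, mode = "SO")
  }
  cv_clean <- crossval_f1(feats(FALSE), ds$manifest$label,
                          n_resamples = 10, seed = 3)
  cv_noise <- crossval_f1(feats(TRUE), ds$manifest$label,
                          n_resamples = 10, seed = 3)
  expect_gt(cv_clean$mean_f1, 0.8)
  expect_gt(cv_noise$mean_f1, 0.6)   # degraded but above chance
})
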