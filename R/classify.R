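#' Build per-image feature vectors from edge lists
#'
#' Three feature sets of increasing order are supported, all L1-normalized
#' per image:
#' \describe{
#'   \item{FO}{first-order statistics: the orientation histogram.}
#'   \item{CM}{the chevron-map subset of the second-order statistics: the
#'     flattened `(psi, theta)` marginal.}
#'   \item{SO}{the full four-dimensional co-occurrence histogram,
#'     flattened with axis order (d, psi, theta, sigma), d varying
#'     fastest.}
#' }
#'
#' @param edge_lists list of `edge_list` objects (one per image).
#' @param mode `"SO"`, `"CM"` or `"FO"`.
#' @param binning a [cooc_binning()] (CM/SO modes).
#' @param n_bins_fo orientation bins for FO mode.
#' @param weighting passed to the histogram stage.
#' @param scale_ratio,base_frequency dictionary geometry (see
#'   [cooc_histogram()]).
#' @return numeric matrix, one row per image (rownames = source ids when
#'   available), with attribute `mode`.
#' @export
make_features <- function(edge_lists, mode = c("SO", "CM", "FO"),
                          binning = cooc_binning(), n_bins_fo = 12L,
                          weighting = "amplitude", scale_ratio = 2,
                          base_frequency = 0.25) {
  mode <- match.arg(mode)
  rows <- lapply(edge_lists, function(e) {
    if (mode == "FO")
      return(first_order_histogram(e, n_bins = n_bins_fo,
                                   weighting = weighting))
    h <- cooc_histogram(e, binning = binning, weighting = weighting,
                        scale_ratio = scale_ratio,
                        base_frequency = base_frequency)
    if (h$n_pairs == 0)
      stop("no edge pairs after masking for image ",
           attr(e, "source_id") %||% "<unnamed>", " (mode ", mode, ")")
    if (mode == "CM") as.numeric(chevron_map(h)$map)
    else as.numeric(as_prob(h))
  })
  x <- do.call(rbind, rows)
  ids <- vapply(seq_along(edge_lists), function(i)
    attr(edge_lists[[i]], "source_id") %||% sprintf("img%04d", i),
    character(1))
  rownames(x) <- ids
  attr(x, "mode") <- mode
  x
}

#' Un-flatten an SO feature vector back to the 4-D table
#'
#' @param v a flattened SO vector.
#' @param binning the [cooc_binning()] it was built with.
#' @export
unflatten_so <- function(v, binning = cooc_binning()) {
  array(v, dim = c(binning$n_d, binning$n_psi, binning$n_theta,
                   binning$n_sigma))
}

#' Binary F1 score from a confusion count
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`: the harmonic mean of precision and
#' recall, weighting false positives and false negatives equally. For
#' balanced binary classes, 0.5 is chance level.
#'
#' @param tp,fp,fn true positive, false positive and false negative counts.
#' @export
f1_score <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Resampled cross-validated SVM classification
#'
#' Repeatedly draws stratified train/test splits, fits a linear support
#' vector machine (C = 1 by default) on the training rows and scores the
#' binary F1 on the held-out rows. Feature rows are scaled to unit L2 norm
#' before fitting (`unit_norm = TRUE`), the standard preprocessing for
#' histogram features with a linear SVM (equivalently, a cosine kernel):
#' without it the tiny norms of L1-normalized high-dimensional histograms
#' leave the margin term no fitting power at moderate C and the classifier
#' degenerates to near-constant predictions. The positive class is the
#' first factor level of `labels`. Per-resample seeds are derived
#' deterministically from `seed`. A degenerate draw (a class absent from
#' the training set) is redrawn with a warning.
#'
#' @param x feature matrix (rows = images), e.g. from [make_features()].
#' @param labels class labels, length `nrow(x)`, exactly two classes.
#' @param n_resamples number of independent train/test draws.
#' @param seed master seed for the resampling stream.
#' @param train_frac fraction of each class used for training.
#' @param cost SVM regularization constant.
#' @param unit_norm scale each feature row to unit L2 norm before fitting.
#' @return object of class `cooc_cv`: list with per-resample `f1` scores,
#'   `mean_f1`, `sd_f1`, `range_f1`, the class labels and settings.
#' @export
crossval_f1 <- function(x, labels, n_resamples = 20L, seed = 1L,
                        train_frac = 0.8, cost = 1, unit_norm = TRUE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (min(table(labels)) < 10)
    stop("need at least 10 images per class")
  feature_mode <- attr(x, "mode") %||% NA_character_
  if (unit_norm)
    x <- x / pmax(sqrt(rowSums(x^2)), .Machine$double.eps)
  f1 <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    set.seed(resample_seed(seed, r))
    repeat {
      tr <- unlist(lapply(levels(labels), function(l) {
        i <- which(labels == l)
        sample(i, max(1, round(train_frac * length(i))))
      }))
      if (nlevels(droplevels(labels[tr])) == 2 &&
          length(tr) < length(labels)) break
      warning("degenerate split redrawn")
    }
    fit <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, x[-tr, , drop = FALSE])
    truth <- labels[-tr]
    pos <- levels(labels)[1]
    f1[r] <- f1_score(tp = sum(pred == pos & truth == pos),
                      fp = sum(pred == pos & truth != pos),
                      fn = sum(pred != pos & truth == pos))
  }
  structure(list(f1 = f1, mean_f1 = mean(f1), sd_f1 = stats::sd(f1),
                 range_f1 = range(f1), classes = levels(labels),
                 n_resamples = n_resamples, train_frac = train_frac,
                 cost = cost, seed = seed, mode = feature_mode),
            class = "cooc_cv")
}

resample_seed <- function(seed, r) {
  (as.integer(seed) * 7919L + 104729L * as.integer(r)) %% 2147483647L
}

#' @export
print.cooc_cv <- function(x, ...) {
  cat(sprintf("SVM cross-validation (%s vs %s%s)\n", x$classes[1],
              x$classes[2],
              if (!is.na(x$mode)) paste0(", ", x$mode, " features") else ""))
  cat(sprintf("  mean F1 = %.1f%%  (SD %.1f, range %.1f-%.1f over %d resamples)\n",
              100 * x$mean_f1, 100 * x$sd_f1, 100 * x$range_f1[1],
              100 * x$range_f1[2], x$n_resamples))
  invisible(x)
}

#' Degrade an image's signal-to-noise ratio
#'
#' Adds seeded white Gaussian noise. `snr_factor` is interpreted as the
#' fraction of the output power carried by the signal: noise power is
#' `P_signal * (1 - snr_factor) / snr_factor`, so `snr_factor = 0.5` (the
#' default, the "halved SNR" condition) adds noise with power equal to the
#' signal power, and `snr_factor >= 1` returns the input unchanged. Signal
#' power is measured about the image mean.
#'
#' @param image numeric matrix.
#' @param snr_factor signal-to-total power fraction (> 0).
#' @param seed optional seed for reproducibility.
#' @export
add_noise <- function(image, snr_factor = 0.5, seed = NULL) {
  stopifnot(is.matrix(image), all(is.finite(image)), snr_factor > 0)
  if (snr_factor >= 1) return(image)
  p_sig <- mean((image - mean(image))^2)
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- sqrt(p_sig * (1 - snr_factor) / snr_factor)
  image + matrix(rnorm(length(image), sd = noise_sd), nrow(image))
}
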