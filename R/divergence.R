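#' Kullback-Leibler divergence between histograms
#'
#' `sum(p * log(p / q))` in nats, after adding `epsilon` to every cell of
#' both tables and renormalizing (empirical co-occurrence tables contain
#' zeros). Non-negative; zero iff the smoothed tables are equal.
#'
#' @param p,q non-negative arrays of identical shape (or `cooc_hist`
#'   objects), normalized or normalizable.
#' @param epsilon smoothing mass per cell; default `1 / (n_cells * n_pairs)`
#'   when `p` is a `cooc_hist` with pairs, else `1 / n_cells^2`.
#' @return divergence in nats.
#' @export
kl_divergence <- function(p, q, epsilon = NULL) {
  epsilon <- default_epsilon(p, epsilon)
  p <- hist_table(p); q <- hist_table(q)
  if (!identical(dim1(p), dim1(q)))
    stop("histograms have different shapes")
  p <- (p + epsilon) / sum(p + epsilon)
  q <- (q + epsilon) / sum(q + epsilon)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence
#'
#' `JS(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, in nats.
#' Symmetric, bounded by `log(2)`, and zero iff `p == q`; its square root is
#' a metric between histograms. No smoothing is needed: the mixture support
#' covers both arguments.
#'
#' @inheritParams kl_divergence
#' @export
js_divergence <- function(p, q) {
  p <- hist_table(p); q <- hist_table(q)
  if (!identical(dim1(p), dim1(q)))
    stop("histograms have different shapes")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl0 <- function(a) {
    pos <- a > 0
    sum(a[pos] * log(a[pos] / m[pos]))
  }
  (kl0(p) + kl0(q)) / 2
}

#' Convert nats to bits
#'
#' @param x divergence values in nats.
#' @export
nats_to_bits <- function(x) x / log(2)

#' Two-sided divergence report
#'
#' @inheritParams kl_divergence
#' @return object of class `divergence_report` with `kl_ab`, `kl_ba`, `js`
#'   (nats) and the `epsilon` used.
#' @export
divergence_report <- function(p, q, epsilon = NULL) {
  epsilon <- default_epsilon(p, epsilon)
  structure(list(kl_ab = kl_divergence(p, q, epsilon),
                 kl_ba = kl_divergence(q, p, epsilon),
                 js = js_divergence(p, q), epsilon = epsilon),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("KL(a||b) = %.4g, KL(b||a) = %.4g, JS = %.4g nats\n",
              x$kl_ab, x$kl_ba, x$js))
  invisible(x)
}

hist_table <- function(h) {
  if (inherits(h, "cooc_hist")) h$w
  else if (inherits(h, "chevron_map")) h$map
  else h
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

default_epsilon <- function(p, epsilon) {
  if (!is.null(epsilon)) {
    stopifnot(epsilon > 0)
    return(epsilon)
  }
  n <- length(hist_table(p))
  if (inherits(p, "cooc_hist") && p$n_pairs > 0) 1 / (n * p$n_pairs)
  else 1 / n^2
}

#' Factorization gaps of the association field
#'
#' How far is the 4-D co-occurrence table from (i) full independence (outer
#' product of its four 1-D marginals) and (ii) the pairwise factorization
#' `p(d, sigma) * p(psi, theta)`? Both gaps are KL divergences in nats; the
#' pairwise gap is never larger (chain rule), and a small pairwise gap
#' justifies analyzing the angular structure `p(psi, theta)` separately from
#' the viewpoint-dependent `p(d, sigma)`.
#'
#' @param h a `cooc_hist` (or a 4-D array with axes d, psi, theta, sigma).
#' @param epsilon smoothing mass per cell (see [kl_divergence()]).
#' @return list with `kl_full_product`, `kl_pair_product` (nats) and
#'   `closer`, the name of the better factorization.
#' @export
factorization_gap <- function(h, epsilon = NULL) {
  epsilon <- default_epsilon(h, epsilon)
  w <- hist_table(h)
  if (length(dim(w)) != 4) stop("need a 4-D histogram")
  if (sum(w) <= 0) stop("no pairs: histogram is empty")
  p <- (w + epsilon) / sum(w + epsilon)
  m1 <- apply(p, 1, sum); m2 <- apply(p, 2, sum)
  m3 <- apply(p, 3, sum); m4 <- apply(p, 4, sum)
  full <- outer(outer(m1, m2), outer(m3, m4))
  p12 <- apply(p, c(1, 4), sum)   # p(d, sigma)
  p34 <- apply(p, c(2, 3), sum)   # p(psi, theta)
  pair <- aperm(outer(p34, p12), c(3, 1, 2, 4))
  kl <- function(q) sum(p * log(p / q))
  gaps <- list(kl_full_product = kl(full), kl_pair_product = kl(pair))
  gaps$closer <- if (gaps$kl_pair_product <= gaps$kl_full_product)
    "pair_product" else "full_product"
  gaps
}

#' Group separation index d-prime
#'
#' Standardized difference between two groups of scores using the pooled
#' standard deviation:
#' `d' = (mean(x) - mean(y)) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @export
dprime <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Per-image histogram bias toward one class average
#'
#' For each image histogram computes
#' `delta = KL(h || class-A mean) - KL(h || class-B mean)`; negative values
#' mean the image's association field is closer to class A. Swapping the
#' class roles negates delta.
#'
#' @param hists list of per-image `cooc_hist` objects.
#' @param ref_a,ref_b class-average histograms (e.g. from [pool_cooc()]).
#' @param epsilon smoothing mass per cell.
#' @return numeric vector of deltas (nats).
#' @export
class_bias_deltas <- function(hists, ref_a, ref_b, epsilon = NULL) {
  vapply(hists, function(h) {
    kl_divergence(h, ref_a, default_epsilon(h, epsilon)) -
      kl_divergence(h, ref_b, default_epsilon(h, epsilon))
  }, numeric(1))
}
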