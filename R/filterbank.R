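#' Log-Gabor dictionary parameters
#'
#' Validates and bundles the parameters of the over-complete log-Gabor
#' dictionary used to model V1 simple-cell receptive fields. Orientation
#' centers are evenly spaced over `[0, pi)` (edges are unoriented, so
#' orientation is defined modulo pi); scale center frequencies form the
#' geometric sequence `base_frequency * scale_ratio^-(s-1)`, s = 1..n_scales.
#'
#' @param n_orientations number of orientation channels (>= 2).
#' @param n_scales number of scales (>= 2).
#' @param base_frequency center frequency of the finest scale, cycles/pixel
#'   (0 < f <= 0.5).
#' @param scale_ratio ratio between successive scale center frequencies
#'   (> 1; 2 gives octave spacing).
#' @param bandwidth_freq Gaussian width of the radial profile on the
#'   log-frequency axis (dimensionless; 0.4 corresponds to roughly a
#'   1.5-octave frequency bandwidth).
#' @param bandwidth_theta Gaussian angular width, radians.
#' @param image_shape integer vector `c(rows, cols)` of the images to be
#'   analyzed.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(n_orientations = 8L, n_scales = 5L,
                          base_frequency = 0.25, scale_ratio = 2,
                          bandwidth_freq = 0.4, bandwidth_theta = pi / 16,
                          image_shape = c(256L, 256L)) {
  if (!is.numeric(n_orientations) || n_orientations < 2)
    stop("invalid filter parameter 'n_orientations': must be >= 2")
  if (!is.numeric(n_scales) || n_scales < 2)
    stop("invalid filter parameter 'n_scales': must be >= 2")
  if (!is.numeric(base_frequency) || base_frequency <= 0 ||
      base_frequency > 0.5)
    stop("invalid filter parameter 'base_frequency': must be in (0, 0.5] ",
         "(0.5 cycles/pixel is the Nyquist frequency)")
  if (!is.numeric(scale_ratio) || scale_ratio <= 1)
    stop("invalid filter parameter 'scale_ratio': must be > 1")
  if (!is.numeric(bandwidth_freq) || bandwidth_freq <= 0)
    stop("invalid filter parameter 'bandwidth_freq': must be > 0")
  if (!is.numeric(bandwidth_theta) || bandwidth_theta <= 0)
    stop("invalid filter parameter 'bandwidth_theta': must be > 0")
  if (length(image_shape) != 2 || any(image_shape < 4))
    stop("invalid filter parameter 'image_shape': need c(rows, cols) >= 4")
  p <- list(n_orientations = as.integer(n_orientations),
            n_scales = as.integer(n_scales),
            base_frequency = base_frequency, scale_ratio = scale_ratio,
            bandwidth_freq = bandwidth_freq,
            bandwidth_theta = bandwidth_theta,
            image_shape = as.integer(image_shape))
  class(p) <- "filter_params"
  p
}

#' @export
print.filter_params <- function(x, ...) {
  cat("log-Gabor dictionary parameters\n")
  cat(sprintf("  %d orientations x %d scales on a %d x %d grid\n",
              x$n_orientations, x$n_scales, x$image_shape[1],
              x$image_shape[2]))
  cat(sprintf("  center frequencies %.4g ... %.4g cycles/pixel (ratio %g)\n",
              x$base_frequency,
              x$base_frequency * x$scale_ratio^-(x$n_scales - 1),
              x$scale_ratio))
  cat(sprintf("  bandwidths: %.3g (log-frequency), %.3g rad (angular)\n",
              x$bandwidth_freq, x$bandwidth_theta))
  invisible(x)
}

# DFT frequencies in cycles/pixel for an n-point axis (Nyquist mapped to -0.5)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Orientation centers of a dictionary
#'
#' @param params a `filter_params` object (or a bank).
#' @return orientations in radians, evenly spaced over `[0, pi)`.
#' @export
bank_orientations <- function(params) {
  if (inherits(params, "log_gabor_bank")) params <- params$params
  (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
}

#' Scale center frequencies (cycles/pixel) of a dictionary
#'
#' @inheritParams bank_orientations
#' @export
bank_frequencies <- function(params) {
  if (inherits(params, "log_gabor_bank")) params <- params$params
  params$base_frequency * params$scale_ratio^-(seq_len(params$n_scales) - 1)
}

#' Build the over-complete log-Gabor dictionary
#'
#' Constructs one frequency-domain transfer function per (scale, orientation)
#' pair. Each kernel is the product of a log-Gaussian radial profile (zero at
#' DC by construction: log-Gabor filters have no mean response) and a Gaussian
#' angular profile centered on the direction orthogonal to the edge
#' orientation. Kernels are single-sided in frequency, so their spatial
#' counterparts are complex quadrature pairs; the modulus of a coefficient is
#' the local oriented energy and its argument the edge phase/polarity.
#' Magnitudes are normalized so that every kernel has unit energy
#' (`sum(|K|^2) == 1` over frequency bins).
#'
#' Kernel slices are ordered scale-major: slice `(s - 1) * n_orientations + o`
#' holds scale `s`, orientation `o`.
#'
#' @param params a [filter_params()] object.
#' @return an object of class `log_gabor_bank` with elements `params` and
#'   `kernels` (complex array `rows x cols x (n_scales * n_orientations)`).
#' @export
build_filterbank <- function(params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  ny <- params$image_shape[1]; nx <- params$image_shape[2]
  fy <- fft_freqs(ny); fx <- fft_freqs(nx)
  FY <- matrix(fy, ny, nx)
  FX <- matrix(fx, ny, nx, byrow = TRUE)
  r <- sqrt(FX^2 + FY^2)
  ang <- atan2(FY, FX)
  # self-conjugate DFT bins (f == -f mod N): must be zero so spatial kernels
  # have exactly orthogonal quadrature components
  selfconj <- outer(fy %in% c(0, -0.5), fx %in% c(0, -0.5), `&`)

  freqs <- bank_frequencies(params)
  oris <- bank_orientations(params)
  nk <- params$n_scales * params$n_orientations
  kernels <- array(0i, dim = c(ny, nx, nk))
  lr <- matrix(0, ny, nx)
  pos <- r > 0
  lr[pos] <- log(r[pos])
  for (s in seq_len(params$n_scales)) {
    radial <- matrix(0, ny, nx)
    radial[pos] <- exp(-(lr[pos] - log(freqs[s]))^2 /
                         (2 * params$bandwidth_freq^2))
    for (o in seq_len(params$n_orientations)) {
      # a filter "oriented at theta" detects edges whose segment runs along
      # theta; its frequency lobe is centered at direction theta + pi/2
      d <- ang - (oris[o] + pi / 2)
      d <- ((d + pi) %% (2 * pi)) - pi
      K <- radial * exp(-d^2 / (2 * params$bandwidth_theta^2))
      K[selfconj] <- 0
      kernels[, , (s - 1) * params$n_orientations + o] <-
        K / sqrt(sum(K^2))
    }
  }
  structure(list(params = params, kernels = kernels),
            class = "log_gabor_bank")
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat("log-Gabor filter bank\n")
  print(x$params)
  cat(sprintf("  %d kernels, unit energy, zero DC\n", dim(x$kernels)[3]))
  invisible(x)
}

# kernels rescaled so real atoms Re(e^{i phi} k) have unit l2 norm
mp_kernels <- function(bank) {
  bank$kernels * sqrt(2 * prod(bank$params$image_shape))
}

check_image <- function(image, bank) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (!all(dim(image) == bank$params$image_shape))
    stop(sprintf("image shape (%d x %d) does not match bank (%d x %d)",
                 nrow(image), ncol(image), bank$params$image_shape[1],
                 bank$params$image_shape[2]))
  if (!all(is.finite(image)))
    stop("image contains non-finite pixel values")
  invisible(TRUE)
}

#' Linear log-Gabor analysis of an image
#'
#' Correlates the (mean-subtracted) image with every kernel of the bank over
#' the full image plane via frequency-domain products. The coefficient at
#' `[y, x, s, o]` is the inner product of the image with kernel `(s, o)`
#' centered at pixel `(x, y)` (0-based), scaled so that the real atom of any
#' phase has unit norm.
#'
#' @param image numeric matrix matching the bank's `image_shape`.
#' @param bank a [build_filterbank()] object.
#' @return complex array `rows x cols x n_scales x n_orientations`.
#' @export
analyze_image <- function(image, bank) {
  check_image(image, bank)
  x <- image - mean(image)
  C <- cpp_correlate(mp_kernels(bank), fft(x) + 0i)
  dim(C) <- c(bank$params$image_shape[1], bank$params$image_shape[2],
              bank$params$n_orientations, bank$params$n_scales)
  # slices are scale-major: reorder to [y, x, scale, orientation]
  aperm(C, c(1, 2, 4, 3))
}
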