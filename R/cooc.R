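#' Fold an angle into [-pi/2, pi/2)
#'
#' Edges are unoriented (orientation is defined modulo pi), so relative
#' angles are reduced to the half-open interval `[-pi/2, pi/2)`.
#'
#' @param x angles in radians.
#' @export
fold_angle <- function(x) ((x + pi / 2) %% pi) - pi / 2

#' Relative geometry of edge pairs
#'
#' For each pair of edges A, B computes the four co-occurrence variables:
#' center distance `d`, azimuth `phi` of B's center relative to A's
#' orientation axis, orientation difference `theta = theta_B - theta_A`, the
#' symmetrized angle `psi` (zero for co-circular pairs, i.e. edges tangent
#' to a common circle), and log2 scale ratio `sigma`. `theta`, `phi` and
#' `psi` are folded into `[-pi/2, pi/2)`; `psi` is invariant under swapping
#' A and B while `theta` changes sign.
#'
#' Because orientations are only defined modulo pi, the textbook formula
#' `psi = phi - theta/2` is ambiguous by pi/2 (replacing theta by theta + pi
#' shifts it by pi/2). The ambiguity is resolved with the
#' tangent-continuation convention: each edge's direction is taken as the
#' representative within pi/2 of the chord joining the two centers, and psi
#' is the (negated) mean of the two chord-relative direction offsets. This
#' agrees with `phi - theta/2` modulo pi/2, makes psi exactly zero for
#' tangents to a common circle at any tangent separation, and puts parallel
#' side-by-side pairs at `psi = -pi/2`.
#'
#' Coincident centers (`d == 0`) leave `phi` undefined; the convention
#' `phi = 0` is used and the pair flagged `degenerate`.
#'
#' @param a,b data frames (rows are paired elementwise) with columns `x`,
#'   `y`, `theta`, `scale_index`.
#' @param scale_ratio the bank's scale ratio, used to express `sigma` in
#'   log2 units.
#' @return data frame with columns `d`, `phi`, `theta`, `psi`, `sigma`,
#'   `degenerate`.
#' @export
pair_geometry <- function(a, b, scale_ratio = 2) {
  dx <- b$x - a$x
  dy <- b$y - a$y
  d <- sqrt(dx^2 + dy^2)
  degenerate <- d == 0
  chord <- atan2(dy, dx)
  chord[degenerate] <- a$theta[degenerate]   # phi := 0 convention
  phi <- fold_angle(chord - a$theta)
  theta <- fold_angle(b$theta - a$theta)
  # tangent-continuation convention: align each edge's direction with the
  # chord (within +/- pi/2) before averaging, so that psi = 0 exactly for
  # every pair of tangents to a common circle, at any tangent separation
  da <- fold_angle(a$theta - chord)
  db <- fold_angle(b$theta - chord)
  psi <- fold_angle(-(da + db) / 2)
  sigma <- (b$scale_index - a$scale_index) * log2(scale_ratio)
  data.frame(d = d, phi = phi, theta = theta, psi = psi, sigma = sigma,
             degenerate = degenerate)
}

#' Binning scheme for the co-occurrence histogram
#'
#' Defaults: 6 log-spaced distance bins spanning `[2, mask_radius]` pixels,
#' 12 x 12 bins for `(psi, theta)` over `[-pi/2, pi/2)`, and 5 bins for the
#' log2 scale ratio over `[-2, 2]`. A distance upper limit given as `NA` is
#' resolved to the mask radius when the histogram is computed.
#'
#' @param n_d,n_psi,n_theta,n_sigma bin counts per axis.
#' @param d_range distance range in pixels (`c(2, NA)` means up to the mask
#'   radius).
#' @param sigma_range range of log2 scale ratios.
#' @param d_scale `"pixels"` for absolute distances or `"normalized"` to
#'   measure `d` in units of the pair's geometric-mean wavelength (making
#'   the histogram invariant under joint rescaling of positions and scales).
#' @export
cooc_binning <- function(n_d = 6L, n_psi = 12L, n_theta = 12L, n_sigma = 5L,
                         d_range = c(2, NA), sigma_range = c(-2, 2),
                         d_scale = c("pixels", "normalized")) {
  d_scale <- match.arg(d_scale)
  stopifnot(n_d >= 1, n_psi >= 1, n_theta >= 1, n_sigma >= 1,
            d_range[1] > 0)
  structure(list(n_d = as.integer(n_d), n_psi = as.integer(n_psi),
                 n_theta = as.integer(n_theta), n_sigma = as.integer(n_sigma),
                 d_range = d_range, sigma_range = sigma_range,
                 d_scale = d_scale),
            class = "cooc_binning")
}

resolve_binning <- function(binning, mask_radius) {
  if (is.na(binning$d_range[2])) binning$d_range[2] <- mask_radius
  if (binning$d_range[2] <= binning$d_range[1])
    stop("invalid distance range")
  binning$d_edges <- exp(seq(log(binning$d_range[1]),
                             log(binning$d_range[2]),
                             length.out = binning$n_d + 1))
  # (0:n)/n keeps the midpoint edge exactly 0 for even bin counts
  binning$psi_edges <- (0:binning$n_psi) / binning$n_psi * pi - pi / 2
  binning$theta_edges <- (0:binning$n_theta) / binning$n_theta * pi - pi / 2
  binning$sigma_edges <- seq(binning$sigma_range[1], binning$sigma_range[2],
                             length.out = binning$n_sigma + 1)
  binning
}

#' Default circular analysis mask radius
#'
#' Edges outside a central circular mask are discarded before computing
#' co-occurrence statistics, to avoid boundary artifacts. The default radius
#' is 0.45 times the smaller image dimension.
#'
#' @param image_shape `c(rows, cols)`.
#' @param fraction mask radius as a fraction of `min(image_shape)`.
#' @export
default_mask_radius <- function(image_shape, fraction = 0.45) {
  fraction * min(image_shape)
}

#' Apply the circular mask to an edge list
#'
#' @param edges an `edge_list`.
#' @param mask_radius radius in pixels (default [default_mask_radius()]).
#' @return the masked `edge_list`, with `mask_radius` recorded.
#' @export
mask_edges <- function(edges, mask_radius = NULL) {
  shp <- attr(edges, "image_shape")
  if (is.null(mask_radius))
    mask_radius <- attr(edges, "mask_radius") %||% default_mask_radius(shp)
  cx <- (shp[2] - 1) / 2; cy <- (shp[1] - 1) / 2
  keep <- (edges$x - cx)^2 + (edges$y - cy)^2 <= mask_radius^2
  out <- edges[keep, , drop = FALSE]
  attributes(out)[c("image_shape", "source_id", "params_hash")] <-
    attributes(edges)[c("image_shape", "source_id", "params_hash")]
  attr(out, "mask_radius") <- mask_radius
  class(out) <- c("edge_list", "data.frame")
  out
}

#' The association field: 4-D edge co-occurrence histogram
#'
#' Accumulates, over all unordered pairs of masked edges, a weighted
#' histogram of the pair geometry `(d, psi, theta, sigma)`. Swapping the
#' two edges of a pair leaves `d` and `psi` unchanged and flips the signs
#' of both `theta` and `sigma`, so each unordered pair is canonicalized to
#' the half-domain `sigma > 0, or theta >= 0 when sigma = 0` before
#' binning. This sign convention depends only on the pair's intrinsic
#' geometry, which makes the histogram exactly independent of edge order
#' and of global translations and rotations of the frame. Pairs falling
#' outside the distance or scale-ratio range are dropped and counted in
#' `n_dropped`, so that the normalized histogram is a proper distribution
#' over the binned domain.
#'
#' @param edges an `edge_list` (masked with [mask_edges()] if it does not
#'   yet carry a mask radius).
#' @param binning a [cooc_binning()] object.
#' @param weighting `"amplitude"` weights each pair by the product of the
#'   two edge amplitudes; `"uniform"` counts pairs equally.
#' @param scale_ratio,base_frequency dictionary geometry used for `sigma`
#'   and for scale-normalized distances.
#' @return an object of class `cooc_hist`: list with the 4-D array `w`
#'   (axes d, psi, theta, sigma), bin edges, `n_pairs` (pairs binned),
#'   `n_dropped`, `weighting`, `mask_radius` and `params_hash`.
#' @export
cooc_histogram <- function(edges, binning = cooc_binning(),
                           weighting = c("amplitude", "uniform"),
                           scale_ratio = 2, base_frequency = 0.25) {
  weighting <- match.arg(weighting)
  if (is.null(attr(edges, "mask_radius"))) edges <- mask_edges(edges)
  b <- resolve_binning(binning, attr(edges, "mask_radius"))
  m <- nrow(edges)
  dims <- c(b$n_d, b$n_psi, b$n_theta, b$n_sigma)
  h <- structure(list(w = array(0, dims), d_edges = b$d_edges,
                      psi_edges = b$psi_edges, theta_edges = b$theta_edges,
                      sigma_edges = b$sigma_edges, binning = b,
                      weighting = weighting, n_pairs = 0L, n_dropped = 0L,
                      mask_radius = attr(edges, "mask_radius"),
                      params_hash = attr(edges, "params_hash"),
                      source_id = attr(edges, "source_id")),
                 class = "cooc_hist")
  if (m < 2) return(h)

  ii <- rep.int(seq_len(m - 1), (m - 1):1)
  jj <- sequence((m - 1):1, from = 2:m)
  a <- edges[ii, , drop = FALSE]; bb <- edges[jj, , drop = FALSE]
  g <- pair_geometry(a, bb, scale_ratio = scale_ratio)
  # canonical unordered-pair representative: flip (theta, sigma) jointly
  # into {sigma > 0} u {sigma = 0, theta >= 0}
  flip <- g$sigma < 0 | (g$sigma == 0 & g$theta < 0)
  g$theta[flip] <- fold_angle(-g$theta[flip])
  g$sigma[flip] <- -g$sigma[flip]
  d <- g$d
  if (b$d_scale == "normalized") {
    lambda <- (1 / base_frequency) *
      scale_ratio^((a$scale_index + bb$scale_index) / 2 - 1)
    d <- d / lambda
  }
  w <- if (weighting == "amplitude") a$amplitude * bb$amplitude
       else rep(1, length(d))

  id <- bin_index(d, b$d_edges)
  ip <- bin_index(g$psi, b$psi_edges)
  it <- bin_index(g$theta, b$theta_edges)
  is <- bin_index(g$sigma, b$sigma_edges)
  ok <- !is.na(id) & !is.na(ip) & !is.na(it) & !is.na(is)
  h$n_pairs <- sum(ok)
  h$n_dropped <- sum(!ok)
  if (h$n_pairs) {
    lin <- (id[ok] - 1) + dims[1] * ((ip[ok] - 1) + dims[2] *
             ((it[ok] - 1) + dims[3] * (is[ok] - 1))) + 1
    acc <- rowsum(w[ok], lin)
    h$w[as.integer(rownames(acc))] <- acc[, 1]
  }
  h
}

# bin index with the last interval closed on the right; NA out of range
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' @export
print.cooc_hist <- function(x, ...) {
  cat("edge co-occurrence histogram p(d, psi, theta, sigma)\n")
  cat(sprintf("  bins %s, %d pairs binned (%d dropped), %s-weighted\n",
              paste(dim(x$w), collapse = " x "), x$n_pairs, x$n_dropped,
              x$weighting))
  invisible(x)
}

#' Normalized probability table of a histogram
#'
#' @param h a `cooc_hist` (or any non-negative array).
#' @return array of the same shape summing to 1.
#' @export
as_prob <- function(h) {
  w <- if (inherits(h, "cooc_hist")) h$w else h
  s <- sum(w)
  if (s <= 0) stop("no pairs: histogram is empty")
  w / s
}

#' Pool histograms
#'
#' Sums the (count/weight) tables of several compatible histograms; used to
#' build class-average association fields.
#'
#' @param hists list of `cooc_hist` objects with identical binning.
#' @export
pool_cooc <- function(hists) {
  h <- hists[[1]]
  for (k in seq_along(hists)[-1]) {
    check_compatible(h, hists[[k]])
    h$w <- h$w + hists[[k]]$w
    h$n_pairs <- h$n_pairs + hists[[k]]$n_pairs
    h$n_dropped <- h$n_dropped + hists[[k]]$n_dropped
  }
  h$source_id <- NULL
  h
}

check_compatible <- function(h1, h2) {
  if (!identical(dim(h1$w), dim(h2$w)) ||
      !isTRUE(all.equal(h1$d_edges, h2$d_edges)) ||
      !isTRUE(all.equal(h1$sigma_edges, h2$sigma_edges)) ||
      !identical(h1$weighting, h2$weighting))
    stop("histograms were computed under different binning parameters ",
         "and cannot be combined")
  invisible(TRUE)
}

#' Chevron map: the (psi, theta) marginal
#'
#' Marginalizes the 4-D association field over distance and scale ratio,
#' giving the probability of each angular configuration of edge pairs
#' ("chevron"). Collinear pairs sit at (psi = 0, theta = 0); co-circular
#' pairs along the theta axis at psi = 0.
#'
#' @param h a `cooc_hist`.
#' @return object of class `chevron_map`: matrix `n_psi x n_theta` in
#'   probability mode (sums to 1).
#' @export
chevron_map <- function(h) {
  p <- as_prob(h)
  structure(list(map = apply(p, c(2, 3), sum), mode = "probability",
                 psi_edges = h$psi_edges, theta_edges = h$theta_edges),
            class = "chevron_map")
}

#' Ratio chevron map between two histograms
#'
#' Cell-wise ratio of two chevron maps after epsilon-smoothing, as used to
#' contrast the association fields of two image classes: a value above 1
#' marks angular configurations more prevalent in `h_test` than in `h_ref`.
#'
#' @param h_test,h_ref `cooc_hist` objects under identical binning.
#' @param epsilon smoothing mass added to every cell before renormalization;
#'   default `1 / (n_cells * min(n_pairs))`.
#' @return `chevron_map` in ratio mode.
#' @export
ratio_map <- function(h_test, h_ref, epsilon = NULL) {
  check_compatible(h_test, h_ref)
  mt <- chevron_map(h_test)$map
  mr <- chevron_map(h_ref)$map
  if (is.null(epsilon))
    epsilon <- 1 / (length(mt) * max(1, min(h_test$n_pairs, h_ref$n_pairs)))
  smooth <- function(m) (m + epsilon) / (1 + length(m) * epsilon)
  structure(list(map = smooth(mt) / smooth(mr), mode = "ratio",
                 psi_edges = h_test$psi_edges,
                 theta_edges = h_test$theta_edges, epsilon = epsilon),
            class = "chevron_map")
}

#' @export
print.chevron_map <- function(x, ...) {
  cat(sprintf("chevron map (%s mode), %d psi x %d theta bins\n", x$mode,
              nrow(x$map), ncol(x$map)))
  invisible(x)
}

#' Render a chevron map
#'
#' Each (psi, theta) cell is drawn as a chevron: a reference segment plus a
#' second segment in the corresponding relative configuration, on a disc
#' colored by probability (or log-ratio).
#'
#' @param x a `chevron_map`.
#' @param ... unused.
#' @export
plot.chevron_map <- function(x, ...) {
  np <- nrow(x$map); nt <- ncol(x$map)
  v <- if (x$mode == "ratio") log(x$map) else x$map - mean(x$map)
  pal <- grDevices::hcl.colors(65, "Blue-Red 2")
  vmax <- max(abs(v), 1e-12)
  ci <- pmin(65L, pmax(1L, 1L + as.integer(32 * (1 + v / vmax))))
  op <- graphics::par(mar = c(4, 4, 2, 1)); on.exit(graphics::par(op))
  plot(NA, xlim = c(0.5, nt + 0.5), ylim = c(0.5, np + 0.5), asp = 1,
       xlab = expression(theta), ylab = expression(psi), axes = FALSE)
  graphics::axis(1, at = c(1, (nt + 1) / 2, nt),
                 labels = c("-pi/2", "0", "pi/2"))
  graphics::axis(2, at = c(1, (np + 1) / 2, np),
                 labels = c("-pi/2", "0", "pi/2"))
  pc <- (x$psi_edges[-1] + x$psi_edges[-(np + 1)]) / 2
  tc <- (x$theta_edges[-1] + x$theta_edges[-(nt + 1)]) / 2
  r <- 0.38
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    graphics::symbols(j, i, circles = 0.45, inches = FALSE, add = TRUE,
                      bg = pal[ci[i, j]], fg = NA)
    # reference edge at azimuth psi + theta/2, second edge rotated by theta
    phi <- pc[i] + tc[j] / 2
    cxa <- j - r * cos(phi) / 2; cya <- i - r * sin(phi) / 2
    cxb <- j + r * cos(phi) / 2; cyb <- i + r * sin(phi) / 2
    graphics::segments(cxa - r / 2, cya, cxa + r / 2, cya, lwd = 2)
    graphics::segments(cxb - r * cos(tc[j]) / 2, cyb - r * sin(tc[j]) / 2,
                       cxb + r * cos(tc[j]) / 2, cyb + r * sin(tc[j]) / 2,
                       lwd = 2)
  }
  title(sprintf("chevron map (%s)", x$mode))
  invisible(x)
}

#' First-order orientation histogram
#'
#' Amplitude-weighted (or unweighted) histogram of edge orientations over
#' `[0, pi)`, normalized to sum to 1.
#'
#' @param edges an `edge_list` (masked if it carries no mask radius).
#' @param n_bins number of orientation bins.
#' @param weighting `"amplitude"` or `"uniform"`.
#' @export
first_order_histogram <- function(edges, n_bins = 12L,
                                  weighting = c("amplitude", "uniform")) {
  weighting <- match.arg(weighting)
  if (is.null(attr(edges, "mask_radius"))) edges <- mask_edges(edges)
  if (!nrow(edges)) stop("no edges after masking")
  brk <- seq(0, pi, length.out = n_bins + 1)
  i <- bin_index(edges$theta %% pi, brk)
  w <- if (weighting == "amplitude") edges$amplitude else rep(1, nrow(edges))
  out <- numeric(n_bins)
  acc <- rowsum(w, i)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out / sum(out)
}

#' Write / read a co-occurrence histogram (JSON container)
#'
#' Stores the full 4-D table with its bin edges, weighting mode, mask radius
#' and pair counts in a single structured JSON file.
#'
#' @param h a `cooc_hist`.
#' @param path output file.
#' @export
write_cooc <- function(h, path) {
  obj <- list(dims = dim(h$w), w = as.numeric(h$w), d_edges = h$d_edges,
              psi_edges = h$psi_edges, theta_edges = h$theta_edges,
              sigma_edges = h$sigma_edges, weighting = h$weighting,
              n_pairs = h$n_pairs, n_dropped = h$n_dropped,
              mask_radius = h$mask_radius, params_hash = h$params_hash,
              source_id = h$source_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_cooc
#' @export
read_cooc <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = array(o$w, o$dims), d_edges = o$d_edges,
                 psi_edges = o$psi_edges, theta_edges = o$theta_edges,
                 sigma_edges = o$sigma_edges, weighting = o$weighting,
                 n_pairs = as.integer(o$n_pairs),
                 n_dropped = as.integer(o$n_dropped),
                 mask_radius = o$mask_radius,
                 params_hash = o$params_hash, source_id = o$source_id),
            class = "cooc_hist")
}
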