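#' Greedy sparse edge extraction (matching pursuit)
#'
#' Decomposes an image into a discrete list of oriented edges by matching
#' pursuit over the log-Gabor dictionary: at each step the (scale,
#' orientation, position) triple with the largest coefficient modulus is
#' selected, recorded as an edge, and its best-phase real atom is subtracted
#' from the residual; all coefficients are then re-derived exactly from the
#' new residual. Iteration stops after `n_edges` selections or as soon as the
#' residual energy falls to `residual_target` times the initial energy,
#' whichever comes first. The image is mean-subtracted before analysis
#' (log-Gabor kernels carry no DC, so the mean is unrecoverable by
#' construction).
#'
#' Ties in the coefficient modulus are broken toward the lowest
#' (scale, orientation, y, x) in lexicographic order, making the
#' decomposition fully deterministic.
#'
#' @param image numeric matrix matching the bank's `image_shape`.
#' @param bank a [build_filterbank()] object.
#' @param n_edges maximum number of edges to extract (>= 1).
#' @param residual_target stop once residual energy / initial energy falls to
#'   this fraction (in (0, 1)).
#' @param source_id optional identifier stored with the edge list.
#' @return an object of class `sparse_fit` with components:
#'   \describe{
#'     \item{edges}{an `edge_list`: data frame with columns `x`, `y`
#'       (0-based pixel coordinates, x = column), `theta` (radians in
#'       `[0, pi)`), `scale_index` (1-based), `amplitude`, `phase`, in
#'       selection order.}
#'     \item{residual}{the residual image (matrix).}
#'     \item{initial_energy, residual_energy}{mean squared pixel energies.}
#'     \item{residual_trace}{residual energy fraction after each selection.}
#'     \item{target_not_reached}{TRUE if `n_edges` was exhausted before the
#'       residual target.}
#'   }
#' @seealso [reconstruct_image()], [residual_energy()]
#' @export
extract_edges <- function(image, bank, n_edges = 2048L,
                          residual_target = 0.05, source_id = NULL) {
  check_image(image, bank)
  if (n_edges < 1) stop("n_edges must be >= 1")
  if (residual_target <= 0 || residual_target >= 1)
    stop("residual_target must be in (0, 1)")
  x <- image - mean(image)
  out <- cpp_mp(mp_kernels(bank), fft(x) + 0i, as.integer(n_edges),
                residual_target)
  sel <- out$sel
  no <- bank$params$n_orientations
  k0 <- if (nrow(sel)) sel[, 1] else numeric(0)
  edges <- data.frame(
    x = if (nrow(sel)) sel[, 2] else numeric(0),
    y = if (nrow(sel)) sel[, 3] else numeric(0),
    theta = (k0 %% no) * pi / no,
    scale_index = k0 %/% no + 1,
    amplitude = if (nrow(sel)) sel[, 4] else numeric(0),
    phase = if (nrow(sel)) sel[, 5] else numeric(0))
  edges <- as_edge_list(edges, image_shape = bank$params$image_shape,
                        source_id = source_id,
                        params_hash = params_hash(bank$params))
  ntot <- prod(bank$params$image_shape)
  residual <- Re(fft(out$residual_hat, inverse = TRUE)) / ntot
  fit <- list(edges = edges, residual = residual,
              initial_energy = out$initial_energy,
              residual_energy = out$residual_energy,
              residual_trace = as.numeric(out$residual_trace),
              target_not_reached = !out$target_reached,
              n_edges = as.integer(n_edges),
              residual_target = residual_target,
              bank_params = bank$params, source_id = source_id)
  class(fit) <- "sparse_fit"
  fit
}

#' Construct an edge list
#'
#' An `edge_list` is a data frame of edges (`x`, `y`, `theta`, `scale_index`,
#' `amplitude`, `phase`) carrying the image geometry as attributes.
#'
#' @param edges data frame with at least `x`, `y`, `theta`, `scale_index`,
#'   `amplitude` (a `phase` column is added as 0 if absent).
#' @param image_shape `c(rows, cols)` of the source image.
#' @param source_id optional image identifier.
#' @param params_hash optional hash of the extraction parameters.
#' @param mask_radius optional mask radius in pixels (set by the statistics
#'   stage if absent).
#' @export
as_edge_list <- function(edges, image_shape, source_id = NULL,
                         params_hash = NULL, mask_radius = NULL) {
  need <- c("x", "y", "theta", "scale_index", "amplitude")
  if (!all(need %in% names(edges)))
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  if (is.null(edges$phase)) edges$phase <- rep(0, nrow(edges))
  edges <- as.data.frame(edges)[, c(need, "phase")]
  if (nrow(edges)) {
    stopifnot(all(edges$amplitude >= 0),
              all(edges$theta >= 0 & edges$theta < pi),
              all(edges$x >= 0 & edges$x < image_shape[2]),
              all(edges$y >= 0 & edges$y < image_shape[1]))
  }
  structure(edges, image_shape = as.integer(image_shape),
            source_id = source_id, params_hash = params_hash,
            mask_radius = mask_radius,
            class = c("edge_list", "data.frame"))
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat("sparse log-Gabor edge decomposition\n")
  cat(sprintf("  %d edges extracted (budget %d), residual energy %.2f%%%s\n",
              nrow(x$edges), x$n_edges,
              100 * x$residual_energy / max(x$initial_energy, .Machine$double.xmin),
              if (x$target_not_reached) " [target not reached]" else ""))
  invisible(x)
}

#' @export
summary.sparse_fit <- function(object, ...) {
  e <- object$edges
  s <- list(n_edges = nrow(e),
            residual_fraction = object$residual_energy /
              max(object$initial_energy, .Machine$double.xmin),
            target_not_reached = object$target_not_reached,
            amplitude_range = range(if (nrow(e)) e$amplitude else NA),
            scales = table(factor(e$scale_index,
                                  levels = seq_len(object$bank_params$n_scales))))
  class(s) <- "summary.sparse_fit"
  s
}

#' @export
print.summary.sparse_fit <- function(x, ...) {
  cat(sprintf("edges: %d   residual: %.3f%%%s\n", x$n_edges,
              100 * x$residual_fraction,
              if (x$target_not_reached) " (budget exhausted)" else ""))
  cat("edges per scale:\n"); print(x$scales)
  invisible(x)
}

#' @export
coef.sparse_fit <- function(object, ...) object$edges$amplitude

#' @export
residuals.sparse_fit <- function(object, ...) object$residual

#' @export
fitted.sparse_fit <- function(object, bank = NULL, ...) {
  if (is.null(bank)) bank <- build_filterbank(object$bank_params)
  reconstruct_image(object$edges, bank)
}

#' @export
plot.sparse_fit <- function(x, bank = NULL, max_edges = Inf, ...) {
  img <- x$residual + if (is.null(bank))
    fitted(x) else fitted(x, bank = bank)
  plot_edges(x$edges, image = img, max_edges = max_edges, ...)
  invisible(x)
}

#' Overlay an edge list on an image
#'
#' Draws each edge as a line segment centered at its position, oriented at
#' its `theta`, with length proportional to the scale's wavelength.
#'
#' @param edges an `edge_list`.
#' @param image optional background matrix.
#' @param bank_params `filter_params` used to map scale indices to lengths
#'   (defaults are used if NULL).
#' @param max_edges draw at most this many (strongest first).
#' @param ... passed to [graphics::image()].
#' @export
plot_edges <- function(edges, image = NULL, bank_params = NULL,
                       max_edges = Inf, ...) {
  shp <- attr(edges, "image_shape")
  if (is.null(bank_params)) bank_params <- filter_params(image_shape = shp)
  if (!is.null(image)) {
    graphics::image(0:(ncol(image)), 0:(nrow(image)),
                    t(image)[, rev(seq_len(nrow(image))), drop = FALSE],
                    col = gray(seq(0, 1, length.out = 64)), asp = 1,
                    xlab = "x", ylab = "y", ...)
  } else {
    plot(NA, xlim = c(0, shp[2]), ylim = c(0, shp[1]), asp = 1,
         xlab = "x", ylab = "y")
  }
  e <- edges[seq_len(min(nrow(edges), max_edges)), , drop = FALSE]
  if (!nrow(e)) return(invisible(edges))
  lambda <- (1 / bank_params$base_frequency) *
    bank_params$scale_ratio^(e$scale_index - 1)
  # y axis flipped for display (origin top-left in pixel coordinates)
  y <- nrow_shape(shp) - e$y
  dx <- cos(e$theta) * lambda / 2
  dy <- -sin(e$theta) * lambda / 2
  graphics::segments(e$x - dx, y - dy, e$x + dx, y + dy, col = "red")
  invisible(edges)
}

nrow_shape <- function(shp) shp[1]

#' Reconstruct an image from an edge list
#'
#' Sums, for every edge, the real dictionary atom at the recorded position,
#' scale, orientation, amplitude and phase. The reconstruction of an empty
#' edge list is the zero image.
#'
#' @param edges an `edge_list` (or a `sparse_fit`).
#' @param bank a [build_filterbank()] object.
#' @return numeric matrix of the bank's `image_shape`.
#' @export
reconstruct_image <- function(edges, bank) {
  if (inherits(edges, "sparse_fit")) edges <- edges$edges
  shp <- bank$params$image_shape
  if (!nrow(edges)) return(matrix(0, shp[1], shp[2]))
  if (any(edges$scale_index < 1 | edges$scale_index > bank$params$n_scales))
    stop("edge list contains scale_index values outside the bank's range")
  no <- bank$params$n_orientations
  oi <- round(edges$theta / (pi / no))
  if (any(abs(edges$theta - oi * pi / no) > 1e-9))
    stop("edge orientations do not lie on the bank's orientation grid")
  kidx <- (edges$scale_index - 1) * no + (oi %% no)
  cpp_synthesize(mp_kernels(bank), as.integer(kidx),
                 as.integer(round(edges$x)), as.integer(round(edges$y)),
                 edges$amplitude, edges$phase)
}

#' Residual energy fraction of an edge decomposition
#'
#' Energy of (image - reconstruction) divided by the energy of the
#' (mean-subtracted) image. Defined as 0 for a zero-energy image.
#'
#' @inheritParams reconstruct_image
#' @param image the original image.
#' @export
residual_energy <- function(image, edges, bank) {
  check_image(image, bank)
  x <- image - mean(image)
  e0 <- mean(x^2)
  if (e0 == 0) return(0)
  mean((x - reconstruct_image(edges, bank))^2) / e0
}

#' Hash of a parameter object
#'
#' MD5 digest of a canonical serialization; used to stamp artifacts so that
#' statistics computed under different settings are never mixed.
#'
#' @param x any serializable R object.
#' @return hex string.
#' @export
params_hash <- function(x) {
  x <- unclass(x)
  if (!is.null(names(x))) x <- x[order(names(x))]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x, control = "exact"), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Write / read an edge list as CSV with a JSON sidecar
#'
#' The CSV has columns `source_id,x,y,theta,scale_index,amplitude,phase`;
#' numeric fields are written with 17 significant digits so that the
#' round-trip is exact. A sidecar `<path>.json` stores `image_shape`,
#' `mask_radius` and `params_hash`.
#'
#' @param edges an `edge_list`.
#' @param path CSV file path.
#' @export
write_edges <- function(edges, path) {
  if (inherits(edges, "sparse_fit")) edges <- edges$edges
  df <- data.frame(
    source_id = rep(attr(edges, "source_id") %||% "", nrow(edges)),
    x = sprintf("%.17g", edges$x), y = sprintf("%.17g", edges$y),
    theta = sprintf("%.17g", edges$theta),
    scale_index = edges$scale_index,
    amplitude = sprintf("%.17g", edges$amplitude),
    phase = sprintf("%.17g", edges$phase))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(image_shape = attr(edges, "image_shape"),
               mask_radius = attr(edges, "mask_radius"),
               params_hash = attr(edges, "params_hash"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_edges
#' @param path CSV file path written by [write_edges()].
#' @export
read_edges <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    source_id = "character", x = "numeric", y = "numeric",
    theta = "numeric", scale_index = "integer", amplitude = "numeric",
    phase = "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sid <- if (nrow(df) && nzchar(df$source_id[1])) df$source_id[1] else NULL
  as_edge_list(df[, -1], image_shape = meta$image_shape,
               source_id = sid, params_hash = meta$params_hash,
               mask_radius = meta$mask_radius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
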