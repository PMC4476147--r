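#' Specification of a synthetic contour-image class
#'
#' Describes a class of images made of smooth contours drawn as chains of
#' oriented odd-symmetric Gabor strokes. Successive stroke orientations turn
#' by `curvature * step` radians, so `curvature_mean = 0` yields straight
#' chains (collinear pair statistics) and a nonzero mean yields arcs of
#' radius `1/curvature` (co-circular pair statistics). Each contour draws
#' its curvature as `sign * N(curvature_mean, curvature_dispersion^2)` with
#' a random sign, plus a small per-step orientation jitter.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_contours contours per image.
#' @param n_steps strokes per contour.
#' @param stroke_wavelength carrier wavelength of the strokes in pixels
#'   (match a dictionary scale: wavelengths are `4 * 2^(s-1)` under the
#'   default bank).
#' @param step stroke spacing along the contour, pixels (default half the
#'   wavelength).
#' @param curvature_mean mean unsigned curvature, 1/pixels.
#' @param curvature_dispersion SD of the per-contour curvature draw.
#' @param orientation_jitter SD of the extra per-step direction noise,
#'   radians.
#' @param amplitude stroke amplitude; each stroke's amplitude is jittered by
#'   a factor `1 + U(-amplitude_jitter, amplitude_jitter)`.
#' @param amplitude_jitter relative amplitude jitter.
#' @param background_rms RMS of the added 1/f noise background, relative to
#'   the RMS of the rendered contours (0 disables the background).
#' @param stroke_style `"gabor"` renders analytic odd-symmetric Gabor
#'   strokes with continuous positions and orientations; `"atom"` snaps
#'   positions to the pixel grid and orientations to the default
#'   dictionary's orientation channels and renders exact log-Gabor atoms,
#'   so that matching pursuit can recover the planted parameters exactly.
#' @param seed integer seed; the same spec and seed give bit-identical
#'   images.
#' @export
fixture_spec <- function(image_shape = c(64L, 64L), n_contours = 3L,
                         n_steps = 12L, stroke_wavelength = 8,
                         step = stroke_wavelength / 2, curvature_mean = 0,
                         curvature_dispersion = 0.002,
                         orientation_jitter = 0.03, amplitude = 1,
                         amplitude_jitter = 0.2, background_rms = 0.2,
                         stroke_style = c("gabor", "atom"), seed = 1L) {
  stroke_style <- match.arg(stroke_style)
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            n_contours >= 1, n_steps >= 2, stroke_wavelength > 0,
            step > 0, curvature_mean >= 0, curvature_dispersion >= 0,
            background_rms >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_contours = as.integer(n_contours),
                 n_steps = as.integer(n_steps),
                 stroke_wavelength = stroke_wavelength, step = step,
                 curvature_mean = curvature_mean,
                 curvature_dispersion = curvature_dispersion,
                 orientation_jitter = orientation_jitter,
                 amplitude = amplitude,
                 amplitude_jitter = amplitude_jitter,
                 background_rms = background_rms,
                 stroke_style = stroke_style, seed = as.integer(seed)),
            class = "fixture_spec")
}

# odd-symmetric Gabor stroke added in place; returns the canvas
render_stroke <- function(canvas, x0, y0, theta, lambda, amp) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  sig_par <- lambda / 2; sig_perp <- lambda / 4
  w <- ceiling(3 * sig_par)
  xs <- max(0, floor(x0) - w):min(nx - 1, ceiling(x0) + w)
  ys <- max(0, floor(y0) - w):min(ny - 1, ceiling(y0) + w)
  if (!length(xs) || !length(ys)) return(canvas)
  gx <- outer(rep(1, length(ys)), xs - x0)
  gy <- outer(ys - y0, rep(1, length(xs)))
  u <- gx * cos(theta) + gy * sin(theta)      # along the stroke
  v <- -gx * sin(theta) + gy * cos(theta)     # across the stroke
  patch <- amp * exp(-(u^2 / (2 * sig_par^2) + v^2 / (2 * sig_perp^2))) *
    sin(2 * pi * v / lambda)
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + patch
  canvas
}

#' Seeded 1/f spatial noise
#'
#' White Gaussian noise shaped to a 1/f amplitude spectrum (the canonical
#' natural-image spectrum), zero mean, scaled to a target RMS.
#'
#' @param image_shape `c(rows, cols)`.
#' @param rms target root-mean-square amplitude.
#' @param seed optional seed.
#' @export
onef_noise <- function(image_shape, rms = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ny <- image_shape[1]; nx <- image_shape[2]
  white <- matrix(rnorm(ny * nx), ny, nx)
  f <- sqrt(outer(fft_freqs(ny)^2, fft_freqs(nx)^2, `+`))
  shape <- ifelse(f > 0, 1 / f, 0)
  z <- Re(fft(fft(white) * shape, inverse = TRUE)) / (ny * nx)
  z <- z - mean(z)
  if (stats::sd(z) > 0) z <- z * rms / sqrt(mean(z^2))
  z
}

#' Generate one synthetic contour image
#'
#' Draws the contour chains of a [fixture_spec()] onto a blank canvas, adds
#' the 1/f background, and returns both the image and the planted strokes as
#' a ground-truth edge list. Strokes whose centers leave the frame (with a
#' half-wavelength margin) are clipped and counted.
#'
#' @param spec a [fixture_spec()].
#' @return list with `image` (matrix), `truth` (an `edge_list` of planted
#'   strokes: continuous positions and orientations, `scale_index` mapped to
#'   the nearest dictionary scale), and `n_clipped`.
#' @export
generate_contour_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  canvas <- matrix(0, ny, nx)
  margin <- spec$stroke_wavelength / 2
  r_start <- 0.30 * min(ny, nx)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  truth <- vector("list", spec$n_contours)
  n_clipped <- 0L
  scale_index <- max(1, round(log2(spec$stroke_wavelength / 4)) + 1)
  for (k in seq_len(spec$n_contours)) {
    rr <- r_start * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
    x <- cx + rr * cos(aa); y <- cy + rr * sin(aa)
    dir <- runif(1, 0, 2 * pi)
    kap <- sample(c(-1, 1), 1) *
      rnorm(1, spec$curvature_mean, spec$curvature_dispersion)
    rows <- list()
    for (s in seq_len(spec$n_steps)) {
      if (x < margin || x > nx - 1 - margin ||
          y < margin || y > ny - 1 - margin) {
        n_clipped <- n_clipped + 1L
        break
      }
      amp <- spec$amplitude *
        (1 + runif(1, -spec$amplitude_jitter, spec$amplitude_jitter))
      # the chain's vertices lie on a common circle; the tangent at a vertex
      # bisects the incoming and outgoing chords, i.e. the outgoing chord
      # direction minus half the turn angle
      th <- (dir - kap * spec$step / 2) %% pi
      xs <- x; ys <- y
      if (spec$stroke_style == "atom") {
        th <- (round(th / (pi / 8)) %% 8) * (pi / 8)
        xs <- round(x); ys <- round(y)
      } else {
        canvas <- render_stroke(canvas, x, y, th, spec$stroke_wavelength,
                                amp)
      }
      rows[[s]] <- data.frame(x = xs, y = ys, theta = th,
                              scale_index = scale_index, amplitude = amp,
                              phase = 0)
      x <- x + spec$step * cos(dir)
      y <- y + spec$step * sin(dir)
      dir <- dir + kap * spec$step + rnorm(1, 0, spec$orientation_jitter)
    }
    truth[[k]] <- do.call(rbind, rows)
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(x = numeric(0), y = numeric(0), theta = numeric(0),
                        scale_index = integer(0), amplitude = numeric(0),
                        phase = numeric(0))
  image <- canvas
  if (spec$stroke_style == "atom" && nrow(truth)) {
    bank <- build_filterbank(filter_params(image_shape = spec$image_shape))
    image <- reconstruct_image(
      as_edge_list(truth, image_shape = spec$image_shape), bank)
  }
  if (spec$background_rms > 0) {
    contour_rms <- sqrt(mean(image^2))
    if (contour_rms == 0) contour_rms <- 1
    image <- image + onef_noise(spec$image_shape,
                                rms = spec$background_rms * contour_rms)
  }
  list(image = image,
       truth = as_edge_list(truth, image_shape = spec$image_shape,
                            source_id = sprintf("synth-seed%d", spec$seed)),
       n_clipped = n_clipped)
}

#' Plant exact dictionary atoms in a 1/f background
#'
#' Builds a "natural-like" test image as a sum of randomly placed,
#' bank-matched real log-Gabor atoms plus optional 1/f noise. Because the
#' strokes are exact dictionary elements, matching pursuit can recover their
#' parameters sharply, which makes this the fixture of choice for
#' parameter-recovery and residual-energy tests.
#'
#' @param bank a [build_filterbank()] object.
#' @param n_strokes number of planted atoms.
#' @param seed integer seed.
#' @param background_rms 1/f background RMS relative to the stroke-image
#'   RMS.
#' @param scale_indices candidate scales for the atoms.
#' @param amplitude_range atom amplitudes drawn uniformly from this range.
#' @param min_separation minimum pairwise center distance in pixels (0
#'   disables the check; used to plant well-separated atoms).
#' @return list with `image` and `truth` (edge list of planted atoms).
#' @export
planted_stroke_image <- function(bank, n_strokes = 30L, seed = 1L,
                                 background_rms = 0.2,
                                 scale_indices = NULL,
                                 amplitude_range = c(0.5, 1.5),
                                 min_separation = 0) {
  set.seed(as.integer(seed))
  p <- bank$params
  ny <- p$image_shape[1]; nx <- p$image_shape[2]
  if (is.null(scale_indices))
    scale_indices <- seq_len(max(2, p$n_scales - 2))
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  rmax <- 0.4 * min(ny, nx)
  xs <- ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n_strokes) {
    if ((attempts <- attempts + 1L) > 10000L * n_strokes)
      stop("cannot place ", n_strokes, " strokes at min_separation ",
           min_separation, " in a ", ny, " x ", nx, " image")
    x <- round(cx + runif(1, -rmax, rmax))
    y <- round(cy + runif(1, -rmax, rmax))
    if (min_separation > 0 && length(xs) &&
        min(sqrt((xs - x)^2 + (ys - y)^2)) < min_separation) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  oi <- sample.int(p$n_orientations, n_strokes, replace = TRUE) - 1
  si <- scale_indices[sample.int(length(scale_indices), n_strokes,
                                 replace = TRUE)]
  truth <- data.frame(
    x = xs, y = ys, theta = oi * pi / p$n_orientations,
    scale_index = si,
    amplitude = runif(n_strokes, amplitude_range[1], amplitude_range[2]),
    phase = runif(n_strokes, -pi, pi))
  truth <- truth[order(-truth$amplitude), ]
  rownames(truth) <- NULL
  truth <- as_edge_list(truth, image_shape = p$image_shape,
                        source_id = sprintf("planted-seed%d", seed))
  image <- reconstruct_image(truth, bank)
  if (background_rms > 0)
    image <- image + onef_noise(p$image_shape,
                                rms = background_rms * sqrt(mean(image^2)))
  list(image = image, truth = truth)
}

child_seed <- function(master, class_idx, image_idx) {
  (as.integer(master) %% 100000L * 10007L + class_idx * 7561L +
     image_idx * 13L) %% 2147483647L
}

#' Generate a labeled synthetic dataset
#'
#' Renders `n_per_class` images for each class spec, with per-image seeds
#' derived deterministically from `seed`. Optionally writes the images as
#' grayscale PNG plus a `manifest.csv` (`path,label,seed`).
#'
#' @param class_specs named list of [fixture_spec()] objects (>= 2).
#' @param n_per_class images per class.
#' @param seed master seed.
#' @param dir output directory (NULL keeps everything in memory).
#' @return list with `images` (list of matrices), `truths` (list of edge
#'   lists), and `manifest` (data frame with `id`, `label`, `seed`, and
#'   `path` when written).
#' @export
generate_dataset <- function(class_specs, n_per_class = 100L, seed = 1L,
                             dir = NULL) {
  if (length(class_specs) < 2) stop("need at least 2 class specs")
  if (is.null(names(class_specs)))
    names(class_specs) <- paste0("class", seq_along(class_specs))
  images <- list(); truths <- list(); manifest <- list()
  n <- 0L
  for (ci in seq_along(class_specs)) {
    label <- names(class_specs)[ci]
    for (i in seq_len(n_per_class)) {
      sp <- class_specs[[ci]]
      sp$seed <- child_seed(seed, ci, i)
      out <- generate_contour_image(sp)
      n <- n + 1L
      id <- sprintf("%s-%03d", label, i)
      attr(out$truth, "source_id") <- id
      images[[n]] <- out$image
      truths[[n]] <- out$truth
      manifest[[n]] <- data.frame(id = id, label = label, seed = sp$seed)
    }
  }
  manifest <- do.call(rbind, manifest)
  names(images) <- names(truths) <- manifest$id
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      paths[i] <- file.path(dir, paste0(manifest$id[i], ".png"))
      if (file.exists(paths[i]))
        stop("output path collision: ", paths[i])
      img <- images[[i]]
      rng <- range(img)
      img01 <- if (diff(rng) > 0) (img - rng[1]) / diff(rng)
               else img * 0 + 0.5
      png::writePNG(img01, paths[i])
    }
    manifest$path <- paths
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, truths = truths, manifest = manifest)
}
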