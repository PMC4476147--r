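#' Default pipeline configuration
#'
#' A nested list mirroring every tunable of the pipeline: dictionary
#' parameters, sparse-coding budget, histogram binning, mask rule,
#' classification settings, noise condition and seeds. Serializable to YAML;
#' [config_hash()] of the configuration is stamped into every artifact so
#' that incompatible histograms are never mixed.
#'
#' @param image_shape image shape the pipeline expects.
#' @export
default_config <- function(image_shape = c(256L, 256L)) {
  list(
    filter = list(n_orientations = 8L, n_scales = 5L, base_frequency = 0.25,
                  scale_ratio = 2, bandwidth_freq = 0.4,
                  bandwidth_theta = pi / 16,
                  image_shape = as.integer(image_shape)),
    sparse = list(n_edges = 2048L, residual_target = 0.05),
    binning = list(n_d = 6L, n_psi = 12L, n_theta = 12L, n_sigma = 5L,
                   d_min = 2, sigma_range = c(-2, 2), d_scale = "pixels"),
    mask = list(fraction = 0.45),
    stats = list(weighting = "amplitude"),
    classify = list(n_resamples = 20L, train_frac = 0.8, cost = 1,
                    seed = 1L),
    noise = list(snr_factor = 0.5),
    seed = 1L)
}

#' Hash of a pipeline configuration
#'
#' @param config a configuration list.
#' @export
config_hash <- function(config) params_hash(config)

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(base)) {
    if (is.list(base[[sec]])) {
      for (k in names(base[[sec]]))
        if (!is.null(cfg[[sec]][[k]])) base[[sec]][[k]] <- cfg[[sec]][[k]]
    } else if (!is.null(cfg[[sec]])) base[[sec]] <- cfg[[sec]]
  }
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_bank <- function(config) {
  f <- config$filter
  build_filterbank(filter_params(
    n_orientations = f$n_orientations, n_scales = f$n_scales,
    base_frequency = f$base_frequency, scale_ratio = f$scale_ratio,
    bandwidth_freq = f$bandwidth_freq, bandwidth_theta = f$bandwidth_theta,
    image_shape = f$image_shape))
}

config_binning <- function(config) {
  b <- config$binning
  cooc_binning(n_d = b$n_d, n_psi = b$n_psi, n_theta = b$n_theta,
               n_sigma = b$n_sigma, d_range = c(b$d_min, NA),
               sigma_range = b$sigma_range, d_scale = b$d_scale)
}

#' Read an image file as a grayscale matrix
#'
#' PNG input; color images are converted with Rec. 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path PNG file.
#' @export
read_image_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) return(a)
  if (dim(a)[3] >= 3)
    return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
  a[, , 1]
}

#' Run a pipeline stage
#'
#' Orchestrates the full analysis as reproducible batch stages:
#' \describe{
#'   \item{synth}{render the configured synthetic dataset to `out_dir`
#'     (PNG + manifest).}
#'   \item{extract}{PNG images in `in_dir` -> one edge CSV per image in
#'     `out_dir`, plus `extract_report.json` with residual energies.}
#'   \item{stats}{edge CSVs in `in_dir` -> one histogram JSON per image,
#'     plus pooled per-label histograms and chevron-map CSV exports when a
#'     `manifest.csv` provides labels.}
#'   \item{classify}{histogram JSONs + manifest labels -> resampled SVM F1
#'     report (JSON) for the requested feature mode.}
#'   \item{compare}{two pooled histograms (`inputs = c(a.json, b.json)`) ->
#'     divergence report, factorization gaps and ratio-map CSV; when
#'     `in_dir` also holds per-image histograms and a manifest, adds the
#'     per-image KL-delta bias analysis with its d-prime.}
#' }
#' Every JSON artifact carries the configuration hash; `classify` and
#' `compare` refuse histogram files stamped with a different hash.
#'
#' @param subcommand one of `"synth"`, `"extract"`, `"stats"`,
#'   `"classify"`, `"compare"`.
#' @param config configuration list (see [default_config()]).
#' @param in_dir input directory (stage-dependent).
#' @param out_dir output directory, created if missing.
#' @param inputs explicit input files (used by `compare`).
#' @param mode feature mode for `classify`: `"SO"`, `"CM"` or `"FO"`.
#' @param noise if TRUE, `extract` degrades each image with the configured
#'   noise condition first.
#' @param synth_specs named list of [fixture_spec()] for `synth` (defaults
#'   to a straight-vs-curved pair at the configured image shape).
#' @param n_per_class images per class for `synth`.
#' @return invisibly, a list of produced artifact paths (plus `failures`).
#' @export
run_pipeline <- function(subcommand, config = default_config(),
                         in_dir = NULL, out_dir = NULL, inputs = NULL,
                         mode = "SO", noise = FALSE, synth_specs = NULL,
                         n_per_class = 20L) {
  subcommand <- match.arg(subcommand,
                          c("synth", "extract", "stats", "classify",
                            "compare"))
  hash <- config_hash(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  switch(subcommand,
    synth = {
      if (is.null(out_dir)) stop("synth needs --out")
      if (is.null(synth_specs))
        synth_specs <- list(
          straight = fixture_spec(image_shape = config$filter$image_shape),
          curved = fixture_spec(image_shape = config$filter$image_shape,
                                curvature_mean = 0.05))
      ds <- generate_dataset(synth_specs, n_per_class = n_per_class,
                             seed = config$seed, dir = out_dir)
      invisible(list(manifest = file.path(out_dir, "manifest.csv")))
    },
    extract = {
      if (is.null(in_dir) || is.null(out_dir))
        stop("extract needs --in and --out")
      files <- list.files(in_dir, pattern = "\\.png$", full.names = TRUE)
      if (!length(files)) stop("no PNG images found in ", in_dir)
      bank <- config_bank(config)
      report <- list(); failures <- character(0); outs <- character(0)
      for (fi in seq_along(files)) {
        f <- files[fi]
        id <- sub("\\.png$", "", basename(f))
        res <- tryCatch({
          img <- read_image_gray(f)
          if (noise)
            img <- add_noise(img, config$noise$snr_factor,
                             seed = child_seed(config$seed, 1L, fi))
          fit <- extract_edges(img, bank, n_edges = config$sparse$n_edges,
                               residual_target =
                                 config$sparse$residual_target,
                               source_id = id)
          out <- file.path(out_dir, paste0(id, ".csv"))
          attr(fit$edges, "params_hash") <- hash
          write_edges(fit$edges, out)
          outs <- c(outs, out)
          report[[id]] <- list(
            n_edges = nrow(fit$edges),
            residual_fraction = fit$residual_energy /
              max(fit$initial_energy, .Machine$double.xmin),
            target_not_reached = fit$target_not_reached)
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res)) {
          failures <- c(failures, paste0(id, ": ", res))
          message("extract failed for ", id, ": ", res)
        }
      }
      jsonlite::write_json(list(config_hash = hash, images = report,
                                failures = failures),
                           file.path(out_dir, "extract_report.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(list(edges = outs, failures = failures))
    },
    stats = {
      if (is.null(in_dir) || is.null(out_dir))
        stop("stats needs --in and --out")
      files <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
      files <- files[basename(files) != "manifest.csv"]
      if (!length(files)) stop("no edge CSVs found in ", in_dir)
      binning <- config_binning(config)
      outs <- character(0); failures <- character(0)
      hists <- list()
      for (f in files) {
        id <- sub("\\.csv$", "", basename(f))
        res <- tryCatch({
          edges <- read_edges(f)
          edges <- mask_edges(edges, default_mask_radius(
            attr(edges, "image_shape"), config$mask$fraction))
          h <- cooc_histogram(edges, binning = binning,
                              weighting = config$stats$weighting,
                              scale_ratio = config$filter$scale_ratio,
                              base_frequency = config$filter$base_frequency)
          h$params_hash <- hash
          out <- file.path(out_dir, paste0(id, ".hist.json"))
          write_cooc(h, out)
          hists[[id]] <- h
          outs <- c(outs, out)
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res)) failures <- c(failures, paste0(id, ": ", res))
      }
      manifest_path <- file.path(in_dir, "manifest.csv")
      if (!file.exists(manifest_path))
        manifest_path <- file.path(dirname(in_dir), "manifest.csv")
      if (file.exists(manifest_path)) {
        man <- utils::read.csv(manifest_path)
        for (lab in unique(man$label)) {
          ids <- intersect(man$id[man$label == lab], names(hists))
          if (!length(ids)) next
          pooled <- pool_cooc(hists[ids])
          write_cooc(pooled, file.path(out_dir,
                                       paste0("pooled-", lab, ".hist.json")))
          cm <- chevron_map(pooled)
          utils::write.csv(cm$map,
                           file.path(out_dir,
                                     paste0("chevron-", lab, ".csv")),
                           row.names = FALSE)
        }
      }
      invisible(list(histograms = outs, failures = failures))
    },
    classify = {
      if (is.null(in_dir) || is.null(out_dir))
        stop("classify needs --in and --out")
      man <- utils::read.csv(locate_manifest(in_dir))
      files <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
      files <- files[basename(files) != "manifest.csv"]
      edge_lists <- lapply(files, read_edges)
      hashes <- unique(vapply(edge_lists,
                              function(e) attr(e, "params_hash") %||% "",
                              character(1)))
      if (length(hashes) > 1)
        stop("refusing to mix edge lists produced under different ",
             "configurations")
      ids <- vapply(seq_along(files), function(i)
        attr(edge_lists[[i]], "source_id") %||%
          sub("\\.csv$", "", basename(files[i])), character(1))
      labels <- man$label[match(ids, man$id)]
      keep <- !is.na(labels)
      x <- make_features(edge_lists[keep], mode = mode,
                         binning = config_binning(config),
                         weighting = config$stats$weighting,
                         scale_ratio = config$filter$scale_ratio,
                         base_frequency = config$filter$base_frequency)
      cv <- crossval_f1(x, labels[keep],
                        n_resamples = config$classify$n_resamples,
                        seed = config$classify$seed,
                        train_frac = config$classify$train_frac,
                        cost = config$classify$cost)
      out <- file.path(out_dir, paste0("classify-", mode, ".json"))
      jsonlite::write_json(list(config_hash = hash, mode = mode,
                                classes = cv$classes,
                                f1_scores = cv$f1,
                                mean_f1_percent = 100 * cv$mean_f1,
                                sd_f1_percent = 100 * cv$sd_f1),
                           out, auto_unbox = TRUE, digits = NA)
      print(cv)
      invisible(list(report = out, cv = cv))
    },
    compare = {
      if (is.null(inputs) || length(inputs) != 2)
        stop("compare needs two histogram files via inputs=")
      ha <- read_cooc(inputs[1]); hb <- read_cooc(inputs[2])
      check_compatible(ha, hb)
      if (!is.null(ha$params_hash) && !is.null(hb$params_hash) &&
          !identical(ha$params_hash, hb$params_hash))
        stop("refusing to compare histograms produced under different ",
             "configurations")
      rep <- divergence_report(ha, hb)
      fg <- list(a = factorization_gap(ha), b = factorization_gap(hb))
      # per-image bias analysis: when a directory of per-image histograms
      # plus labels is supplied, score every image's KL delta against the
      # two class-average histograms and summarize with d-prime
      bias <- NULL
      if (!is.null(in_dir)) {
        man <- utils::read.csv(locate_manifest(in_dir))
        files <- list.files(in_dir, pattern = "\\.hist\\.json$",
                            full.names = TRUE)
        files <- files[!grepl("^pooled-", basename(files))]
        ids <- sub("\\.hist\\.json$", "", basename(files))
        labs <- man$label[match(ids, man$id)]
        keep <- !is.na(labs) & labs %in% unique(labs)[1:2]
        hists <- lapply(files[keep], read_cooc)
        deltas <- class_bias_deltas(hists, ha, hb)
        groups <- split(deltas, labs[keep])
        bias <- list(labels = names(groups),
                     mean_delta = vapply(groups, mean, numeric(1)),
                     dprime = dprime(groups[[1]], groups[[2]]))
      }
      out <- NULL
      if (!is.null(out_dir)) {
        rm <- ratio_map(ha, hb)
        utils::write.csv(rm$map, file.path(out_dir, "ratio_map.csv"),
                         row.names = FALSE)
        out <- file.path(out_dir, "compare.json")
        jsonlite::write_json(
          list(config_hash = hash, kl_ab = rep$kl_ab, kl_ba = rep$kl_ba,
               js = rep$js,
               factorization = list(
                 a = fg$a[c("kl_full_product", "kl_pair_product")],
                 b = fg$b[c("kl_full_product", "kl_pair_product")]),
               bias = bias),
          out, auto_unbox = TRUE, digits = NA)
      }
      print(rep)
      invisible(list(report = out, divergence = rep,
                     factorization = fg, bias = bias))
    })
}

locate_manifest <- function(in_dir) {
  for (p in c(file.path(in_dir, "manifest.csv"),
              file.path(dirname(in_dir), "manifest.csv")))
    if (file.exists(p)) return(p)
  stop("no manifest.csv found near ", in_dir)
}
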