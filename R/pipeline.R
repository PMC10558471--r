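#' Pipeline configuration
#'
#' Programmatic constructor for a validated pipeline configuration. All
#' violations are reported together, not first-failure.
#'
#' @param input_dir Directory of section images; each image `x.tif`/`x.png`
#'   pairs with the label mask `x_mask.tif` (override with `mask_overrides`).
#' @param output_dir Directory for `results.csv`, `report.csv`,
#'   `manifest.json` and `audit.jsonl`.
#' @param pixel_size_mm Pixel edge length in millimetres (from the
#'   acquisition metadata; never parsed from file tags).
#' @param channel_order Channel roles in storage order.
#' @param label_names Named label dictionary, see [region_label_map()].
#' @param denoiser `"none"`, `"threshold"` or `"dncnn"`.
#' @param threshold_cutoff Cutoff for the threshold denoiser, on the native
#'   intensity scale.
#' @param weights_file DnCNN weights container for `denoiser = "dncnn"`
#'   (see [save_dncnn_weights()]).
#' @param quantification A [quant_params()] list.
#' @param stats_variant,stats_alpha t-test variant and significance level for
#'   the report.
#' @param mask_overrides Optional named list mapping image basenames to mask
#'   paths.
#' @param seed Integer master seed recorded in the manifest; all pipeline
#'   randomness (none at inference time) derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            pixel_size_mm = 0.002,
                            channel_order = c("pgp95_red", "dapi_blue"),
                            label_names = c(`1` = "epidermis", `2` = "dermis"),
                            denoiser = "none", threshold_cutoff = NULL,
                            weights_file = NULL,
                            quantification = quant_params(),
                            stats_variant = "welch", stats_alpha = 0.05,
                            mask_overrides = NULL, seed = 0L) {
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  if (!is.character(input_dir) || length(input_dir) != 1L || !dir.exists(input_dir)) {
    note(sprintf("input_dir: directory not found ('%s')", input_dir))
  }
  if (!is.character(output_dir) || length(output_dir) != 1L) {
    note("output_dir: must be a single path")
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    note("pixel_size_mm: must be a single positive number")
  }
  roles <- c("pgp95_red", "dapi_blue", "other")
  if (!all(channel_order %in% roles)) {
    note(sprintf("channel_order: unknown role(s) %s",
                 paste(setdiff(channel_order, roles), collapse = ", ")))
  }
  if (!"pgp95_red" %in% channel_order) {
    note("channel_order: must include pgp95_red (the quantified channel)")
  }
  if (!denoiser %in% c("none", "threshold", "dncnn")) {
    note(sprintf("denoiser: unknown name '%s' (none|threshold|dncnn)", denoiser))
  }
  if (identical(denoiser, "threshold") &&
      (is.null(threshold_cutoff) || !is.numeric(threshold_cutoff) ||
       threshold_cutoff < 0)) {
    note("threshold_cutoff: required (non-negative) for denoiser 'threshold'")
  }
  if (identical(denoiser, "dncnn") &&
      (is.null(weights_file) || !file.exists(weights_file))) {
    note("weights_file: required and must exist for denoiser 'dncnn'")
  }
  qp <- tryCatch(
    if (inherits(quantification, "quant_params")) quantification
    else do.call(quant_params, quantification),
    error = function(e) { note(paste("quantification:", conditionMessage(e))); NULL })
  if (!stats_variant %in% c("welch", "pooled")) {
    note(sprintf("stats_variant: unknown '%s' (welch|pooled)", stats_variant))
  }
  if (!is.numeric(stats_alpha) || stats_alpha <= 0 || stats_alpha >= 1) {
    note("stats_alpha: must lie in (0, 1)")
  }
  lbl <- tryCatch({
    region_label_map(matrix(as.integer(names(label_names))[1], 1, 1), label_names)
    label_names
  }, error = function(e) { note(paste("label_names:", conditionMessage(e))); NULL })
  if (length(errs) > 0L) {
    stop(paste(c("invalid pipeline configuration:",
                 paste0("  - ", errs)), collapse = "\n"), call. = FALSE)
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 pixel_size_mm = pixel_size_mm, channel_order = channel_order,
                 label_names = lbl, denoiser = denoiser,
                 threshold_cutoff = threshold_cutoff,
                 weights_file = weights_file, quantification = qp,
                 stats_variant = stats_variant, stats_alpha = stats_alpha,
                 mask_overrides = mask_overrides, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a YAML pipeline configuration
#'
#' Reads a YAML file, fills documented defaults, and returns a validated
#' [pipeline_config()]. Every violation is listed in the error message.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("config must be a YAML mapping", call. = FALSE)
  args <- list()
  for (f in c("input_dir", "output_dir", "pixel_size_mm", "denoiser",
              "threshold_cutoff", "weights_file", "stats_variant",
              "stats_alpha", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$channel_order)) args$channel_order <- unlist(y$channel_order)
  if (!is.null(y$label_names)) {
    args$label_names <- stats::setNames(unlist(y$label_names),
                                        names(y$label_names))
  }
  if (!is.null(y$quantification)) args$quantification <- y$quantification
  do.call(pipeline_config, args)
}

parse_day_from_id <- function(sample_id) {
  m <- regmatches(sample_id, regexpr("day\\s*0*([0-9]+)", sample_id))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub("day\\s*0*", "", m))
}

#' Run the full quantification pipeline over a directory
#'
#' For every image in the input directory: read it and its paired label
#' mask, denoise the PGP9.5 channel per the configured denoiser, quantify
#' every compartment plus the whole section, and collect the density
#' records. Per-image failures are logged to stderr and skipped; the batch
#' continues. Writes `results.csv` (deterministic, byte-identical across
#' reruns with the same inputs and config), a per-image `audit.jsonl` of
#' backgrounds and thresholds, `manifest.json`, and — when a `reepi.csv` is
#' present and at least two days are covered — the time-course `report.csv`.
#'
#' @param config A [pipeline_config()] (or a YAML path, which is passed to
#'   [validate_config()]).
#' @return Invisibly, a list of class `innerva_run`: `records`, `report`
#'   (an `innerva_timecourse` or `NULL`), `skipped` (character), `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  files <- sort(list.files(config$input_dir,
                           pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE))
  files <- files[!grepl("_mask\\.", files)]
  if (length(files) == 0L) stop("no images found in input_dir", call. = FALSE)

  model <- if (identical(config$denoiser, "dncnn")) {
    load_dncnn_weights(config$weights_file)
  } else NULL

  records <- list()
  audit <- list()
  skipped <- character(0)
  for (f in files) {
    base <- tools::file_path_sans_ext(f)
    res <- tryCatch({
      mask_path <- if (!is.null(config$mask_overrides) &&
                       base %in% names(config$mask_overrides)) {
        config$mask_overrides[[base]]
      } else {
        cand <- file.path(config$input_dir,
                          paste0(base, "_mask.", tools::file_ext(f)))
        if (!file.exists(cand)) {
          cand2 <- list.files(config$input_dir, full.names = TRUE,
                              pattern = paste0("^", base, "_mask\\."))
          if (length(cand2) > 0) cand2[1] else cand
        } else cand
      }
      img <- read_image(file.path(config$input_dir, f), config$pixel_size_mm,
                        config$channel_order, sample_id = base,
                        day = parse_day_from_id(base))
      map <- read_label_map(mask_path, config$label_names)
      red <- get_channel(img, "pgp95_red")
      if (!identical(dim(red$pixels), dim(map$labels))) {
        stop("image and mask shapes differ")
      }
      red_dn <- switch(config$denoiser,
        none = red,
        threshold = threshold_denoise(red, config$threshold_cutoff),
        dncnn = denoise(model, red))
      img <- replace_channel(img, red_dn)
      recs <- quantify_image(img, map, config$quantification)
      list(recs = recs)
    }, error = function(e) {
      message(sprintf("[innervaquant] skipping '%s': %s", f,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      skipped <- c(skipped, f)
    } else {
      records[[base]] <- res$recs
      audit[[base]] <- list(
        sample_id = base, day = parse_day_from_id(base),
        compartments = lapply(seq_len(nrow(res$recs)), function(i) {
          r <- res$recs[i, ]
          list(compartment = r$compartment, background = r$background,
               threshold = r$threshold, positive_pixels = r$positive_pixels)
        }))
    }
  }
  if (length(records) == 0L) stop("every image failed; nothing to report",
                                  call. = FALSE)
  records <- dplyr::bind_rows(records)

  results_path <- file.path(config$output_dir, "results.csv")
  readr::write_csv(records, results_path)
  audit_path <- file.path(config$output_dir, "audit.jsonl")
  writeLines(vapply(audit, function(a) {
    as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA))
  }, character(1)), audit_path)

  report <- NULL
  reepi_path <- file.path(config$input_dir, "reepi.csv")
  if (file.exists(reepi_path) &&
      length(unique(stats::na.omit(records$day))) >= 2L) {
    reepi <- readr::read_csv(reepi_path, show_col_types = FALSE)
    report <- timecourse_report(records, reepi,
                                variant = config$stats_variant,
                                alpha = config$stats_alpha)
    readr::write_csv(report$tests, file.path(config$output_dir, "report.csv"))
    readr::write_csv(report$summaries,
                     file.path(config$output_dir, "report_summaries.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("innervaquant")),
    config = config[setdiff(names(config), "mask_overrides")],
    n_images = length(files), n_quantified = length(audit),
    skipped = skipped,
    r_squared = if (!is.null(report)) report$fit$r_squared else NULL,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  invisible(structure(list(records = records, report = report,
                           skipped = skipped,
                           paths = list(results = results_path,
                                        audit = audit_path,
                                        manifest = file.path(config$output_dir,
                                                             "manifest.json"))),
                      class = "innerva_run"))
}

#' @export
print.innerva_run <- function(x, ...) {
  cat(sprintf("<pipeline run> %d density records, %d skipped image(s)\n",
              nrow(x$records), length(x$skipped)))
  if (!is.null(x$report)) {
    cat(sprintf("time-course R^2 = %.3f\n", x$report$fit$r_squared))
  }
  invisible(x)
}
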