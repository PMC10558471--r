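#' Specification for a synthetic wound section
#'
#' Describes an immunofluorescence-like section: dim curvilinear nerve fibers
#' over a nonuniform autofluorescent background in the red (PGP9.5) channel,
#' nuclei blobs in the blue (DAPI) channel, and additive Gaussian sensor
#' noise. Everything is seeded, and the clean pre-noise image is retained so
#' denoisers can be scored against ground truth.
#'
#' @param shape Raster dimensions `c(rows, cols)`, at least 64 x 64.
#' @param pixel_size_mm Pixel edge length in millimetres.
#' @param bit_depth Storage bit depth (8 or 16).
#' @param fiber_count Number of fibers to draw (ignored when
#'   `target_area_fraction` is set).
#' @param target_area_fraction Optional: keep adding fibers until the
#'   ground-truth fiber mask covers at least this fraction of the labelled
#'   area.
#' @param fiber_length_px Range (min, max) of fiber path lengths in pixels.
#' @param fiber_width_px Range of the Gaussian cross-profile sigma in pixels.
#' @param fiber_intensity Mean and SD of the per-fiber peak amplitude on
#'   `[0, 1]`.
#' @param fiber_epidermis_fraction Probability that a fiber lies in the
#'   epidermis (intraepidermal) rather than the dermis.
#' @param background_level Flat background level on `[0, 1]`.
#' @param autofluorescence_blobs List with `count`, `size` (Gaussian sigma,
#'   px) and `amplitude` of blob-like autofluorescent confounders.
#' @param noise_sigma Additive Gaussian noise SD on `[0, 1]`.
#' @param noise_model `"gaussian"` (default) or `"poisson_gaussian"` (scaled
#'   Poisson shot noise plus Gaussian read noise) for stress tests.
#' @param nuclei_count Number of nuclei in the blue channel.
#' @param region_geometry List with `epidermis_band_fraction` (top rows that
#'   are epidermis) and `wound_gap_fraction` (central columns forming the
#'   wound center, flanked by the outer edges).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(160L, 160L), pixel_size_mm = 0.002,
                           bit_depth = 8L,
                           fiber_count = 8L, target_area_fraction = NULL,
                           fiber_length_px = c(25, 60),
                           fiber_width_px = c(0.8, 1.6),
                           fiber_intensity = c(mean = 0.65, sd = 0.05),
                           fiber_epidermis_fraction = 0.4,
                           background_level = 0.08,
                           autofluorescence_blobs = list(count = 4, size = 5,
                                                         amplitude = 0.10),
                           noise_sigma = 15 / 255,
                           noise_model = c("gaussian", "poisson_gaussian"),
                           nuclei_count = 40L,
                           region_geometry = list(epidermis_band_fraction = 0.25,
                                                  wound_gap_fraction = 0.4),
                           seed = 0L) {
  noise_model <- match.arg(noise_model)
  if (any(shape < 64L)) stop("`shape` must be at least 64 x 64", call. = FALSE)
  stopifnot(pixel_size_mm > 0, bit_depth %in% c(8L, 16L),
            fiber_count >= 0, background_level >= 0, background_level <= 1,
            noise_sigma >= 0,
            fiber_intensity[["mean"]] > 0, fiber_intensity[["mean"]] <= 1,
            fiber_epidermis_fraction >= 0, fiber_epidermis_fraction <= 1,
            region_geometry$epidermis_band_fraction >= 0,
            region_geometry$epidermis_band_fraction <= 1,
            region_geometry$wound_gap_fraction >= 0,
            region_geometry$wound_gap_fraction <= 1)
  if (!is.null(target_area_fraction)) {
    stopifnot(target_area_fraction >= 0, target_area_fraction < 0.5)
  }
  structure(list(shape = as.integer(shape), pixel_size_mm = pixel_size_mm,
                 bit_depth = as.integer(bit_depth),
                 fiber_count = as.integer(fiber_count),
                 target_area_fraction = target_area_fraction,
                 fiber_length_px = fiber_length_px,
                 fiber_width_px = fiber_width_px,
                 fiber_intensity = fiber_intensity,
                 fiber_epidermis_fraction = fiber_epidermis_fraction,
                 background_level = background_level,
                 autofluorescence_blobs = autofluorescence_blobs,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 nuclei_count = as.integer(nuclei_count),
                 region_geometry = region_geometry, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Stamp one fiber (momentum random walk, Gaussian cross-profile) onto the
# canvas, restricted to the rows of its compartment. Returns the updated
# canvas and the half-peak ground-truth mask of this fiber.
draw_fiber <- function(canvas, rows_allowed, spec) {
  H <- nrow(canvas); W <- ncol(canvas)
  sigma <- stats::runif(1, spec$fiber_width_px[1], spec$fiber_width_px[2])
  amp <- min(1, max(0.1, stats::rnorm(1, spec$fiber_intensity[["mean"]],
                                      spec$fiber_intensity[["sd"]])))
  len <- round(stats::runif(1, spec$fiber_length_px[1], spec$fiber_length_px[2]))
  r <- stats::runif(1, rows_allowed[1], rows_allowed[2])
  c0 <- stats::runif(1, 1, W)
  theta <- stats::runif(1, 0, 2 * pi)
  rad <- ceiling(3 * sigma)
  prof <- matrix(0, H, W)
  for (i in seq_len(len)) {
    theta <- theta + stats::rnorm(1, 0, 0.25)
    r <- r + sin(theta)
    c0 <- c0 + cos(theta)
    if (r < rows_allowed[1]) { r <- rows_allowed[1]; theta <- -theta }
    if (r > rows_allowed[2]) { r <- rows_allowed[2]; theta <- -theta }
    if (c0 < 1) { c0 <- 1; theta <- pi - theta }
    if (c0 > W) { c0 <- W; theta <- pi - theta }
    ri <- max(1L, floor(r - rad)):min(H, ceiling(r + rad))
    ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    d2 <- outer((ri - r)^2, (ci - c0)^2, `+`)
    prof[ri, ci] <- pmax(prof[ri, ci], exp(-d2 / (2 * sigma^2)))
  }
  keep <- matrix(FALSE, H, W)
  keep[rows_allowed[1]:rows_allowed[2], ] <- TRUE
  prof[!keep] <- 0
  list(canvas = pmax(canvas, amp * prof), mask = prof >= 0.5)
}

#' Generate one synthetic wound section with ground truth
#'
#' Draws seeded curvilinear fibers (momentum random walks with a Gaussian
#' cross-profile) confined to their compartment, adds blob-like
#' autofluorescence and a flat background, injects sensor noise, and builds
#' the paired region map, ground-truth half-peak fiber mask, and nuclei
#' (blue) channel. The clean pre-noise red channel is retained for PSNR
#' oracles.
#'
#' @param spec A [synthetic_spec()].
#' @param sample_id,day Metadata stored on the generated image.
#' @return A list of class `synthetic_section`: `image`
#'   ([multichannel_image()]), `region_map` (epidermis/dermis),
#'   `subregion_map` (outer_edge_1 / wound_center / outer_edge_2),
#'   `fiber_mask`, `true_area_fraction`, `clean` (noise-free red channel on
#'   `[0, 1]`), and the `spec`.
#' @export
generate_section <- function(spec, sample_id = "synthetic", day = NA_integer_) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$shape[1]; W <- spec$shape[2]

  ep_rows <- max(1L, round(spec$region_geometry$epidermis_band_fraction * H))
  labels <- matrix(2L, H, W)
  if (spec$region_geometry$epidermis_band_fraction > 0) {
    labels[seq_len(ep_rows), ] <- 1L
  }
  region_map <- region_label_map(labels, c(`1` = "epidermis", `2` = "dermis"))

  gap <- round(spec$region_geometry$wound_gap_fraction * W)
  side <- (W - gap) %/% 2L
  sub <- matrix(2L, H, W)
  if (side > 0L) {
    sub[, seq_len(side)] <- 1L
    sub[, seq.int(W - side + 1L, W)] <- 3L
  }
  subregion_map <- region_label_map(
    sub, c(`1` = "outer_edge_1", `2` = "wound_center", `3` = "outer_edge_2"))

  canvas <- matrix(0, H, W)
  mask <- matrix(FALSE, H, W)
  labelled <- sum(labels > 0L)
  one_fiber <- function() {
    in_epi <- ep_rows > 1L && stats::runif(1) < spec$fiber_epidermis_fraction
    rows <- if (in_epi) c(1L, ep_rows) else c(min(ep_rows + 1L, H), H)
    draw_fiber(canvas, rows, spec)
  }
  if (!is.null(spec$target_area_fraction)) {
    max_fibers <- 50L + ceiling(spec$target_area_fraction * labelled / 10)
    n_drawn <- 0L
    while (sum(mask) / labelled < spec$target_area_fraction) {
      if (n_drawn >= max_fibers) {
        stop("target area fraction unachievable for this raster", call. = FALSE)
      }
      f <- one_fiber()
      canvas <- f$canvas
      mask <- mask | f$mask
      n_drawn <- n_drawn + 1L
    }
  } else {
    for (i in seq_len(spec$fiber_count)) {
      f <- one_fiber()
      canvas <- f$canvas
      mask <- mask | f$mask
    }
  }

  af <- matrix(0, H, W)
  blobs <- spec$autofluorescence_blobs
  for (i in seq_len(blobs$count)) {
    r <- stats::runif(1, 1, H); c0 <- stats::runif(1, 1, W)
    s <- blobs$size * stats::runif(1, 0.6, 1.4)
    a <- blobs$amplitude * stats::runif(1, 0.5, 1)
    rad <- ceiling(3 * s)
    ri <- max(1L, floor(r - rad)):min(H, ceiling(r + rad))
    ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    d2 <- outer((ri - r)^2, (ci - c0)^2, `+`)
    af[ri, ci] <- af[ri, ci] + a * exp(-d2 / (2 * s^2))
  }

  clean <- pmin(pmax(spec$background_level + af + canvas, 0), 1)
  noisy <- switch(spec$noise_model,
    gaussian = clean + stats::rnorm(H * W, sd = spec$noise_sigma),
    poisson_gaussian = {
      scale <- 50
      stats::rpois(H * W, clean * scale) / scale +
        stats::rnorm(H * W, sd = spec$noise_sigma / 2)
    })
  noisy <- matrix(pmin(pmax(noisy, 0), 1), H, W)

  blue <- matrix(0, H, W)
  for (i in seq_len(spec$nuclei_count)) {
    r <- stats::runif(1, 1, H); c0 <- stats::runif(1, 1, W)
    s <- stats::runif(1, 1.5, 3)
    rad <- ceiling(3 * s)
    ri <- max(1L, floor(r - rad)):min(H, ceiling(r + rad))
    ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    d2 <- outer((ri - r)^2, (ci - c0)^2, `+`)
    blue[ri, ci] <- pmax(blue[ri, ci], 0.6 * exp(-d2 / (2 * s^2)))
  }
  blue <- matrix(pmin(pmax(blue + stats::rnorm(H * W, sd = spec$noise_sigma / 2),
                           0), 1), H, W)

  hi <- 2^spec$bit_depth - 1
  image <- multichannel_image(
    list(channel_image(round(noisy * hi), spec$bit_depth, "pgp95_red",
                       spec$pixel_size_mm),
         channel_image(round(blue * hi), spec$bit_depth, "dapi_blue",
                       spec$pixel_size_mm)),
    sample_id = sample_id, day = day)

  structure(list(image = image, region_map = region_map,
                 subregion_map = subregion_map, fiber_mask = mask,
                 true_area_fraction = sum(mask & labels > 0L) / labelled,
                 clean = clean, spec = spec),
            class = "synthetic_section")
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(sprintf("<synthetic_section> %d x %d, true fiber area fraction %.4f\n",
              x$spec$shape[1], x$spec$shape[2], x$true_area_fraction))
  invisible(x)
}

#' Ground-truth density records of a synthetic section
#'
#' Computes, from the generator's fiber mask, the density record each
#' compartment would have under perfect classification.
#'
#' @param fixture A [generate_section()] result.
#' @return A tibble of density records (background/threshold are `NA`).
#' @export
true_density_records <- function(fixture) {
  stopifnot(inherits(fixture, "synthetic_section"))
  map <- fixture$region_map
  ps <- fixture$image$channels[[1]]$pixel_size_mm
  sels <- list(epidermis = map$labels == label_of(map, "epidermis"),
               dermis = map$labels == label_of(map, "dermis"),
               whole = map$labels > 0L)
  purrr::map_dfr(names(sels), function(comp) {
    sel <- sels[[comp]]
    n_lab <- sum(sel)
    pos <- sum(fixture$fiber_mask[sel])
    tibble::tibble(sample_id = fixture$image$sample_id,
                   day = fixture$image$day, region = "wound_bed",
                   compartment = comp, positive_pixels = as.integer(pos),
                   area_mm2 = n_lab * ps^2,
                   density = if (n_lab > 0) pos / (n_lab * ps^2) else NA_real_,
                   area_fraction = if (n_lab > 0) pos / n_lab else NA_real_,
                   background = NA_real_, threshold = NA_real_)
  })
}

#' Generate a dilution series of fiber-bearing sections
#'
#' Sections with strictly increasing true fiber area fraction, all other
#' generator parameters held fixed. Used to check that the estimated density
#' increases monotonically in the truth.
#'
#' @param base A [synthetic_spec()] providing all non-dilution parameters.
#' @param fractions Strictly increasing target area fractions.
#' @param seeds One seed per fraction, or a single seed from which
#'   per-section seeds are derived.
#' @return A list of [generate_section()] results of class
#'   `synthetic_series`.
#' @export
generate_dilution_series <- function(base, fractions, seeds = base$seed) {
  stopifnot(inherits(base, "synthetic_spec"))
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("`fractions` must be strictly increasing", call. = FALSE)
  }
  if (length(seeds) == 1L) {
    seeds <- seeds + seq_along(fractions)
  }
  stopifnot(length(seeds) == length(fractions))
  out <- vector("list", length(fractions))
  prev <- -Inf
  for (i in seq_along(fractions)) {
    spec <- base
    spec$target_area_fraction <- max(fractions[i], prev + 1e-4)
    spec$seed <- as.integer(seeds[i])
    out[[i]] <- generate_section(spec,
                                 sample_id = sprintf("dilution_%02d", i))
    prev <- out[[i]]$true_area_fraction
  }
  structure(out, class = c("synthetic_series", "list"))
}

#' Generate a wound-healing time course with paired re-epithelialization
#'
#' Produces replicate sections per post-wounding day with a day-dependent
#' fiber density shaped like the healing time course (near-zero innervation
#' early, recovering by day 15, intraepidermal fibers only reappearing late),
#' plus a paired re-epithelialization table generated proportional to the
#' day's target density. Fully seeded.
#'
#' @param days Post-wounding days. Default `c(3, 7, 10, 15)`.
#' @param target_fractions Target true fiber area fraction per day. The
#'   default follows the healing time course shape: negligible at day 3,
#'   slight at day 7, clearly increased at day 10 and near-recovered at
#'   day 15.
#' @param epidermis_fractions Per-day probability that a fiber is
#'   intraepidermal (the epidermis only regenerates late).
#' @param reepi_percent Per-day mean re-epithelialization percentage; the
#'   default is proportional to `target_fractions`, capped at 100.
#' @param replicates Sections per day (default 3, as in a triplicate animal
#'   experiment).
#' @param base A [synthetic_spec()] for all other parameters.
#' @param seed Master seed; per-section seeds are derived from it.
#' @return A list of class `synthetic_timecourse`: `sections` (list of
#'   [generate_section()] results) and `reepi` (tibble with `sample_id`,
#'   `day`, `left_length`, `right_length`, `total_wound_length`, `percent`).
#' @export
generate_timecourse <- function(days = c(3L, 7L, 10L, 15L),
                                target_fractions = c(0.005, 0.011, 0.024, 0.042),
                                epidermis_fractions = c(0, 0, 0.2, 0.5),
                                reepi_percent = NULL,
                                replicates = 3L,
                                base = synthetic_spec(),
                                seed = 0L) {
  if (length(days) < 2L) stop("need at least 2 days", call. = FALSE)
  stopifnot(length(target_fractions) == length(days),
            length(epidermis_fractions) == length(days),
            replicates >= 1L)
  if (is.null(reepi_percent)) {
    reepi_percent <- pmin(100, 95 * target_fractions / max(target_fractions))
  }
  stopifnot(length(reepi_percent) == length(days))
  sections <- list()
  reepi <- list()
  set.seed(seed)
  wound_len <- 8 # mm, a standard biopsy-punch wound
  for (i in seq_along(days)) {
    for (r in seq_len(replicates)) {
      spec <- base
      spec$target_area_fraction <- target_fractions[i]
      spec$fiber_epidermis_fraction <- epidermis_fractions[i]
      spec$seed <- as.integer(seed + 1000L * i + r)
      sid <- sprintf("day%02d_rep%d", days[i], r)
      sections[[sid]] <- generate_section(spec, sample_id = sid,
                                          day = days[i])
      pct <- min(100, max(0, reepi_percent[i] + stats::rnorm(1, 0, 2)))
      covered <- pct / 100 * wound_len
      split <- stats::runif(1, 0.3, 0.7)
      reepi[[sid]] <- tibble::tibble(
        sample_id = sid, day = days[i],
        left_length = covered * split, right_length = covered * (1 - split),
        total_wound_length = wound_len, percent = pct)
    }
  }
  structure(list(sections = sections, reepi = dplyr::bind_rows(reepi)),
            class = "synthetic_timecourse")
}

#' Write a synthetic time course to disk
#'
#' Writes each section's image and region mask as TIFFs (mask basename is
#' the image basename plus `_mask`), the paired re-epithelialization CSV,
#' and a ground-truth JSON — the on-disk layout [run_pipeline()] consumes.
#'
#' @param tc A [generate_timecourse()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_timecourse <- function(tc, dir) {
  stopifnot(inherits(tc, "synthetic_timecourse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (sec in tc$sections) {
    sid <- sec$image$sample_id
    write_image(sec$image, file.path(dir, paste0(sid, ".tif")))
    write_label_map(sec$region_map, file.path(dir, paste0(sid, "_mask.tif")))
    truth[[sid]] <- list(day = sec$image$day,
                         true_area_fraction = sec$true_area_fraction)
  }
  readr::write_csv(tc$reepi, file.path(dir, "reepi.csv"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Clean training patches for desk-scale denoiser training
#'
#' Extracts non-overlapping clean (pre-noise) patches from seeded synthetic
#' sections, the standard training input for [train_dncnn()].
#'
#' @param n Number of patches.
#' @param size Patch edge length in pixels.
#' @param seed Integer seed.
#' @return A list of `size x size` matrices with intensities in `[0, 1]`.
#' @export
dncnn_training_patches <- function(n = 64L, size = 32L, seed = 0L) {
  patches <- vector("list", n)
  k <- 1L
  s <- 0L
  per_side <- 96L %/% size
  while (k <= n) {
    s <- s + 1L
    sec <- generate_section(synthetic_spec(
      shape = c(96L, 96L), fiber_count = 12L, seed = seed + 7919L * s))
    for (i in seq_len(per_side) - 1L) {
      for (j in seq_len(per_side) - 1L) {
        if (k > n) break
        patches[[k]] <- sec$clean[i * size + seq_len(size),
                                  j * size + seq_len(size)]
        k <- k + 1L
      }
    }
  }
  patches
}

#' Train the desk-scale DnCNN on the standard seeded fixture
#'
#' Convenience wrapper: builds a compact residual denoiser (depth 7, 16
#' filters — a desk-scale configuration of the same Conv+BN+ReLU residual
#' architecture) and trains it for `steps` Adam steps on `n_patches` clean
#' 32 x 32 synthetic patches with additive Gaussian noise of SD
#' `sigma`.
#'
#' @param seed Integer seed driving patch generation, initialization and
#'   training noise.
#' @param steps Optimizer steps. Default 200.
#' @param n_patches Number of clean patches. Default 64.
#' @param sigma Training noise SD. Default 15/255.
#' @return A list with `model` and `report`, as [train_dncnn()].
#' @export
train_desk_dncnn <- function(seed = 0L, steps = 200L, n_patches = 64L,
                             sigma = 15 / 255) {
  patches <- dncnn_training_patches(n = n_patches, seed = seed)
  model <- build_dncnn(dncnn_config(depth = 7L, filters = 16L, seed = seed))
  train_dncnn(model, patches, sigma = sigma, steps = steps, seed = seed)
}

#' Packaged dim-fiber and bright-fiber comparison fixtures
#'
#' `dim_fiber_fixture()` draws fibers whose intensity distribution overlaps
#' a conventional background cutoff, so a threshold denoiser removes genuine
#' neurite pixels; `bright_fiber_fixture()` draws fibers far above the
#' cutoff with minimal autofluorescence, where both denoising paths should
#' recover the ground-truth fiber area. Each result carries a
#' `suggested_cutoff` field (native 8-bit intensity scale) for
#' [compare_denoisers()].
#'
#' @param seed Integer seed.
#' @return A [generate_section()] result with an extra `suggested_cutoff`.
#' @export
dim_fiber_fixture <- function(seed = 0L) {
  sec <- generate_section(synthetic_spec(
    shape = c(160L, 160L), target_area_fraction = 0.05,
    fiber_intensity = c(mean = 0.30, sd = 0.03),
    autofluorescence_blobs = list(count = 3, size = 5, amplitude = 0.05),
    noise_sigma = 15 / 255, seed = seed), sample_id = "dim_fiber")
  sec$suggested_cutoff <- 90
  sec
}

#' @rdname dim_fiber_fixture
#' @export
bright_fiber_fixture <- function(seed = 0L) {
  sec <- generate_section(synthetic_spec(
    shape = c(160L, 160L), target_area_fraction = 0.10,
    fiber_intensity = c(mean = 0.85, sd = 0.02),
    autofluorescence_blobs = list(count = 2, size = 4, amplitude = 0.03),
    noise_sigma = 15 / 255, seed = seed), sample_id = "bright_fiber")
  sec$suggested_cutoff <- 38
  sec
}
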