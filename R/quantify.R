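#' Quantification parameters
#'
#' Bundles the tunable parameters of the positive-pixel statistic.
#'
#' @param low_fraction Fraction of the region's lowest pixel values defining
#'   the "low spectrum" used for background estimation. Default 0.25.
#' @param outlier_fraction Fraction of values removed as outliers by the
#'   distance-to-median rule. Default 0.05.
#' @param threshold_scope `"per_region"` computes background, outlier
#'   exclusion and the Q3/maximum threshold separately in every compartment;
#'   `"per_image"` computes them once over all labelled pixels and shares the
#'   threshold across compartments.
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(low_fraction = 0.25, outlier_fraction = 0.05,
                         threshold_scope = c("per_region", "per_image")) {
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(low_fraction > 0, low_fraction < 1,
            outlier_fraction >= 0, outlier_fraction < 1)
  structure(list(low_fraction = low_fraction,
                 outlier_fraction = outlier_fraction,
                 threshold_scope = threshold_scope),
            class = "quant_params")
}

#' Pixel values of a labelled region
#'
#' Returns the intensities of all pixels carrying `label`, in row-major order
#' (top row left-to-right first). This is the "list of R values" every
#' downstream statistic is computed from.
#'
#' @param channel A [channel_image()].
#' @param map A [region_label_map()] of the same shape.
#' @param label Integer region label.
#' @return Numeric vector of intensities.
#' @export
pixel_values <- function(channel, map, label) {
  stopifnot(inherits(channel, "channel_image"), inherits(map, "region_label_map"))
  if (!identical(dim(channel$pixels), dim(map$labels))) {
    stop("channel and label map shapes differ", call. = FALSE)
  }
  sel <- map$labels == label
  if (!any(sel)) stop(sprintf("region %s is empty", label), call. = FALSE)
  values_row_major(channel$pixels, sel)
}

# row-major extraction of selected pixels
values_row_major <- function(pixels, sel) {
  idx <- which(sel, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  pixels[idx[ord, , drop = FALSE]]
}

#' Summary statistics of an intensity list
#'
#' Minimum, maximum, mean, median, first and third quartiles and the IQR.
#' Quartiles use linear interpolation between order statistics (the inclusive
#' method, `stats::quantile(type = 7)`), so `c(1:8)` gives Q1 = 2.75 and
#' Q3 = 6.25.
#'
#' @param values Non-empty numeric vector.
#' @return A list of class `pixel_stats`.
#' @export
compute_stats <- function(values) {
  if (length(values) == 0L || anyNA(values)) {
    stop("`values` must be non-empty and free of NA", call. = FALSE)
  }
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(minimum = min(values), maximum = max(values),
                 mean = mean(values), median = q[2],
                 q1 = q[1], q3 = q[3], iqr = q[3] - q[1]),
            class = "pixel_stats")
}

#' @export
print.pixel_stats <- function(x, ...) {
  cat(sprintf(
    "<pixel_stats> min %.4g | q1 %.4g | median %.4g | mean %.4g | q3 %.4g | max %.4g (iqr %.4g)\n",
    x$minimum, x$q1, x$median, x$mean, x$q3, x$maximum, x$iqr))
  invisible(x)
}

#' Median-distance outlier exclusion
#'
#' Removes exactly `floor(fraction * n)` values with the largest absolute
#' distance from the median. Ties are broken by removing the larger value
#' first, then the later (row-major) position. Every removed distance is at
#' least as large as every retained distance.
#'
#' @param values Numeric vector (length >= 1).
#' @param fraction Fraction to remove, in `[0, 1)`. Default 0.05.
#' @return List with `retained` and `removed` (original order preserved
#'   within each), plus `removed_idx` (positions removed).
#' @export
exclude_outliers <- function(values, fraction = 0.05) {
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)", call. = FALSE)
  k <- floor(fraction * n)
  if (k == 0L) {
    return(list(retained = values, removed = values[0], removed_idx = integer(0)))
  }
  d <- abs(values - stats::median(values))
  ord <- order(d, values, seq_len(n), decreasing = TRUE)
  rm_idx <- sort(ord[seq_len(k)])
  list(retained = values[-rm_idx], removed = values[rm_idx], removed_idx = rm_idx)
}

#' Estimate the background intensity of a region
#'
#' The background is the mean of the region's "low spectrum": the lowest
#' `low_fraction` of pixel values, after removing the `outlier_fraction` of
#' that subset farthest from its median (see [exclude_outliers()]). It serves
#' as the reference level subtracted from every pixel, making sections with
#' different staining backgrounds comparable. The estimator is monotone and
#' translation-equivariant: shifting all intensities by a constant shifts the
#' background by exactly that constant.
#'
#' @param values Numeric vector of region intensities (length >= 4).
#' @param low_fraction Fraction of lowest values forming the low spectrum.
#' @param outlier_fraction Fraction removed inside the low spectrum.
#' @return A list of class `background_estimate` with fields `value`,
#'   `n_pixels_used`, `low_fraction`, `outlier_fraction`.
#' @export
estimate_background <- function(values, low_fraction = 0.25,
                                outlier_fraction = 0.05) {
  if (length(values) < 4L) stop("need at least 4 values", call. = FALSE)
  if (low_fraction <= 0 || low_fraction >= 1) {
    stop("`low_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("`outlier_fraction` must be in [0, 1)", call. = FALSE)
  }
  m <- max(1L, floor(low_fraction * length(values)))
  low <- sort(values)[seq_len(m)]
  kept <- exclude_outliers(low, outlier_fraction)$retained
  structure(list(value = mean(kept), n_pixels_used = length(kept),
                 low_fraction = low_fraction,
                 outlier_fraction = outlier_fraction),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> %.4g (from %d pixels, low %.0f%%, outliers %.0f%%)\n",
              x$value, x$n_pixels_used, 100 * x$low_fraction,
              100 * x$outlier_fraction))
  invisible(x)
}

#' Subtract the background level from a channel
#'
#' Each pixel becomes `max(0, pixel - background)`; shape, bit depth and
#' calibration are preserved. This normalization makes intensity lists from
#' differently stained sections comparable before thresholding.
#'
#' @param channel A [channel_image()].
#' @param bg A [estimate_background()] result, or a single number.
#' @return A new [channel_image()].
#' @export
subtract_background <- function(channel, bg) {
  stopifnot(inherits(channel, "channel_image"))
  b <- if (inherits(bg, "background_estimate")) bg$value else bg
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  out <- channel
  out$pixels <- pmax(channel$pixels - b, 0)
  out
}

#' Classify neurite-positive pixels
#'
#' A pixel is positive when its (background-subtracted) intensity lies closer
#' to the region's maximum than to its third quartile:
#' `(max - v) < (v - q3)`, equivalently `v > (max + q3) / 2`. The inequality
#' is strict — a pixel exactly at the midpoint is negative. Every pixel in
#' the region is classified, including those excluded from threshold
#' estimation. A degenerate region with `max == q3` yields an all-negative
#' mask with a warning.
#'
#' @param channel A [channel_image()] (normally background-subtracted).
#' @param map A [region_label_map()] of the same shape.
#' @param label Integer region label.
#' @param stats A [compute_stats()] result for the region's retained values.
#' @return A list of class `neurite_mask` with a logical `mask` (TRUE only
#'   inside the region) and the `threshold` used.
#' @export
classify_neurites <- function(channel, map, label, stats) {
  stopifnot(inherits(channel, "channel_image"),
            inherits(map, "region_label_map"),
            inherits(stats, "pixel_stats"))
  if (!identical(dim(channel$pixels), dim(map$labels))) {
    stop("channel and label map shapes differ", call. = FALSE)
  }
  sel <- map$labels == label
  thr <- (stats$maximum + stats$q3) / 2
  mask <- matrix(FALSE, nrow(channel$pixels), ncol(channel$pixels))
  if (stats$maximum == stats$q3) {
    warning("degenerate region (maximum equals Q3): no positive pixels",
            call. = FALSE)
  } else {
    v <- channel$pixels[sel]
    mask[sel] <- (stats$maximum - v) < (v - stats$q3)
  }
  structure(list(mask = mask, threshold = thr), class = "neurite_mask")
}

#' Nerve fiber density of a region
#'
#' Density is the count of positive pixels inside the label divided by the
#' region area in mm^2; the resolution-free area fraction (positives over
#' labelled pixels) is reported alongside.
#'
#' @param mask A [classify_neurites()] result.
#' @param map A [region_label_map()] of the same shape.
#' @param label Integer region label.
#' @param pixel_size_mm Pixel edge length in millimetres.
#' @param sample_id,day,region,compartment,background Metadata columns copied
#'   into the record.
#' @return A one-row tibble (a density record) with columns `sample_id`,
#'   `day`, `region`, `compartment`, `positive_pixels`, `area_mm2`,
#'   `density`, `area_fraction`, `background`, `threshold`.
#' @export
compute_density <- function(mask, map, label, pixel_size_mm,
                            sample_id = NA_character_, day = NA_integer_,
                            region = NA_character_,
                            compartment = NA_character_,
                            background = NA_real_) {
  stopifnot(inherits(mask, "neurite_mask"), inherits(map, "region_label_map"))
  if (!identical(dim(mask$mask), dim(map$labels))) {
    stop("mask and label map shapes differ", call. = FALSE)
  }
  sel <- map$labels == label
  n_lab <- sum(sel)
  if (n_lab == 0L) stop(sprintf("region %s has zero area", label), call. = FALSE)
  pos <- sum(mask$mask[sel])
  area <- n_lab * pixel_size_mm^2
  tibble::tibble(
    sample_id = sample_id, day = day, region = region,
    compartment = compartment,
    positive_pixels = as.integer(pos), area_mm2 = area,
    density = pos / area, area_fraction = pos / n_lab,
    background = background, threshold = mask$threshold
  )
}

# Core worker: quantify an arbitrary pixel selection of a channel.
# Returns the record fields plus the classification mask so callers can
# share a threshold across sub-compartments.
quantify_selection <- function(channel, sel, params) {
  idx <- which(sel, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  vals <- channel$pixels[idx[ord, , drop = FALSE]]
  bg <- estimate_background(vals, params$low_fraction, params$outlier_fraction)
  sub <- pmax(vals - bg$value, 0)
  kept <- exclude_outliers(sub, params$outlier_fraction)$retained
  st <- compute_stats(kept)
  # The quartiles are hardened against freak pixels by the median-distance
  # exclusion, but the classification anchors to the genuine signal peak:
  # with sparse innervation (< the exclusion fraction) every fiber pixel is
  # by construction among the farthest-from-median values, and a maximum
  # taken from the pruned list would collapse the midpoint threshold into
  # the background bulk. See the methods vignette.
  st$maximum <- max(sub)
  thr <- (st$maximum + st$q3) / 2
  mask <- matrix(FALSE, nrow(channel$pixels), ncol(channel$pixels))
  degenerate <- st$maximum == st$q3
  if (degenerate) {
    warning("degenerate region (maximum equals Q3): no positive pixels",
            call. = FALSE)
  } else {
    v <- pmax(channel$pixels[sel] - bg$value, 0)
    mask[sel] <- (st$maximum - v) < (v - st$q3)
  }
  list(mask = mask, background = bg$value, threshold = thr, stats = st)
}

#' Quantify one labelled region end-to-end
#'
#' Composes the full positive-pixel statistic on a single region: extract the
#' region's intensity list, estimate and subtract the background, exclude the
#' median-distance outliers, compute Q3 and the maximum on the retained list,
#' classify every region pixel against the `(max + q3) / 2` midpoint, and
#' convert the positive count to a density. The input channel should normally
#' be denoised first (see [denoise()]); callers may opt out.
#'
#' @param channel A [channel_image()].
#' @param map A [region_label_map()] of the same shape.
#' @param label Integer region label.
#' @param params A [quant_params()] list.
#' @param sample_id,day,region,compartment Metadata for the record.
#' @return A one-row density record tibble (see [compute_density()]).
#' @export
quantify_region <- function(channel, map, label, params = quant_params(),
                            sample_id = NA_character_, day = NA_integer_,
                            region = NA_character_,
                            compartment = NA_character_) {
  sel <- map$labels == label
  if (!any(sel)) stop(sprintf("region %s is empty", label), call. = FALSE)
  q <- quantify_selection(channel, sel, params)
  compute_density(structure(list(mask = q$mask, threshold = q$threshold),
                            class = "neurite_mask"),
                  map, label, channel$pixel_size_mm,
                  sample_id = sample_id, day = day, region = region,
                  compartment = compartment, background = q$background)
}

#' Quantify all compartments of a section
#'
#' Produces one density record per compartment named in the label map plus a
#' `"whole"` record over the union of all labelled pixels. Under the default
#' `per_region` scope each compartment gets its own background and threshold;
#' under `per_image` the statistics are computed once over the union and the
#' shared threshold is applied everywhere (whole-region positive counts then
#' equal the sum over compartments).
#'
#' @param image A [multichannel_image()] or a bare [channel_image()]. For a
#'   multichannel image the `pgp95_red` channel is quantified.
#' @param map A [region_label_map()].
#' @param params A [quant_params()] list.
#' @param region Region name recorded in the output (e.g. `"wound_bed"`).
#' @return A tibble of density records, one row per compartment and one for
#'   `"whole"`.
#' @export
quantify_image <- function(image, map, params = quant_params(),
                           region = "wound_bed") {
  if (inherits(image, "multichannel_image")) {
    channel <- get_channel(image, "pgp95_red")
    sample_id <- image$sample_id
    day <- image$day
  } else {
    stopifnot(inherits(image, "channel_image"))
    channel <- image
    sample_id <- NA_character_
    day <- NA_integer_
  }
  if (!identical(dim(channel$pixels), dim(map$labels))) {
    stop("channel and label map shapes differ", call. = FALSE)
  }
  present <- intersect(as.integer(names(map$label_names)),
                       unique(as.vector(map$labels)))
  if (length(present) == 0L) stop("label map has zero analyzable area", call. = FALSE)
  whole_sel <- map$labels > 0L

  one_record <- function(sel, mask_info, compartment) {
    n_lab <- sum(sel)
    pos <- sum(mask_info$mask[sel])
    area <- n_lab * channel$pixel_size_mm^2
    tibble::tibble(
      sample_id = sample_id, day = day, region = region,
      compartment = compartment, positive_pixels = as.integer(pos),
      area_mm2 = area, density = pos / area, area_fraction = pos / n_lab,
      background = mask_info$background, threshold = mask_info$threshold
    )
  }

  if (params$threshold_scope == "per_image") {
    q <- quantify_selection(channel, whole_sel, params)
    recs <- lapply(present, function(lab) {
      one_record(map$labels == lab, q, map$label_names[[as.character(lab)]])
    })
    recs <- c(recs, list(one_record(whole_sel, q, "whole")))
  } else {
    recs <- lapply(present, function(lab) {
      sel <- map$labels == lab
      q <- quantify_selection(channel, sel, params)
      one_record(sel, q, map$label_names[[as.character(lab)]])
    })
    qw <- quantify_selection(channel, whole_sel, params)
    recs <- c(recs, list(one_record(whole_sel, qw, "whole")))
  }
  dplyr::bind_rows(recs)
}
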