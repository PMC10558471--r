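#' Single-channel intensity image with calibration
#'
#' A `channel_image` is a 2-D intensity raster (numeric matrix, rows = image
#' rows, origin at the top-left, 0-based pixel coordinates in all external
#' contracts) together with its bit depth, the biological role of the channel
#' and the physical pixel size. Intensities are stored on the native integer
#' scale `[0, 2^bit_depth - 1]`; nothing is rescaled on construction.
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth Either 8 or 16.
#' @param channel_role One of `"pgp95_red"` (the quantified PGP9.5
#'   immunofluorescence channel), `"dapi_blue"` (nuclear stain, context only)
#'   or `"other"`.
#' @param pixel_size_mm Physical length of one pixel edge in millimetres.
#' @return An object of class `channel_image`.
#' @examples
#' ch <- channel_image(matrix(0:3, 2, 2), bit_depth = 8, pixel_size_mm = 0.001)
#' dim(ch$pixels)
#' @export
channel_image <- function(pixels, bit_depth = 8L,
                          channel_role = c("other", "pgp95_red", "dapi_blue"),
                          pixel_size_mm = 0.001) {
  channel_role <- match.arg(channel_role)
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  hi <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > hi) {
    stop(sprintf("intensities must lie in [0, %d]", hi), call. = FALSE)
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("`pixel_size_mm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         channel_role = channel_role, pixel_size_mm = pixel_size_mm),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %d x %d, %d-bit, role = %s, %.6g mm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$channel_role,
              x$pixel_size_mm))
  invisible(x)
}

#' Multichannel fluorescence image
#'
#' Bundles one or more [channel_image()]s sharing a common shape and
#' calibration, with a sample identifier and the post-wounding day.
#'
#' @param channels List of `channel_image` objects; at most one channel per
#'   role other than `"other"`.
#' @param sample_id Character scalar naming the section.
#' @param day Integer day post-wounding (`NA` for unknown / unwounded).
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, sample_id = "sample", day = NA_integer_) {
  if (!is.list(channels) || length(channels) == 0L ||
      !all(vapply(channels, inherits, logical(1), "channel_image"))) {
    stop("`channels` must be a non-empty list of channel_image objects",
         call. = FALSE)
  }
  shp <- dim(channels[[1]]$pixels)
  ps <- channels[[1]]$pixel_size_mm
  for (ch in channels) {
    if (!identical(dim(ch$pixels), shp)) {
      stop("all channels must share one shape", call. = FALSE)
    }
    if (!identical(ch$pixel_size_mm, ps)) {
      stop("all channels must share one calibration", call. = FALSE)
    }
  }
  roles <- vapply(channels, `[[`, character(1), "channel_role")
  named <- roles[roles != "other"]
  if (anyDuplicated(named)) {
    stop("at most one channel per role", call. = FALSE)
  }
  if (!is.na(day) && (day < 0 || day != as.integer(day))) {
    stop("`day` must be a non-negative integer or NA", call. = FALSE)
  }
  structure(
    list(channels = channels, sample_id = as.character(sample_id),
         day = as.integer(day)),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  roles <- vapply(x$channels, `[[`, character(1), "channel_role")
  cat(sprintf("<multichannel_image> '%s' day %s, %d channel(s): %s\n",
              x$sample_id, ifelse(is.na(x$day), "?", x$day),
              length(x$channels), paste(roles, collapse = ", ")))
  invisible(x)
}

#' Extract the channel with a given role
#'
#' @param image A [multichannel_image()].
#' @param role Channel role to extract.
#' @return The matching [channel_image()].
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "multichannel_image"))
  roles <- vapply(image$channels, `[[`, character(1), "channel_role")
  i <- which(roles == role)
  if (length(i) == 0L) stop(sprintf("no channel with role '%s'", role), call. = FALSE)
  image$channels[[i[1]]]
}

#' Region label map
#'
#' An integer label raster naming the anatomical compartments (epidermis,
#' dermis) and wound subregions (outer edges, wound center) of a section.
#' Label 0 is reserved for excluded/background pixels and never appears in the
#' dictionary.
#'
#' @param labels Integer matrix of region labels.
#' @param label_names Named mapping from label integers (as names) to region
#'   names; every nonzero value occurring in `labels` must be present. Allowed
#'   region names: epidermis, dermis, wound_bed, outer_edge_1, wound_center,
#'   outer_edge_2, excluded.
#' @return An object of class `region_label_map`.
#' @examples
#' m <- region_label_map(matrix(c(0L, 1L, 2L, 2L), 2, 2),
#'                       c(`1` = "epidermis", `2` = "dermis"))
#' @export
region_label_map <- function(labels, label_names) {
  if (!is.matrix(labels) || length(labels) == 0L) {
    stop("`labels` must be a non-empty matrix", call. = FALSE)
  }
  if (anyNA(labels) || any(labels != as.integer(labels)) || min(labels) < 0) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  allowed <- c("epidermis", "dermis", "wound_bed", "outer_edge_1",
               "wound_center", "outer_edge_2", "excluded")
  if (is.null(names(label_names)) || !all(unlist(label_names) %in% allowed)) {
    stop("`label_names` must be a named mapping onto known region names",
         call. = FALSE)
  }
  dict <- as.integer(names(label_names))
  if (anyNA(dict) || any(dict == 0L)) {
    stop("label dictionary keys must be nonzero integers", call. = FALSE)
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, dict)
  if (length(unknown) > 0L) {
    stop(sprintf("labels not in dictionary: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(labels = labels,
         label_names = stats::setNames(as.character(unlist(label_names)),
                                       as.character(dict))),
    class = "region_label_map"
  )
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("<region_label_map> %d x %d, labels: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%s", names(x$label_names), x$label_names),
                    collapse = ", ")))
  invisible(x)
}

#' Integer label of a named region
#'
#' @param map A [region_label_map()].
#' @param name Region name present in the dictionary.
#' @return The integer label.
#' @export
label_of <- function(map, name) {
  stopifnot(inherits(map, "region_label_map"))
  i <- which(map$label_names == name)
  if (length(i) == 0L) stop(sprintf("no region named '%s'", name), call. = FALSE)
  as.integer(names(map$label_names)[i[1]])
}

#' Physical area of a labelled region
#'
#' Area is the pixel count carrying `label` times the squared pixel edge
#' length, i.e. the denominator of the nerve-fiber density (positive pixels
#' per mm^2).
#'
#' @param map A [region_label_map()].
#' @param label Integer label present in the dictionary.
#' @param pixel_size_mm Pixel edge length in millimetres.
#' @return Area in mm^2 (0 when no pixel carries the label).
#' @examples
#' m <- region_label_map(matrix(1L, 100, 100), c(`1` = "dermis"))
#' region_area_mm2(m, 1L, 0.01)  # 1 mm^2
#' @export
region_area_mm2 <- function(map, label, pixel_size_mm) {
  stopifnot(inherits(map, "region_label_map"))
  if (!as.character(label) %in% names(map$label_names)) {
    stop(sprintf("unknown label %s", label), call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size_mm), pixel_size_mm > 0)
  sum(map$labels == label) * pixel_size_mm^2
}
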