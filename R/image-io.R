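#' Read a multichannel section image
#'
#' Reads a TIFF (8- or 16-bit) or PNG (8-bit) image, splits it into channels
#' by index, attaches the user-supplied calibration, and assigns each channel
#' the declared biological role. Channels are split by raw index with no
#' colorimetric conversion: the quantified signal is the raw red-channel
#' intensity. The calibration always comes from the caller (config), never
#' from file tags. 16-bit data are preserved on the native `[0, 65535]` scale.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size_mm Pixel edge length in millimetres.
#' @param channel_order Character vector of roles, one per stored channel, in
#'   storage order. Roles from [channel_image()].
#' @param sample_id,day Metadata forwarded to [multichannel_image()].
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, pixel_size_mm, channel_order = "pgp95_red",
                       sample_id = tools::file_path_sans_ext(basename(path)),
                       day = NA_integer_) {
  raw <- read_raster(path)
  arr <- raw$data
  nch <- if (length(dim(arr)) == 3L) dim(arr)[3] else 1L
  if (nch != length(channel_order)) {
    stop(sprintf("file has %d channel(s) but channel_order names %d",
                 nch, length(channel_order)), call. = FALSE)
  }
  hi <- 2^raw$bit_depth - 1
  chans <- lapply(seq_len(nch), function(k) {
    px <- if (nch == 1L && length(dim(arr)) == 2L) arr else arr[, , k]
    channel_image(round(px * hi), bit_depth = raw$bit_depth,
                  channel_role = channel_order[k],
                  pixel_size_mm = pixel_size_mm)
  })
  multichannel_image(chans, sample_id = sample_id, day = day)
}

#' Write a multichannel image (or single channel) to disk
#'
#' TIFF carries 8- or 16-bit data; PNG is restricted to 8-bit. The write/read
#' pair is bit-identical on the integer intensity scale.
#'
#' @param image A [multichannel_image()] or [channel_image()].
#' @param path Destination; extension selects the format (.tif/.tiff or .png).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "channel_image")) {
    image <- multichannel_image(list(image))
  }
  stopifnot(inherits(image, "multichannel_image"))
  bit <- image$channels[[1]]$bit_depth
  hi <- 2^bit - 1
  mats <- lapply(image$channels, function(ch) ch$pixels / hi)
  arr <- if (length(mats) == 1L) mats[[1]] else {
    simplify2array(mats)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = bit)
  } else if (ext == "png") {
    if (bit != 8L) stop("PNG output is 8-bit only; use TIFF for 16-bit",
                        call. = FALSE)
    png::writePNG(arr, path)
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Read a region label map
#'
#' Reads a single-channel integer raster of region labels and validates it
#' against the label dictionary; any label missing from the dictionary is an
#' error, and 0 always means excluded.
#'
#' @param path Path to a single-channel TIFF or PNG.
#' @param label_names Named mapping, see [region_label_map()].
#' @return A [region_label_map()].
#' @export
read_label_map <- function(path, label_names) {
  raw <- read_raster(path)
  if (length(dim(raw$data)) == 3L) {
    if (dim(raw$data)[3] != 1L) {
      stop("label map must be single-channel", call. = FALSE)
    }
    raw$data <- raw$data[, , 1]
  }
  labels <- round(raw$data * (2^raw$bit_depth - 1))
  storage.mode(labels) <- "integer"
  region_label_map(labels, label_names)
}

#' Write a region label map
#'
#' Labels are stored as a single-channel 16-bit TIFF (or 8-bit PNG when all
#' labels fit), pairing losslessly with [read_label_map()].
#'
#' @param map A [region_label_map()].
#' @param path Destination path (.tif/.tiff or .png).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "region_label_map"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (max(map$labels) > 255L) stop("labels exceed 8-bit PNG range", call. = FALSE)
    png::writePNG(map$labels / 255, path)
  } else {
    stop(sprintf("unsupported format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

# Read a raster as doubles on [0,1] plus its stored bit depth.
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # two-channel (red/blue) TIFFs trigger a harmless libtiff note about
    # non-color extra samples; silence it, keep everything else
    x <- withCallingHandlers(
      tiff::readTIFF(path, info = TRUE),
      warning = function(w) {
        if (grepl("ExtraSamples|Photometric", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    list(data = unclass_keep_dim(x), bit_depth = as.integer(bits))
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    list(data = unclass_keep_dim(x), bit_depth = as.integer(bits))
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
}

unclass_keep_dim <- function(x) {
  d <- dim(x)
  x <- as.numeric(x)
  dim(x) <- d
  x
}
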