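#' Multichannel image stacks
#'
#' An `ImageStack` bundles one or more fluorescence channels of identical
#' geometry with the physical pixel size and the image axis that carries the
#' applied uniaxial strain. Each channel is a numeric `[y, x, z]` array (a
#' 2-D raster becomes a single-plane stack). Channel labels name the stain
#' or probe (e.g. `actin`, `pxn`, `vcl`, `lc3b`, `dapi`, `tomm20`,
#' `mitotracker`, `jc1_red`, `jc1_green`, `gfp`).
#'
#' @param channels named list of numeric matrices or `[y, x, z]` arrays, all
#'   with identical dimensions.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param stretch_axis image axis of the 0 deg strain direction, `"x"` or
#'   `"y"`.
#' @param dtype_max maximum representable value of the source integer type
#'   (e.g. 65535 for 16-bit), or `NULL` for native floating point. Retained
#'   so [save_image()] can round-trip integer data bit-exactly.
#' @return an object of class `ImageStack`.
#' @seealso [load_image()], [max_project()]
#' @export
image_stack <- function(channels, pixel_size_um, stretch_axis = "x",
                        dtype_max = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("'channels' must be a named list of rasters")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop("each channel must be a matrix or [y, x, z] array")
    storage.mode(ch) <- "double"
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    stop("all channels must share identical (y, x, z) dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  if (!stretch_axis %in% c("x", "y"))
    stop("'stretch_axis' must be \"x\" or \"y\"")
  bad <- vapply(channels, function(ch) any(!is.finite(ch)) || any(ch < 0),
                logical(1))
  if (any(bad))
    stop("intensities must be finite and non-negative (channel: ",
         paste(names(channels)[bad], collapse = ", "), ")")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 stretch_axis = stretch_axis, dtype_max = dtype_max),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("ImageStack: %d x %d px, %d plane(s), %d channel(s) [%s]\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size %.4g um, stretch axis %s\n",
              x$pixel_size_um, x$stretch_axis))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$channels[[1]])

get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!channel %in% names(stack$channels))
    stop("unknown channel '", channel, "'; available: ",
         paste(names(stack$channels), collapse = ", "))
  stack$channels[[channel]]
}

#' Read a microscopy TIFF into an ImageStack
#'
#' Accepts single- or multi-page TIFFs, with pages interpreted either as one
#' page per channel (`z_layout = "page_per_channel"`) or as one page per
#' z-plane of a single channel (`z_layout = "page_per_z"`). Pages that carry
#' several samples per pixel (RGB-style) are split into channels. Integer
#' intensities are converted to floating point; the original bit depth is
#' kept on the stack for bit-exact round-trip writing.
#'
#' @param path path to a readable TIFF file.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param channel_map character vector naming the channels in file order;
#'   its length must match the number of channels found in the file.
#' @param stretch_axis strain axis, `"x"` (default) or `"y"`.
#' @param z_layout page interpretation, `"page_per_channel"` (default) or
#'   `"page_per_z"`.
#' @return an [image_stack()].
#' @export
load_image <- function(path, pixel_size_um, channel_map,
                       stretch_axis = "x",
                       z_layout = c("page_per_channel", "page_per_z")) {
  z_layout <- match.arg(z_layout)
  if (!file.exists(path)) stop("cannot read TIFF file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1]], "bits.per.sample") %||% 16L
  dtype_max <- 2^bps - 1
  # split multi-sample pages into per-channel matrices
  split_page <- function(pg) {
    if (length(dim(pg)) == 3L)
      lapply(seq_len(dim(pg)[3]), function(s) pg[, , s]) else list(pg)
  }
  mats <- unlist(lapply(pages, split_page), recursive = FALSE)
  if (z_layout == "page_per_channel") {
    if (length(channel_map) != length(mats))
      stop("channel_map has length ", length(channel_map),
           " but the file contains ", length(mats), " channel page(s)")
    channels <- lapply(mats, function(m) array(m, dim = c(dim(m), 1L)))
    names(channels) <- channel_map
  } else {
    if (length(channel_map) != 1L)
      stop("z_layout 'page_per_z' requires a single channel label")
    arr <- array(0, dim = c(dim(mats[[1]]), length(mats)))
    for (k in seq_along(mats)) arr[, , k] <- mats[[k]]
    channels <- stats::setNames(list(arr), channel_map)
  }
  image_stack(channels, pixel_size_um, stretch_axis, dtype_max = dtype_max)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Channels are written as one page per channel (the first z-plane of each),
#' or, for a single-channel stack, one page per z-plane. Integer-typed
#' stacks (those loaded from integer TIFFs or built with `dtype_max`) are
#' written back at the same bit depth, bit-exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_image <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  dmax <- stack$dtype_max %||% max(1, max(unlist(lapply(stack$channels, max))))
  bps <- if (!is.null(stack$dtype_max) && stack$dtype_max <= 255) 8L else 16L
  nz <- dim(stack)[3]
  pages <- if (length(stack$channels) == 1L && nz > 1L)
    lapply(seq_len(nz), function(k) stack$channels[[1]][, , k])
  else lapply(stack$channels, function(ch) ch[, , 1])
  pages <- lapply(pages, function(m) pmin(pmax(m / dmax, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bps)
  invisible(path)
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z-dimension of a channel by taking the per-pixel maximum
#' across planes, the standard projection used before the intensity-based
#' readouts (MitoTracker, JC-1).
#'
#' @param stack an [image_stack()].
#' @param channel channel label to project.
#' @return a 2-D numeric matrix `[y, x]`.
#' @export
max_project <- function(stack, channel) {
  ch <- get_channel(stack, channel)
  apply(ch, c(1, 2), max)
}
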