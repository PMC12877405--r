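#' Segment mitochondria in one Tomm20 plane
#'
#' The per-plane chain: disk median filter (radius 2 px at 0.183 um/px) ->
#' white top-hat (disk radius 5) -> CLAHE (2% clip, 1/8 x 1/8 tiles) ->
#' Sauvola local threshold (radius 15 px, k = 0.2) -> binary opening with a
#' two-pixel disk (separating touching objects while keeping the 2-4 px
#' wide tubules themselves) -> skeletonization (Zhang-Suen thinning). Both
#' the binary mask and its skeleton are returned: object number is read
#' off the skeleton, object area off the pre-skeleton mask.
#'
#' @param plane 2-D raster of one z-plane.
#' @param median_radius,tophat_radius,clip,sauvola_radius,sauvola_k
#'   stage parameters as above.
#' @param open_px diameter of the separation-opening disk in pixels; the
#'   brush spans `open_px + 1` pixels, so the default 2 keeps any structure
#'   at least 3 px wide.
#' @return list with logical matrices `mask` and `skeleton` (the skeleton
#'   is a subset of the mask); a constant plane yields empty masks.
#' @export
tomm20_segment_plane <- function(plane, median_radius = 2, tophat_radius = 5,
                                 clip = 0.02, sauvola_radius = 15,
                                 sauvola_k = 0.2, open_px = 2) {
  stopifnot(is.matrix(plane))
  blank <- matrix(FALSE, nrow(plane), ncol(plane))
  if (diff(range(plane)) <= 0) return(list(mask = blank, skeleton = blank))
  x <- as.matrix(EBImage::medianFilter(norm01(plane),
                                       size = as.integer(median_radius)))
  x <- as.matrix(EBImage::whiteTopHat(x, disc_brush(tophat_radius)))
  if (diff(range(x)) <= 0) return(list(mask = blank, skeleton = blank))
  x <- clahe_clip(x, clip = clip)
  bin <- sauvola_mask(x, radius = sauvola_radius, k = sauvola_k)
  brush <- EBImage::makeBrush(as.integer(open_px) + 1L +
                                (as.integer(open_px) %% 2L), "disc")
  bin <- as.matrix(EBImage::opening(matrix(as.numeric(bin), nrow(bin),
                                           ncol(bin)), brush)) > 0.5
  skel <- thin_cpp(matrix(as.integer(bin), nrow(bin), ncol(bin))) > 0
  list(mask = bin, skeleton = skel)
}

#' Geometric length of a skeleton in pixels
#'
#' Sums the links of the 8-connected skeleton graph: orthogonal neighbour
#' links count 1, diagonal links `sqrt(2)` (each link once). For a thin
#' curvilinear skeleton this estimates the traced path length.
#'
#' @param skeleton logical matrix, e.g. from [tomm20_segment_plane()].
#' @return total length in pixel units.
#' @export
skeleton_length <- function(skeleton) {
  s <- skeleton != 0
  nr <- nrow(s); nc <- ncol(s)
  n_orth <- sum(s[-nr, ] & s[-1, ]) + sum(s[, -nc] & s[, -1])
  # diagonal links that merely chord an L of two orthogonal links would
  # double-count the path; keep only diagonals with both corners empty
  d1 <- s[-nr, -nc] & s[-1, -1] & !(s[-1, -nc] | s[-nr, -1])
  d2 <- s[-1, -nc] & s[-nr, -1] & !(s[-nr, -nc] | s[-1, -1])
  n_orth + sqrt(2) * (sum(d1) + sum(d2))
}

#' Mitochondrial morphology statistics across a z-stack
#'
#' Runs [tomm20_segment_plane()] on every plane, counts skeleton connected
#' components and the mean binary-object area per plane, then averages over
#' planes: object count is divided by the cell number, mean object area is
#' normalized to the total cell-mask area of the image.
#'
#' @param stack an [image_stack()] with a `tomm20` channel.
#' @param cell_masks logical matrix (applied to every plane) or list of
#'   per-plane logical matrices delimiting the cell-covered area (e.g. from
#'   the actin channel); `NULL` analyzes the full frame.
#' @param n_cells number of cells in the image (>= 1).
#' @return a `MitoMorphology` list: `per_plane` (data frame with
#'   `n_objects`, `mean_object_area_px`), `objects_per_cell`,
#'   `mean_area_normalized` (mean object area / total cell area).
#' @export
tomm20_stats <- function(stack, cell_masks = NULL, n_cells) {
  stopifnot(inherits(stack, "ImageStack"), n_cells >= 1)
  ch <- get_channel(stack, "tomm20")
  nz <- dim(ch)[3]
  get_mask <- function(k) {
    if (is.null(cell_masks)) matrix(TRUE, dim(ch)[1], dim(ch)[2])
    else if (is.list(cell_masks)) cell_masks[[k]]
    else cell_masks
  }
  n_obj <- numeric(nz); mean_area <- numeric(nz); cell_area <- numeric(nz)
  for (k in seq_len(nz)) {
    msk <- get_mask(k)
    stopifnot(identical(dim(msk), dim(ch)[1:2]))
    seg <- tomm20_segment_plane(ch[, , k])
    bin <- seg$mask & msk
    skel <- seg$skeleton & msk
    n_obj[k] <- n_regions(label_regions(skel))
    areas <- label_regions(bin)$regions$area_px
    mean_area[k] <- if (length(areas)) mean(areas) else 0
    cell_area[k] <- sum(msk)
  }
  structure(list(per_plane = data.frame(plane = seq_len(nz),
                                        n_objects = n_obj,
                                        mean_object_area_px = mean_area),
                 objects_per_cell = mean(n_obj) / n_cells,
                 mean_area_normalized = mean(mean_area) / mean(cell_area)),
            class = "MitoMorphology")
}

#' @export
print.MitoMorphology <- function(x, ...) {
  cat(sprintf(
    "MitoMorphology: %.2f objects/cell, normalized mean area %.3g\n",
    x$objects_per_cell, x$mean_area_normalized))
  invisible(x)
}

#' Background-corrected MitoTracker intensity
#'
#' Maximum-intensity projection of the green signal; background correction
#' by subtracting the morphological opening with a 251 x 251 square
#' structuring element (at 0.18 um/px); subtraction of the minimum gray
#' value; Otsu threshold divided by three (to include darker pixels in the
#' cell mask); opening/closing post-processing of the mask and removal of
#' objects with areas below `min_object_px` (a 1000-px object is
#' retained). The readout is the mean gray value inside the mask minus the
#' mean outside it, computed on the original projection.
#'
#' @param stack an [image_stack()] with a `mitotracker` channel.
#' @param control_mean mean corrected intensity of the unstretched
#'   condition; when given, `normalized = corrected / control_mean`.
#' @param open_size edge of the square background structuring element.
#' @param min_object_px strict "below" removal bound (default 1000).
#' @param post_radius disk radius for the opening/closing mask cleanup.
#' @return an `IntensityResult` list: `mean_cell_intensity`,
#'   `mean_background_intensity`, `corrected_intensity`, `normalized`,
#'   `mask`.
#' @export
mitotracker_intensity <- function(stack, control_mean = NULL,
                                  open_size = 251, min_object_px = 1000,
                                  post_radius = 3) {
  mip <- max_project(stack, "mitotracker")
  op <- box_open(mip, open_size)
  corr <- mip - op
  corr <- corr - min(corr)
  thr <- otsu_threshold(corr) / 3
  mask <- corr > thr
  mm <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  mm <- EBImage::closing(EBImage::opening(mm, disc_brush(post_radius)),
                         disc_brush(post_radius))
  lr <- label_regions(as.matrix(mm) > 0.5)
  keep <- lr$regions$label[lr$regions$area_px >= min_object_px]
  if (length(keep) == 0)
    stop(sprintf(paste0("empty cell mask after filtering (threshold %.4g; ",
                        "largest object %s px)"),
                 thr,
                 if (nrow(lr$regions)) max(lr$regions$area_px) else 0))
  mask <- keep_regions(lr, keep)$labels > 0L
  inside <- mean(mip[mask]); outside <- mean(mip[!mask])
  structure(list(mean_cell_intensity = inside,
                 mean_background_intensity = outside,
                 corrected_intensity = inside - outside,
                 normalized = if (is.null(control_mean)) NA_real_
                              else (inside - outside) / control_mean,
                 red_green_ratio = NA_real_,
                 mask = mask),
            class = "IntensityResult")
}

# Grayscale opening with a w x w square structuring element.
box_open <- function(img, w) {
  as.matrix(EBImage::opening(img, EBImage::makeBrush(as.integer(w), "box")))
}

#' JC-1 red/green intensity ratio
#'
#' Maximum-intensity projections of both channels are summed; the sum is
#' Gaussian-smoothed (sigma 3 at 0.721 um/px), globally z-score normalized,
#' and a grayscale opening (disk radius 15) is subtracted to enhance local
#' features; the result is segmented at a fixed threshold of 0.6. The
#' readout is the ratio of red to green mean intensity within that
#' bright-region mask.
#'
#' @param stack an [image_stack()] with `jc1_red` and `jc1_green` channels
#'   (alternatively pass two single-channel stacks as `stack` and `green`).
#' @param green optional second [image_stack()] holding the green channel
#'   when `stack` holds only the red one.
#' @param smooth_sigma Gaussian sigma in pixels.
#' @param open_radius disk radius of the subtracted opening.
#' @param threshold fixed threshold on the enhanced image (default 0.6).
#' @return an `IntensityResult` with `red_green_ratio` and the `mask`.
#' @export
jc1_ratio <- function(stack, green = NULL, smooth_sigma = 3,
                      open_radius = 15, threshold = 0.6) {
  if (is.null(green)) {
    red_mip <- max_project(stack, "jc1_red")
    green_mip <- max_project(stack, "jc1_green")
  } else {
    red_mip <- max_project(stack, names(stack$channels)[1])
    green_mip <- max_project(green, names(green$channels)[1])
  }
  comp <- red_mip + green_mip
  if (sd(comp) == 0) stop("flat composite image; cannot z-score normalize")
  sm <- gauss_smooth(comp, smooth_sigma)
  s <- sd(sm)
  if (s == 0) stop("flat composite image; cannot z-score normalize")
  z <- (sm - mean(sm)) / s
  op <- EBImage::opening(z - min(z), disc_brush(open_radius))
  enh <- (z - min(z)) - as.matrix(op)
  mask <- enh > threshold
  if (!any(mask)) stop("empty JC-1 mask at threshold ", threshold)
  gmean <- mean(green_mip[mask])
  if (gmean <= 0) stop("zero green mean inside the JC-1 mask")
  structure(list(mean_cell_intensity = mean(red_mip[mask]),
                 mean_background_intensity = NA_real_,
                 corrected_intensity = NA_real_,
                 normalized = NA_real_,
                 red_green_ratio = mean(red_mip[mask]) / gmean,
                 mask = mask),
            class = "IntensityResult")
}

#' @export
print.IntensityResult <- function(x, ...) {
  if (!is.na(x$red_green_ratio))
    cat(sprintf("IntensityResult: red/green ratio %.3f\n", x$red_green_ratio))
  else
    cat(sprintf(
      "IntensityResult: cell %.3f - background %.3f = corrected %.3f\n",
      x$mean_cell_intensity, x$mean_background_intensity,
      x$corrected_intensity))
  invisible(x)
}
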