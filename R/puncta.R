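#' Segment LC3B puncta by global thresholding and small-object rejection
#'
#' Connected components (8-connected) of pixels above the threshold;
#' components with pixel area below `min_area_px` are rejected and the
#' remainder relabeled consecutively. The area rule is strict in the
#' reject direction: a component of exactly `min_area_px` pixels is kept.
#'
#' @param image 2-D raster (single LC3B channel or plane).
#' @param threshold numeric intensity cutoff, or `"auto"` for Otsu's method
#'   on the whole image (a constant image then yields zero spots).
#' @param min_area_px minimum retained component area in pixels
#'   (default 70, the published rejection rule at 0.071 um/px).
#' @param pixel_size_um physical pixel size for the area measurements.
#' @return a [label_regions()] object; the threshold actually applied is
#'   attached as attribute `"threshold"` for auditability.
#' @export
segment_puncta <- function(image, threshold = "auto", min_area_px = 70,
                           pixel_size_um = 0.071) {
  stopifnot(is.matrix(image), min_area_px >= 1)
  thr <- if (identical(threshold, "auto")) otsu_threshold(image)
         else as.numeric(threshold)
  lr <- label_regions(image > thr, pixel_size_um)
  keep <- lr$regions$label[lr$regions$area_px >= min_area_px]
  out <- keep_regions(lr, keep)
  attr(out, "threshold") <- thr
  out
}

# Otsu threshold on the image's own intensity range (constant image -> +Inf
# so nothing is segmented).
otsu_threshold <- function(image) {
  r <- range(image)
  if (r[2] <= r[1]) return(Inf)
  t01 <- EBImage::otsu(norm01(image), range = c(0, 1))
  r[1] + t01 * (r[2] - r[1])
}

#' Split touching puncta by distance-transform watershed
#'
#' Each connected component is subdivided by a watershed on its Euclidean
#' distance transform: local maxima of the distance map act as basin
#' markers, so a dumbbell of two merged spots splits in two while a
#' component with a single maximum is returned unchanged. Maxima closer
#' than `min_peak_sep` (or lower than `tolerance` relative to their
#' neighbourhood) are merged into one marker, which also assigns one marker
#' per connected plateau.
#'
#' @param regions a `LabeledRegions` object (from [segment_puncta()]).
#' @param tolerance minimum distance-map height difference between a
#'   maximum and the saddle towards its neighbour for it to seed its own
#'   basin. Touching diffraction-limited spots leave saddles well under
#'   one pixel deep, hence the sub-pixel default.
#' @param min_peak_sep minimum separation of distance-map maxima in pixels.
#' @return a `LabeledRegions` object covering exactly the same pixels with
#'   at least as many regions.
#' @export
split_clusters <- function(regions, tolerance = 0.5, min_peak_sep = 5) {
  stopifnot(inherits(regions, "LabeledRegions"))
  mask <- regions$labels > 0L
  if (!any(mask)) return(regions)
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  # a neighbourhood radius of floor(sep / 2) makes maxima closer than
  # `min_peak_sep` share one marker (and one marker per plateau)
  ws <- EBImage::watershed(dm, tolerance = tolerance,
                           ext = max(1L, floor(min_peak_sep / 2)))
  labeled_regions(matrix(as.integer(ws), nrow(mask), ncol(mask)),
                  regions$pixel_size_um)
}

#' Count nuclei in a DAPI channel (or pass a manual count through)
#'
#' The reference procedure counted nuclei manually; `manual_count` is
#' therefore honoured verbatim when given. Otherwise nuclei are counted
#' automatically: Gaussian smoothing, Otsu threshold, distance-transform
#' watershed to split touching nuclei, and a minimum-area filter.
#'
#' @param dapi 2-D DAPI raster (ignored when `manual_count` is given).
#' @param manual_count manually counted nuclei, if available.
#' @param smooth_sigma Gaussian scale in pixels.
#' @param min_area_px minimum nucleus area in pixels.
#' @return integer nucleus count (>= 1; zero nuclei is an error because
#'   per-cell normalization would be undefined).
#' @export
count_nuclei <- function(dapi = NULL, manual_count = NULL, smooth_sigma = 2,
                         min_area_px = 100) {
  if (!is.null(manual_count)) {
    n <- as.integer(manual_count)
    if (n < 1) stop("nucleus count must be >= 1")
    return(n)
  }
  stopifnot(is.matrix(dapi))
  sm <- gauss_smooth(dapi, smooth_sigma)
  thr <- otsu_threshold(sm)
  lr <- label_regions(sm > thr, 1)
  lr <- split_clusters(lr)
  n <- sum(lr$regions$area_px >= min_area_px)
  if (n < 1) stop("no nuclei detected; supply manual_count")
  n
}

#' LC3B spots per cell, optionally normalized to an unstretched control
#'
#' @param regions segmented (and cluster-split) puncta, a `LabeledRegions`.
#' @param n_nuclei nucleus count of the same image (>= 1).
#' @param control_mean mean spots-per-cell of the unstretched untreated
#'   control condition; when supplied the result also carries
#'   `normalized_to_control = spots_per_cell / control_mean`.
#' @return a `SpotCountResult` list: `n_spots`, `n_nuclei`,
#'   `spots_per_cell`, `normalized_to_control` (or `NA`).
#' @export
puncta_per_cell <- function(regions, n_nuclei, control_mean = NULL) {
  stopifnot(inherits(regions, "LabeledRegions"))
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  spc <- n_regions(regions) / n_nuclei
  structure(list(n_spots = n_regions(regions), n_nuclei = n_nuclei,
                 spots_per_cell = spc,
                 normalized_to_control =
                   if (is.null(control_mean)) NA_real_
                   else spc / control_mean),
            class = "SpotCountResult")
}

#' @export
print.SpotCountResult <- function(x, ...) {
  cat(sprintf("SpotCountResult: %d spot(s) / %d nuclei = %.3f per cell",
              x$n_spots, x$n_nuclei, x$spots_per_cell))
  if (!is.na(x$normalized_to_control))
    cat(sprintf(" (%.3f x control)", x$normalized_to_control))
  cat("\n")
  invisible(x)
}
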