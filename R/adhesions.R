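#' Background-peak threshold from a smoothed gray-value histogram
#'
#' Builds a 256-bin histogram of the image's gray values, smooths it with a
#' Savitzky-Golay filter (21-bin window, cubic polynomial), locates the
#' first local maximum (the background peak), measures that peak's full
#' width at half maximum by linear interpolation of the half-max crossings,
#' and returns the intensity 0.2 FWHM to the right of the peak. When the
#' right flank never falls to half maximum, twice the measurable left
#' half-width stands in for the FWHM and a warning of class
#' `stretchquant_fwhm_fallback` is signalled.
#'
#' @param image 2-D raster with at least two distinct gray levels.
#' @param bins histogram bin count (default 256, bit-depth independent).
#' @param sg_window,sg_order Savitzky-Golay window (bins) and polynomial
#'   order.
#' @return the threshold intensity (scalar).
#' @export
background_peak_threshold <- function(image, bins = 256, sg_window = 21,
                                      sg_order = 3) {
  r <- range(image)
  if (!is.finite(r[1]) || r[2] <= r[1])
    stop("degenerate histogram: image needs >= 2 distinct gray levels")
  br <- seq(r[1], r[2], length.out = bins + 1)
  mids <- (br[-1] + br[-(bins + 1)]) / 2
  h <- tabulate(pmin(findInterval(as.numeric(image), br,
                                  rightmost.closed = TRUE), bins), bins)
  hs <- signal::sgolayfilt(h, p = sg_order, n = sg_window)
  hs <- pmax(hs, 0)
  # first local maximum with non-negligible mass (smoothing ripple in empty
  # leading bins must not count); plateaus count once, at their left edge
  floor_h <- 0.05 * max(hs)
  peak <- NA_integer_
  for (i in seq_len(bins)) {
    left <- if (i == 1) -Inf else hs[i - 1]
    right <- if (i == bins) -Inf else hs[i + 1]
    if (hs[i] >= floor_h && hs[i] > left && hs[i] >= right) { peak <- i; break }
  }
  if (is.na(peak) || hs[peak] <= 0)
    stop("no local maximum found in the smoothed histogram")
  half <- hs[peak] / 2
  cross <- function(side) {
    idx <- if (side == "right") seq.int(peak, bins) else seq.int(peak, 1)
    below <- which(hs[idx] < half)
    if (length(below) == 0) return(NA_real_)
    j <- idx[below[1]]; jprev <- if (side == "right") j - 1 else j + 1
    frac <- (hs[jprev] - half) / (hs[jprev] - hs[j])
    mids[jprev] + frac * (mids[j] - mids[jprev])
  }
  xr <- cross("right"); xl <- cross("left")
  bw <- mids[2] - mids[1]
  peak_x <- mids[peak]
  fwhm <- if (!is.na(xr) && !is.na(xl)) {
    xr - xl
  } else if (!is.na(xr)) {
    2 * (xr - peak_x)
  } else if (!is.na(xl)) {
    warning(structure(class = c("stretchquant_fwhm_fallback", "warning",
                                "condition"),
                      list(message = "right flank never reached half maximum; using twice the left half-width",
                           call = sys.call())))
    2 * (peak_x - xl)
  } else {
    stop("half maximum never reached on either flank")
  }
  peak_x + 0.2 * fwhm
}

#' Cell-covered area from the paxillin channel
#'
#' CLAHE (2% clip) -> disk median filter (radius 5 px at 0.183 um/px) ->
#' Gaussian smoothing (sigma 5 px) -> binarization at the
#' [background_peak_threshold()] of the smoothed image. Only pixels inside
#' this mask take part in downstream spot detection.
#'
#' @param pxn_image 2-D paxillin raster.
#' @param clip CLAHE clip limit (fraction of tile pixels).
#' @param median_radius disk radius of the median filter in pixels.
#' @param gauss_sigma Gaussian sigma in pixels.
#' @return logical matrix, `TRUE` on cell-covered pixels.
#' @export
cell_mask <- function(pxn_image, clip = 0.02, median_radius = 5,
                      gauss_sigma = 5) {
  stopifnot(is.matrix(pxn_image))
  if (diff(range(pxn_image)) <= 0) {
    if (max(pxn_image) == 0)
      stop("degenerate histogram: blank image has no cell/background contrast")
    # constant positive signal: one population, everything is cell
    warning("uniformly bright image; treating the full frame as cell-covered")
    return(matrix(TRUE, nrow(pxn_image), ncol(pxn_image)))
  }
  x <- clahe_clip(pxn_image, clip = clip)
  x <- as.matrix(EBImage::medianFilter(x, size = as.integer(median_radius)))
  x <- gauss_smooth(x, gauss_sigma)
  thr <- tryCatch(background_peak_threshold(x), error = function(e) {
    # a single intensity population (uniformly cell-covered frame) has no
    # separable background peak: everything is cell
    warning("no separable background population; treating the full frame as cell-covered")
    -Inf
  })
  x > thr
}

#' Detect bright spots in one channel by local z-scoring
#'
#' Gaussian smoothing (sigma 3) -> CLAHE (2% clip) -> per-pixel z-score
#' `(I - local mean) / local SD` over a centred `window_px` x `window_px`
#' square (mirror-padded at borders; locally constant windows give z = 0)
#' -> binarize at `z > z_threshold` inside the cell mask -> 8-connected
#' components -> retain components whose area strictly exceeds
#' `min_area_px`.
#'
#' @param image 2-D raster of one adhesion channel (pxn or vcl).
#' @param mask logical cell mask congruent with `image` (default: all).
#' @param window_px square window edge for the local statistics (odd).
#' @param z_threshold z-score cutoff (default 1).
#' @param min_area_px strict lower area bound: a 100-px spot is rejected,
#'   a 101-px spot retained (default 100).
#' @param smooth_sigma,clip pre-processing parameters.
#' @param pixel_size_um physical pixel size for region measurements.
#' @return a `LabeledRegions` object.
#' @export
channel_spots <- function(image, mask = NULL, window_px = 35, z_threshold = 1,
                          min_area_px = 100, smooth_sigma = 3, clip = 0.02,
                          pixel_size_um = 0.183) {
  stopifnot(is.matrix(image), window_px %% 2 == 1)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(mask), dim(image)))
  x <- gauss_smooth(image, smooth_sigma)
  if (diff(range(x)) > 0) x <- clahe_clip(x, clip = clip)
  ms <- box_mean_sd(x, window_px)
  z <- matrix(0, nrow(x), ncol(x))
  ok <- ms$sd > 0
  z[ok] <- (x[ok] - ms$mean[ok]) / ms$sd[ok]
  lr <- label_regions(z > z_threshold & mask, pixel_size_um)
  keep <- lr$regions$label[lr$regions$area_px > min_area_px]
  keep_regions(lr, keep)
}

#' Mutual-overlap filter between two channels' spots
#'
#' A spot in channel A is retained iff its pixel intersection with at least
#' one single spot in channel B reaches `min_overlap_px` (and vice versa);
#' overlap is counted per partner spot, never pooled over partners. The
#' published rule is inclusive: "at least five pixels".
#'
#' @param spots_a,spots_b `LabeledRegions` on congruent rasters.
#' @param min_overlap_px inclusive overlap bound (default 5).
#' @return list with retained `a` and `b` (`LabeledRegions`, relabeled) and
#'   `pairs`, a data frame of the surviving (a, b) spot pairs with their
#'   overlap pixel counts (labels refer to the input regions).
#' @export
mutual_overlap_filter <- function(spots_a, spots_b, min_overlap_px = 5) {
  stopifnot(inherits(spots_a, "LabeledRegions"),
            inherits(spots_b, "LabeledRegions"),
            identical(dim(spots_a$labels), dim(spots_b$labels)))
  both <- spots_a$labels > 0L & spots_b$labels > 0L
  if (!any(both)) {
    empty_pairs <- data.frame(a = integer(), b = integer(),
                              overlap_px = integer())
    return(list(a = keep_regions(spots_a, integer(0)),
                b = keep_regions(spots_b, integer(0)), pairs = empty_pairs))
  }
  la <- spots_a$labels[both]; lb <- spots_b$labels[both]
  cnt <- as.data.frame(table(a = la, b = lb), stringsAsFactors = FALSE)
  cnt <- cnt[cnt$Freq > 0, ]
  pairs <- data.frame(a = as.integer(cnt$a), b = as.integer(cnt$b),
                      overlap_px = cnt$Freq)
  ok <- pairs[pairs$overlap_px >= min_overlap_px, , drop = FALSE]
  list(a = keep_regions(spots_a, unique(ok$a)),
       b = keep_regions(spots_b, unique(ok$b)),
       pairs = ok)
}

#' Assemble focal adhesions as the union of overlapping spots
#'
#' The union of the retained pxn and vcl foreground is decomposed into
#' 8-connected components; every component containing pixels from both
#' channels becomes one focal adhesion, measured by its per-channel pixel
#' areas, union area (pixels and um^2), centroid and fitted-ellipse
#' orientation folded to `[0, 90]` against the stretch axis. Components
#' built from more than one spot per channel are flagged as multi-partner.
#'
#' @param retained_a,retained_b retained spots from
#'   [mutual_overlap_filter()] (pxn and vcl respectively).
#' @param pixel_size_um physical pixel size (um/px).
#' @param stretch_axis strain axis for orientation folding.
#' @return an `AdhesionTable`: list with `adhesions` (data frame: `fa_id`,
#'   `pxn_area_px`, `vcl_area_px`, `union_area_px`, `union_area_um2`,
#'   `orientation_deg` folded, `centroid_x`, `centroid_y`,
#'   `multi_partner`), the FA `labels` raster, `pixel_size_um` and
#'   `stretch_axis`.
#' @export
build_adhesions <- function(retained_a, retained_b, pixel_size_um = 0.183,
                            stretch_axis = "x") {
  stopifnot(inherits(retained_a, "LabeledRegions"),
            inherits(retained_b, "LabeledRegions"))
  amask <- retained_a$labels > 0L; bmask <- retained_b$labels > 0L
  uni <- label_regions(amask | bmask, pixel_size_um)
  lab <- uni$labels
  rows <- NULL
  keep_ids <- integer(0)
  for (id in uni$regions$label) {
    comp <- lab == id
    apx <- sum(comp & amask); bpx <- sum(comp & bmask)
    if (apx == 0 || bpx == 0) next  # an FA requires both proteins
    keep_ids <- c(keep_ids, id)
    idx <- which(comp)
    y <- (idx - 1L) %% nrow(lab) + 1L
    x <- (idx - 1L) %/% nrow(lab) + 1L
    ori <- fold_to_stretch(ellipse_orientation(x, y), stretch_axis)
    n_a <- length(unique(retained_a$labels[comp & amask]))
    n_b <- length(unique(retained_b$labels[comp & bmask]))
    rows <- rbind(rows, data.frame(
      fa_id = id, pxn_area_px = apx, vcl_area_px = bpx,
      union_area_px = length(idx),
      union_area_um2 = length(idx) * pixel_size_um^2,
      orientation_deg = ori, centroid_x = mean(x), centroid_y = mean(y),
      multi_partner = n_a > 1 || n_b > 1))
  }
  if (is.null(rows))
    rows <- data.frame(fa_id = integer(), pxn_area_px = integer(),
                       vcl_area_px = integer(), union_area_px = integer(),
                       union_area_um2 = numeric(), orientation_deg = numeric(),
                       centroid_x = numeric(), centroid_y = numeric(),
                       multi_partner = logical())
  lab[!(lab %in% keep_ids)] <- 0L
  rows$fa_id <- seq_len(nrow(rows))
  stopifnot(all(rows$union_area_px >=
                pmax(rows$pxn_area_px, rows$vcl_area_px)))
  structure(list(adhesions = rows, labels = lab,
                 pixel_size_um = pixel_size_um, stretch_axis = stretch_axis),
            class = "AdhesionTable")
}

#' @export
print.AdhesionTable <- function(x, ...) {
  cat(sprintf("AdhesionTable: %d focal adhesion(s), %.3g um/px\n",
              nrow(x$adhesions), x$pixel_size_um))
  if (nrow(x$adhesions) > 0) print(utils::head(x$adhesions, 10))
  invisible(x)
}

#' Per-image adhesion summaries and the FA orientation distribution
#'
#' Computes the per-image readouts reported for the adhesion assay: mean
#' pxn and vcl spot areas (um^2, per FA), the fraction of total FA area
#' covered by each channel, mean FA (union) area, FAs per cell, and the
#' angular distribution of FA orientations (one folded angle per FA).
#'
#' @param table an `AdhesionTable` from [build_adhesions()].
#' @param n_cells cell count of the image (e.g. from [count_nuclei()]).
#' @return list with `summary` (named list of the six per-image values)
#'   and `distribution` (an `AngularDistribution`, `NULL` when no FAs).
#' @export
adhesion_metrics <- function(table, n_cells) {
  stopifnot(inherits(table, "AdhesionTable"), n_cells >= 1)
  ad <- table$adhesions
  ps2 <- table$pixel_size_um^2
  if (nrow(ad) == 0) {
    return(list(summary = list(mean_pxn_spot_area_um2 = NA_real_,
                               mean_vcl_spot_area_um2 = NA_real_,
                               pxn_coverage_fraction = NA_real_,
                               vcl_coverage_fraction = NA_real_,
                               mean_fa_area_um2 = NA_real_,
                               fa_per_cell = 0),
                distribution = NULL))
  }
  pxn_cov <- sum(ad$pxn_area_px) / sum(ad$union_area_px)
  vcl_cov <- sum(ad$vcl_area_px) / sum(ad$union_area_px)
  stopifnot(pxn_cov > 0, pxn_cov <= 1, vcl_cov > 0, vcl_cov <= 1)
  list(summary = list(
         mean_pxn_spot_area_um2 = mean(ad$pxn_area_px) * ps2,
         mean_vcl_spot_area_um2 = mean(ad$vcl_area_px) * ps2,
         pxn_coverage_fraction = pxn_cov,
         vcl_coverage_fraction = vcl_cov,
         mean_fa_area_um2 = mean(ad$union_area_px) * ps2,
         fa_per_cell = nrow(ad) / n_cells),
       distribution = cumulative_distribution(ad$orientation_deg))
}

#' Run the full two-channel focal-adhesion pipeline on one image
#'
#' Cell mask from the paxillin channel, spot detection in both channels,
#' mutual-overlap filtering, FA assembly and per-image metrics.
#'
#' @param stack an [image_stack()] with `pxn` and `vcl` channels.
#' @param n_cells cell count for the per-cell summary.
#' @param min_overlap_px inclusive overlap bound (default 5 px).
#' @param min_area_px strict per-channel spot area bound (default 100 px).
#' @param use_cell_mask set `FALSE` to skip masking (e.g. synthetic scenes
#'   that fill the frame).
#' @return list with `table` (an `AdhesionTable`), `metrics` (from
#'   [adhesion_metrics()]) and the retained per-channel spots.
#' @export
analyze_adhesions <- function(stack, n_cells, min_overlap_px = 5,
                              min_area_px = 100, use_cell_mask = TRUE) {
  pxn <- get_channel(stack, "pxn")[, , 1]
  vcl <- get_channel(stack, "vcl")[, , 1]
  msk <- if (use_cell_mask) cell_mask(pxn) else NULL
  sa <- channel_spots(pxn, msk, min_area_px = min_area_px,
                      pixel_size_um = stack$pixel_size_um)
  sb <- channel_spots(vcl, msk, min_area_px = min_area_px,
                      pixel_size_um = stack$pixel_size_um)
  flt <- mutual_overlap_filter(sa, sb, min_overlap_px)
  tab <- build_adhesions(flt$a, flt$b, stack$pixel_size_um,
                         stack$stretch_axis)
  list(table = tab, metrics = adhesion_metrics(tab, n_cells),
       spots_pxn = flt$a, spots_vcl = flt$b)
}
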