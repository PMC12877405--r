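#' Per-pixel fiber orientation from gray-value gradients
#'
#' After light Gaussian pre-smoothing, Sobel gradients are computed and the
#' local fiber orientation is taken orthogonal to the intensity gradient
#' (a bright fiber's gradient points across the fiber). The squared
#' gradient magnitude serves as the per-pixel weight, so flat regions carry
#' no orientation signal. A constant image yields all-zero weights, which
#' is valid (no signal), not an error.
#'
#' @param image 2-D numeric raster, at least 3 x 3.
#' @param smooth_sigma Gaussian pre-smoothing scale in pixels (default 1).
#' @return an `OrientationField`: list with `angle` (degrees in
#'   `[0, 180)`, same size as `image`) and `weight` (squared gradient
#'   magnitude, >= 0).
#' @export
orientation_field <- function(image, smooth_sigma = 1) {
  stopifnot(is.matrix(image), nrow(image) >= 3, ncol(image) >= 3)
  sm <- gauss_smooth(image, smooth_sigma)
  g <- sobel_gradients(sm)
  w <- g$gx^2 + g$gy^2
  # fiber direction is orthogonal to the gradient: rotate by 90 deg
  ang <- (atan2(g$gy, g$gx) * 180 / pi + 90) %% 180
  ang[w == 0] <- 0
  structure(list(angle = ang, weight = w), class = "OrientationField")
}

#' Main orientation per grid square ("cell equivalent")
#'
#' Lays an `n_cols x n_rows` grid over the image (remainder pixels are
#' assigned to the last column/row), builds for every square a
#' weight-weighted histogram of pixel orientations in 1-degree bins over
#' `[0, 180)`, smooths it circularly (5-bin moving average) and returns the
#' histogram maximum as the square's main fiber orientation. Ties break
#' toward the smaller angle. Squares whose total gradient weight falls
#' below `min_weight_fraction` of the mean per-square weight are omitted
#' (they contain no cells/fibers).
#'
#' @param field an [orientation_field()] result.
#' @param grid `c(n_cols, n_rows)`; the 5 x 3 default treats each square as
#'   one cell equivalent of a confluent monolayer.
#' @param min_weight_fraction omission threshold relative to the mean
#'   per-square total weight (default 0.05).
#' @return numeric vector of main orientations in degrees, `[0, 180)`.
#' @export
grid_main_orientations <- function(field, grid = c(5, 3),
                                   min_weight_fraction = 0.05) {
  stopifnot(inherits(field, "OrientationField"), length(grid) == 2)
  nr <- nrow(field$angle); nc <- ncol(field$angle)
  n_cols <- grid[1]; n_rows <- grid[2]
  col_id <- pmin(ceiling(seq_len(nc) / floor(nc / n_cols)), n_cols)
  row_id <- pmin(ceiling(seq_len(nr) / floor(nr / n_rows)), n_rows)
  sq <- outer(row_id, col_id, function(r, c) (c - 1L) * n_rows + r)
  tot_w <- vapply(seq_len(n_cols * n_rows),
                  function(s) sum(field$weight[sq == s]), numeric(1))
  keep <- tot_w >= min_weight_fraction * mean(tot_w) & tot_w > 0
  out <- numeric(0)
  for (s in which(keep)) {
    i <- sq == s
    out <- c(out, histogram_mode(field$angle[i], field$weight[i]))
  }
  out
}

# Weighted 1-degree histogram over [0, 180) with circular 5-bin moving
# average; returns the bin-centre of the maximum (ties -> smaller angle).
histogram_mode <- function(angles, weights, bin_width = 1, smooth_bins = 5) {
  nb <- as.integer(180 / bin_width)
  bin <- pmin(floor(angles / bin_width), nb - 1) + 1L
  h <- vapply(seq_len(nb), function(b) sum(weights[bin == b]), numeric(1))
  k <- (smooth_bins - 1) / 2
  idx <- outer(seq_len(nb), -k:k, function(i, d) ((i + d - 1) %% nb) + 1)
  hs <- rowMeans(matrix(h[idx], nb, smooth_bins))
  (which.max(hs) - 0.5) * bin_width
}

#' Fold an orientation onto the stretch axis
#'
#' Returns the acute angle (degrees, `[0, 90]`) between an axial
#' orientation in `[0, 180)` and the stretch axis: 0 means parallel to
#' stretch, 90 perpendicular.
#'
#' @param angle orientation(s) in degrees (any real; reduced mod 180).
#' @param stretch_axis `"x"` or `"y"`.
#' @return folded angle(s) in `[0, 90]`.
#' @export
fold_to_stretch <- function(angle, stretch_axis = "x") {
  if (!stretch_axis %in% c("x", "y"))
    stop("'stretch_axis' must be \"x\" or \"y\"")
  a <- angle %% 180
  if (stretch_axis == "y") a <- (a + 90) %% 180
  pmin(a, 180 - a)
}

#' Empirical cumulative angular distribution over [0, 90]
#'
#' The standard presentation of reorientation data: folded angles from
#' parallel (0 deg) to perpendicular (90 deg) to strain, as an empirical
#' CDF, together with the mean folded angle (the per-image statistic used
#' for condition-level comparisons).
#'
#' @param angles folded angles in degrees, each in `[0, 90]`; non-empty.
#' @return an `AngularDistribution`: list with `angles` (sorted), `n_units`,
#'   `mean_angle`, and `cumulative`, a function mapping degrees to
#'   cumulative frequency (`cumulative(90) == 1`).
#' @export
cumulative_distribution <- function(angles) {
  if (length(angles) == 0) stop("empty angle list")
  if (any(angles < 0 | angles > 90)) stop("angles must lie in [0, 90]")
  structure(list(angles = sort(angles), n_units = length(angles),
                 mean_angle = mean(angles), cumulative = ecdf(angles)),
            class = "AngularDistribution")
}

#' @export
print.AngularDistribution <- function(x, ...) {
  cat(sprintf("AngularDistribution: n = %d, mean = %.2f deg, median = %.2f deg\n",
              x$n_units, x$mean_angle, median(x$angles)))
  invisible(x)
}

#' Analyze actin fiber orientation of one image
#'
#' Convenience wrapper running the full per-image chain: orientation field
#' from gradients, per-square main orientations on the grid, folding to the
#' stretch axis, and the cumulative distribution with the per-image mean.
#'
#' @param stack an [image_stack()] with an `actin` channel (first z-plane
#'   is analyzed), or a plain 2-D raster.
#' @param grid `c(n_cols, n_rows)` cell-equivalent grid.
#' @param stretch_axis strain axis; taken from the stack if omitted.
#' @param min_weight_fraction see [grid_main_orientations()].
#' @return list with `square_angles` (folded per-square orientations),
#'   `distribution` (an `AngularDistribution`) and `mean_angle`.
#' @export
analyze_orientation <- function(stack, grid = c(5, 3), stretch_axis = NULL,
                                min_weight_fraction = 0.05) {
  if (inherits(stack, "ImageStack")) {
    img <- get_channel(stack, "actin")[, , 1]
    stretch_axis <- stretch_axis %||% stack$stretch_axis
  } else {
    img <- stack
    stretch_axis <- stretch_axis %||% "x"
  }
  f <- orientation_field(img)
  main <- grid_main_orientations(f, grid, min_weight_fraction)
  folded <- fold_to_stretch(main, stretch_axis)
  if (length(folded) == 0)
    return(list(square_angles = folded, distribution = NULL,
                mean_angle = NA_real_))
  d <- cumulative_distribution(folded)
  list(square_angles = folded, distribution = d, mean_angle = d$mean_angle)
}
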