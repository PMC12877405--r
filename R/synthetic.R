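#' Synthetic fluorescence scenes with ground truth
#'
#' Every assay in the package is exercised on generated scenes whose object
#' geometry is known exactly. A `SceneTruth` records, for each rendered
#' foreground object, its kind (`fiber`, `punctum`, `nucleus`,
#' `adhesion_pair`, `mito_branch`, `jc1_region`), geometry and intensity
#' parameters, together with the generative distribution parameters, the
#' seed and the pixel size. Regenerating with the same seed and parameters
#' yields an identical raster.
#'
#' @name SceneTruth
#' @keywords internal
NULL

scene_truth <- function(objects, generative_params, seed, pixel_size_um,
                        masks = NULL) {
  structure(list(objects = objects, generative_params = generative_params,
                 seed = seed, pixel_size_um = pixel_size_um, masks = masks),
            class = "SceneTruth")
}

#' @export
print.SceneTruth <- function(x, ...) {
  cat(sprintf("SceneTruth: %d object(s), seed %s\n", nrow(x$objects),
              format(x$seed)))
  if (nrow(x$objects) > 0) print(table(x$objects$kind))
  invisible(x)
}

# ---- low-level renderers ---------------------------------------------------

# Paint an anti-aliased capsule (thick line segment) into img via pixelwise
# maximum; returns the updated matrix.
render_capsule <- function(img, x0, y0, x1, y1, halfwidth, amp = 1) {
  nr <- nrow(img); nc <- ncol(img)
  m <- ceiling(halfwidth) + 2L
  xs <- max(1L, floor(min(x0, x1)) - m):min(nc, ceiling(max(x0, x1)) + m)
  ys <- max(1L, floor(min(y0, y1)) - m):min(nr, ceiling(max(y0, y1)) + m)
  if (length(xs) == 0 || length(ys) == 0) return(img)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(pmax(((X - x0) * dx + (Y - y0) * dy) / len2, 0), 1)
  d <- sqrt((X - (x0 + t * dx))^2 + (Y - (y0 + t * dy))^2)
  val <- amp * pmin(pmax(halfwidth + 0.5 - d, 0), 1)
  img[ys, xs] <- pmax(img[ys, xs], val)
  img
}

# Additively paint a 2-D Gaussian spot truncated at trunc * sigma.
render_gaussian <- function(img, cx, cy, sigma, amp = 1, trunc = 3) {
  nr <- nrow(img); nc <- ncol(img)
  m <- ceiling(trunc * sigma) + 1L
  xs <- max(1L, floor(cx) - m):min(nc, ceiling(cx) + m)
  ys <- max(1L, floor(cy) - m):min(nr, ceiling(cy) + m)
  if (length(xs) == 0 || length(ys) == 0) return(img)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  r2 <- (X - cx)^2 + (Y - cy)^2
  val <- amp * exp(-r2 / (2 * sigma^2))
  val[r2 > (trunc * sigma)^2] <- 0
  img[ys, xs] <- img[ys, xs] + val
  img
}

# Paint a filled, anti-aliased, rotated ellipse via pixelwise maximum.
render_ellipse <- function(img, cx, cy, a, b, theta_deg = 0, amp = 1) {
  nr <- nrow(img); nc <- ncol(img)
  m <- ceiling(max(a, b)) + 2L
  xs <- max(1L, floor(cx) - m):min(nc, ceiling(cx) + m)
  ys <- max(1L, floor(cy) - m):min(nr, ceiling(cy) + m)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, length(ys), length(xs)) - cy
  th <- theta_deg * pi / 180
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  val <- amp * pmin(pmax((1 - rho) * min(a, b) + 0.5, 0), 1)
  img[ys, xs] <- pmax(img[ys, xs], val)
  img
}

# Pixel coordinates (x, y columns) of a rotated super-ellipse
# |u/a|^4 + |v/b|^4 <= 1 centred at (cx, cy).
superellipse_pixels <- function(cx, cy, a, b, theta_deg, shape) {
  m <- ceiling(max(a, b)) + 2L
  xs <- max(1L, floor(cx) - m):min(shape[2], ceiling(cx) + m)
  ys <- max(1L, floor(cy) - m):min(shape[1], ceiling(cy) + m)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, length(ys), length(xs)) - cy
  th <- theta_deg * pi / 180
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  inside <- (abs(u) / a)^4 + (abs(v) / b)^4 <= 1
  cbind(x = matrix(xs, length(ys), length(xs), byrow = TRUE)[inside],
        y = matrix(ys, length(ys), length(xs))[inside])
}

# Axial orientation sampler: angles in [0, 180) degrees under the requested
# law. Von Mises samples use the doubled-angle construction standard for
# axial data (2 * theta ~ VM(2 * mu, kappa)).
sample_orientations <- function(n, law) {
  kind <- law$kind %||% "uniform"
  switch(kind,
    uniform = runif(n, 0, 180),
    fixed = rep((law$theta %||% 0) %% 180, n),
    von_mises = {
      mu2 <- 2 * (law$mu %||% 0) * pi / 180
      phi <- rvonmises(n, mu2, law$kappa %||% 4)
      ((phi / 2) * 180 / pi) %% 180
    },
    stop("unknown orientation law: ", kind))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# Rejection-sample k centres inside margins with pairwise min separation.
place_centers <- function(k, shape, margin, min_sep, max_tries = 1000L) {
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      px <- runif(1, margin + 1, shape[2] - margin)
      py <- runif(1, margin + 1, shape[1] - margin)
      if (length(cx) == 0 || all((cx - px)^2 + (cy - py)^2 >= min_sep^2)) {
        cx <- c(cx, px); cy <- c(cy, py); ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible packing: could not place object ", i,
                  " after ", max_tries, " tries")
  }
  cbind(x = cx, y = cy)
}

# ---- scene generators ------------------------------------------------------

#' Generate a synthetic actin-fiber scene
#'
#' Renders `n_fibers` anti-aliased bright line segments on a dark
#' background, with fiber axial orientations drawn from the requested law.
#' The truth table records each fiber's orientation both raw (`[0, 180)`)
#' and folded to `[0, 90]` against the stretch axis.
#'
#' @param n_fibers number of fibers (>= 0).
#' @param orientation_law a list: `list(kind = "uniform")`,
#'   `list(kind = "fixed", theta = 30)`, or
#'   `list(kind = "von_mises", mu = 75, kappa = 8)` (degrees).
#' @param fiber_length,fiber_width segment length and full width in pixels.
#' @param image_shape `(ny, nx)` raster size in pixels.
#' @param pixel_size_um physical pixel size.
#' @param stretch_axis strain axis of the scene.
#' @param seed RNG seed (scene is reproducible for a fixed seed).
#' @return `list(stack = ImageStack, truth = SceneTruth)`.
#' @export
make_fiber_scene <- function(n_fibers, orientation_law = list(kind = "uniform"),
                             fiber_length = 40, fiber_width = 3,
                             image_shape = c(288, 384), pixel_size_um = 0.5,
                             stretch_axis = "x", seed = 1) {
  stopifnot(n_fibers >= 0, fiber_length > 0, fiber_width > 0)
  if (any(image_shape < fiber_width))
    stop("degenerate image shape: smaller than fiber width")
  with_seed(seed, {
    img <- matrix(0, image_shape[1], image_shape[2])
    theta <- sample_orientations(n_fibers, orientation_law)
    cx <- runif(n_fibers, 1, image_shape[2])
    cy <- runif(n_fibers, 1, image_shape[1])
    hw <- fiber_width / 2
    for (i in seq_len(n_fibers)) {
      th <- theta[i] * pi / 180
      dx <- cos(th) * fiber_length / 2
      dy <- sin(th) * fiber_length / 2
      img <- render_capsule(img, cx[i] - dx, cy[i] - dy,
                            cx[i] + dx, cy[i] + dy, hw)
    }
    objects <- data.frame(kind = rep("fiber", n_fibers),
                          x = cx, y = cy, theta_deg = theta,
                          theta_folded = fold_to_stretch(theta, stretch_axis),
                          length_px = rep(fiber_length, n_fibers),
                          width_px = rep(fiber_width, n_fibers))
    stack <- image_stack(list(actin = img), pixel_size_um, stretch_axis)
    list(stack = stack,
         truth = scene_truth(objects,
                             c(list(orientation_law = orientation_law,
                                    n_fibers = n_fibers)),
                             seed, pixel_size_um))
  })
}

#' Generate a synthetic LC3B/DAPI puncta scene
#'
#' Puncta are 2-D Gaussian profiles (truncated at 3 sigma) in the `lc3b`
#' channel; nuclei are ellipses in the `dapi` channel. `cluster_pairs` of
#' the `n_spots` puncta are rendered as touching pairs to exercise
#' watershed splitting; the rest are placed at least `min_separation_px`
#' apart. The truth records each punctum's centre, sigma and the pixel area
#' over which its rendered profile exceeds `support_threshold` (the area
#' the downstream `< 70 px` filter acts on).
#'
#' @param n_spots total number of puncta, including clustered ones.
#' @param spot_radius_px radius of the support at `support_threshold`.
#' @param n_nuclei number of DAPI nuclei.
#' @param min_separation_px minimum centre separation of non-cluster spots.
#' @param cluster_pairs number of touching pairs (uses `2 * cluster_pairs`
#'   of the spots).
#' @param image_shape `(ny, nx)` in pixels.
#' @param support_threshold intensity level defining the rendered support.
#' @param amplitude peak intensity of each punctum.
#' @param pixel_size_um physical pixel size (LC3B assay default 0.071 um).
#' @param seed RNG seed.
#' @return `list(stack, truth)`.
#' @export
make_puncta_scene <- function(n_spots, spot_radius_px = 6, n_nuclei = 4,
                              min_separation_px = 4 * spot_radius_px,
                              cluster_pairs = 0, image_shape = c(256, 256),
                              support_threshold = 0.2, amplitude = 1,
                              pixel_size_um = 0.071, seed = 1) {
  stopifnot(n_spots >= 0, n_spots >= 2 * cluster_pairs, spot_radius_px > 0)
  with_seed(seed, {
    sigma <- spot_radius_px / sqrt(2 * log(amplitude / support_threshold))
    n_single <- n_spots - 2L * cluster_pairs
    margin <- 3 * sigma + 2
    # place singles and pair midpoints in one pass so nothing collides
    anchors <- place_centers(n_single + cluster_pairs, image_shape, margin,
                             min_separation_px + 2 * spot_radius_px)
    centers <- NULL; pair_id <- integer(0)
    if (n_single > 0) {
      centers <- anchors[seq_len(n_single), , drop = FALSE]
      pair_id <- rep(NA_integer_, n_single)
    }
    if (cluster_pairs > 0) {
      gap <- 1.8 * spot_radius_px  # centres closer than 2r: supports touch
      for (p in seq_len(cluster_pairs)) {
        mid <- anchors[n_single + p, ]
        ang <- runif(1, 0, pi)
        off <- c(cos(ang), sin(ang)) * gap / 2
        centers <- rbind(centers,
                         c(mid[1] - off[1], mid[2] - off[2]),
                         c(mid[1] + off[1], mid[2] + off[2]))
        pair_id <- c(pair_id, p, p)
      }
    }
    lc3b <- matrix(0, image_shape[1], image_shape[2])
    area_px <- integer(0)
    if (n_spots > 0) {
      for (i in seq_len(n_spots)) {
        lc3b <- render_gaussian(lc3b, centers[i, 1], centers[i, 2],
                                sigma, amplitude)
        solo <- render_gaussian(matrix(0, image_shape[1], image_shape[2]),
                                centers[i, 1], centers[i, 2], sigma, amplitude)
        area_px <- c(area_px, sum(solo > support_threshold))
      }
    }
    # nuclei: disjoint ellipses in the DAPI channel
    dapi <- matrix(0, image_shape[1], image_shape[2])
    nuc <- if (n_nuclei > 0)
      place_centers(n_nuclei, image_shape, 22, 48) else NULL
    nuc_df <- NULL
    for (i in seq_len(n_nuclei)) {
      a <- runif(1, 12, 16); b <- runif(1, 9, 12); th <- runif(1, 0, 180)
      dapi <- render_ellipse(dapi, nuc[i, 1], nuc[i, 2], a, b, th, amp = 0.9)
      nuc_df <- rbind(nuc_df,
                      data.frame(kind = "nucleus", x = nuc[i, 1],
                                 y = nuc[i, 2], theta_deg = th,
                                 theta_folded = NA, sigma = NA,
                                 rendered_area_px = NA, pair_id = NA))
    }
    spot_df <- if (n_spots > 0)
      data.frame(kind = "punctum", x = centers[, 1], y = centers[, 2],
                 theta_deg = NA, theta_folded = NA, sigma = sigma,
                 rendered_area_px = area_px, pair_id = pair_id)
    else NULL
    objects <- rbind(spot_df, nuc_df)
    if (is.null(objects))
      objects <- data.frame(kind = character(), x = numeric(), y = numeric(),
                            theta_deg = numeric(), theta_folded = numeric(),
                            sigma = numeric(), rendered_area_px = numeric(),
                            pair_id = integer())
    stack <- image_stack(list(lc3b = lc3b, dapi = dapi), pixel_size_um, "x")
    list(stack = stack,
         truth = scene_truth(objects,
                             list(n_spots = n_spots, n_nuclei = n_nuclei,
                                  spot_radius_px = spot_radius_px,
                                  support_threshold = support_threshold,
                                  cluster_pairs = cluster_pairs),
                             seed, pixel_size_um))
  })
}

#' Generate a two-channel focal-adhesion scene
#'
#' Each adhesion pair is a rotated super-ellipse support rendered in the
#' `pxn` channel and a shifted copy in the `vcl` channel sharing exactly
#' `overlap_px` foreground pixels (the shift runs along the pair's major
#' axis; surplus intersection pixels are trimmed from the trailing edge of
#' the `vcl` spot, which keeps it connected). Optional lone spots appear
#' only in the `pxn` channel.
#'
#' @param n_pairs number of adhesion pairs.
#' @param overlap_px exact shared-pixel count per pair (`<= spot_area_px`).
#' @param spot_area_px approximate per-spot support area in pixels.
#' @param orientation_law axial orientation law (see [make_fiber_scene()]).
#' @param n_lone number of unpaired `pxn`-only spots.
#' @param image_shape `(ny, nx)` in pixels.
#' @param pixel_size_um physical pixel size (FA assay default 0.183 um).
#' @param stretch_axis strain axis.
#' @param seed RNG seed.
#' @return `list(stack, truth)`; the truth has one `adhesion_pair` row per
#'   pair with per-channel areas, union area and overlap.
#' @export
make_adhesion_scene <- function(n_pairs, overlap_px = 5, spot_area_px = 150,
                                orientation_law = list(kind = "uniform"),
                                n_lone = 0, image_shape = c(256, 256),
                                pixel_size_um = 0.183, stretch_axis = "x",
                                seed = 1) {
  stopifnot(n_pairs >= 0, overlap_px >= 0, overlap_px <= spot_area_px)
  with_seed(seed, {
    # aspect-3 super-ellipse sized to the requested area
    c4 <- 3.708149  # area of |x|^4 + |y|^4 <= 1
    b <- sqrt(spot_area_px / (3 * c4)); a <- 3 * b
    theta <- sample_orientations(n_pairs + n_lone, orientation_law)
    margin <- 2 * a + 6
    ctr <- if (n_pairs + n_lone > 0)
      place_centers(n_pairs + n_lone, image_shape, margin, 2 * (2 * a + 4))
    else matrix(numeric(0), 0, 2)
    pxn <- matrix(0, image_shape[1], image_shape[2])
    vcl <- matrix(0, image_shape[1], image_shape[2])
    rows <- NULL
    for (i in seq_len(n_pairs)) {
      th <- theta[i]
      A <- superellipse_pixels(ctr[i, 1], ctr[i, 2], a, b, th, image_shape)
      dirv <- c(cos(th * pi / 180), sin(th * pi / 180))
      keyA <- A[, "x"] * 1e5 + A[, "y"]
      B <- NULL
      # largest integer shift along the axis keeping >= overlap_px shared px
      for (d in seq(2 * a + 4, 0, by = -1)) {
        cand <- cbind(x = round(A[, "x"] + dirv[1] * d),
                      y = round(A[, "y"] + dirv[2] * d))
        cand <- cand[cand[, 1] >= 1 & cand[, 1] <= image_shape[2] &
                     cand[, 2] >= 1 & cand[, 2] <= image_shape[1], , drop = FALSE]
        cand <- cand[!duplicated(cand[, 1] * 1e5 + cand[, 2]), , drop = FALSE]
        inter <- (cand[, 1] * 1e5 + cand[, 2]) %in% keyA
        if (sum(inter) >= overlap_px) { B <- cand; break }
      }
      if (is.null(B)) stop("could not realise requested overlap for pair ", i)
      keyB <- B[, 1] * 1e5 + B[, 2]
      inter_idx <- which(keyB %in% keyA)
      excess <- length(inter_idx) - overlap_px
      if (excess > 0) {
        # drop intersection pixels deepest into A (trailing tip of B)
        proj <- B[inter_idx, 1] * dirv[1] + B[inter_idx, 2] * dirv[2]
        drop_idx <- inter_idx[order(proj)][seq_len(excess)]
        B <- B[-drop_idx, , drop = FALSE]
        inter_idx <- which((B[, 1] * 1e5 + B[, 2]) %in% keyA)
      }
      pxn[cbind(A[, "y"], A[, "x"])] <- 1
      vcl[cbind(B[, 2], B[, 1])] <- 1
      union_px <- nrow(A) + nrow(B) - length(inter_idx)
      rows <- rbind(rows, data.frame(
        kind = "adhesion_pair", x = ctr[i, 1], y = ctr[i, 2],
        theta_deg = th, theta_folded = fold_to_stretch(th, stretch_axis),
        pxn_area_px = nrow(A), vcl_area_px = nrow(B),
        union_area_px = union_px, overlap_px = length(inter_idx)))
    }
    for (i in seq_len(n_lone)) {
      j <- n_pairs + i
      A <- superellipse_pixels(ctr[j, 1], ctr[j, 2], a, b, theta[j], image_shape)
      pxn[cbind(A[, "y"], A[, "x"])] <- 1
      rows <- rbind(rows, data.frame(
        kind = "lone_spot", x = ctr[j, 1], y = ctr[j, 2],
        theta_deg = theta[j],
        theta_folded = fold_to_stretch(theta[j], stretch_axis),
        pxn_area_px = nrow(A), vcl_area_px = 0,
        union_area_px = nrow(A), overlap_px = 0))
    }
    if (is.null(rows))
      rows <- data.frame(kind = character(), x = numeric(), y = numeric(),
                         theta_deg = numeric(), theta_folded = numeric(),
                         pxn_area_px = integer(), vcl_area_px = integer(),
                         union_area_px = integer(), overlap_px = integer())
    stack <- image_stack(list(pxn = pxn, vcl = vcl), pixel_size_um,
                         stretch_axis)
    list(stack = stack,
         truth = scene_truth(rows,
                             list(n_pairs = n_pairs, overlap_px = overlap_px,
                                  spot_area_px = spot_area_px,
                                  orientation_law = orientation_law,
                                  n_lone = n_lone),
                             seed, pixel_size_um))
  })
}

#' Generate a curvilinear mitochondrial-network scene
#'
#' Branches are random-walk polylines (unit steps with small angular
#' diffusion) dilated to the requested width, distributed across
#' `n_planes`; an `actin` channel carries large cell-shaped regions for
#' masking. The truth records each branch's plane, step length and rendered
#' support area.
#'
#' @param n_branches number of branches.
#' @param branch_length_law `list(kind = "uniform", min = 20, max = 60)` or
#'   `list(kind = "fixed", length = 100)` (in unit steps).
#' @param intensity_scale peak branch intensity.
#' @param image_shape `(ny, nx)` in pixels.
#' @param n_planes number of z-planes in the mitochondrial channel.
#' @param width_px full branch width after dilation (2-4 px typical).
#' @param wiggle angular-diffusion SD per step in radians (0 = straight).
#' @param channel channel label, `"tomm20"` or `"mitotracker"`.
#' @param pixel_size_um physical pixel size.
#' @param seed RNG seed.
#' @return `list(stack, truth)`.
#' @export
make_mito_scene <- function(n_branches,
                            branch_length_law = list(kind = "uniform",
                                                     min = 20, max = 60),
                            intensity_scale = 1, image_shape = c(256, 256),
                            n_planes = 1, width_px = 3, wiggle = 0.15,
                            channel = "tomm20", pixel_size_um = 0.183,
                            seed = 1) {
  stopifnot(n_branches >= 0, n_planes >= 1, width_px >= 1)
  with_seed(seed, {
    arr <- array(0, dim = c(image_shape[1], image_shape[2], n_planes))
    lens <- switch(branch_length_law$kind %||% "uniform",
      uniform = round(runif(n_branches, branch_length_law$min %||% 20,
                            branch_length_law$max %||% 60)),
      fixed = rep(branch_length_law$length %||% 40, n_branches),
      stop("unknown branch length law"))
    margin <- max(lens %||% 0, 10) / 2 + width_px + 2
    planes <- if (n_branches > 0)
      sample(rep_len(seq_len(n_planes), n_branches)) else integer(0)
    rows <- NULL
    hw <- width_px / 2
    occupied <- replicate(n_planes, matrix(FALSE, image_shape[1],
                                           image_shape[2]), simplify = FALSE)
    for (i in seq_len(n_branches)) {
      ok <- FALSE
      for (t in 1:200) {
        x <- runif(1, margin, image_shape[2] - margin)
        y <- runif(1, margin, image_shape[1] - margin)
        ang <- runif(1, 0, 2 * pi)
        px <- x; py <- y
        pts <- matrix(c(x, y), 1, 2)
        for (s in seq_len(lens[i])) {
          ang <- ang + rnorm(1, 0, wiggle)
          px <- px + cos(ang); py <- py + sin(ang)
          pts <- rbind(pts, c(px, py))
        }
        if (!(all(pts[, 1] > hw + 1) && all(pts[, 1] < image_shape[2] - hw) &&
              all(pts[, 2] > hw + 1) && all(pts[, 2] < image_shape[1] - hw)))
          next
        # exclusion zone: a fattened version of the branch must not touch
        # previously placed branches in the same plane, so object counts
        # in the truth stay exact
        excl <- matrix(0, image_shape[1], image_shape[2])
        for (s in seq_len(nrow(pts) - 1))
          excl <- render_capsule(excl, pts[s, 1], pts[s, 2], pts[s + 1, 1],
                                 pts[s + 1, 2], hw + 3)
        if (any(occupied[[planes[i]]] & excl > 0)) next
        ok <- TRUE; break
      }
      if (!ok) stop("infeasible packing for branch ", i)
      occupied[[planes[i]]] <- occupied[[planes[i]]] | excl > 0
      # inset the endpoints by the half-width so the rendered end-to-end
      # extent (and hence the skeleton length) matches the step length
      np <- nrow(pts)
      v1 <- pts[2, ] - pts[1, ]; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- pts[np - 1, ] - pts[np, ]; v2 <- v2 / sqrt(sum(v2^2))
      pts[1, ] <- pts[1, ] + v1 * hw
      pts[np, ] <- pts[np, ] + v2 * hw
      pl <- matrix(0, image_shape[1], image_shape[2])
      for (s in seq_len(np - 1))
        pl <- render_capsule(pl, pts[s, 1], pts[s, 2], pts[s + 1, 1],
                             pts[s + 1, 2], hw, amp = intensity_scale)
      arr[, , planes[i]] <- pmax(arr[, , planes[i]], pl)
      rows <- rbind(rows, data.frame(kind = "mito_branch", x = pts[1, 1],
                                     y = pts[1, 2], plane = planes[i],
                                     length_px = lens[i],
                                     area_px = sum(pl > intensity_scale / 2)))
    }
    if (is.null(rows))
      rows <- data.frame(kind = character(), x = numeric(), y = numeric(),
                         plane = integer(), length_px = numeric(),
                         area_px = integer())
    # cell regions in the actin channel (2 large soft ellipses)
    actin <- matrix(0, image_shape[1], image_shape[2])
    actin <- render_ellipse(actin, image_shape[2] * 0.3, image_shape[1] * 0.5,
                            image_shape[2] * 0.26, image_shape[1] * 0.4,
                            20, amp = 0.6)
    actin <- render_ellipse(actin, image_shape[2] * 0.72, image_shape[1] * 0.5,
                            image_shape[2] * 0.26, image_shape[1] * 0.4,
                            160, amp = 0.6)
    actin_arr <- array(rep(actin, n_planes),
                       dim = c(image_shape[1], image_shape[2], n_planes))
    channels <- stats::setNames(list(arr, actin_arr), c(channel, "actin"))
    stack <- image_stack(channels, pixel_size_um, "x")
    list(stack = stack,
         truth = scene_truth(rows,
                             list(n_branches = n_branches,
                                  branch_length_law = branch_length_law,
                                  width_px = width_px, n_planes = n_planes,
                                  total_area_px = sum(arr > intensity_scale / 2),
                                  cell_mask = NULL),
                             seed, pixel_size_um,
                             masks = list(cell = actin > 0.3)))
  })
}

#' Generate a dual-channel JC-1 scene with a prescribed red/green ratio
#'
#' Cells are rendered as identical soft-edged supports in the `jc1_red` and
#' `jc1_green` channels; the red channel is the green channel scaled by
#' `red_green_ratio`, so the foreground mean-intensity ratio equals the
#' prescribed value exactly before noise.
#'
#' @param red_green_ratio target ratio of red to green foreground means.
#' @param n_cells number of cell regions.
#' @param image_shape `(ny, nx)` in pixels.
#' @param green_level peak green foreground intensity.
#' @param pixel_size_um physical pixel size (JC-1 assay default 0.721 um).
#' @param seed RNG seed.
#' @return `list(stack, truth)`; `truth$masks$cells` is the union support.
#' @export
make_jc1_scene <- function(red_green_ratio, n_cells = 5,
                           image_shape = c(256, 256), green_level = 100,
                           pixel_size_um = 0.721, seed = 1) {
  stopifnot(red_green_ratio > 0, n_cells >= 0)
  with_seed(seed, {
    green <- matrix(0, image_shape[1], image_shape[2])
    ctr <- if (n_cells > 0) place_centers(n_cells, image_shape, 30, 62)
           else matrix(numeric(0), 0, 2)
    rows <- NULL
    for (i in seq_len(n_cells)) {
      a <- runif(1, 18, 26); b <- runif(1, 12, 20); th <- runif(1, 0, 180)
      green <- render_ellipse(green, ctr[i, 1], ctr[i, 2], a, b, th,
                              amp = green_level)
      rows <- rbind(rows, data.frame(kind = "jc1_region", x = ctr[i, 1],
                                     y = ctr[i, 2], a = a, b = b,
                                     theta_deg = th))
    }
    if (is.null(rows))
      rows <- data.frame(kind = character(), x = numeric(), y = numeric(),
                         a = numeric(), b = numeric(), theta_deg = numeric())
    red <- green * red_green_ratio
    stack <- image_stack(list(jc1_red = red, jc1_green = green),
                         pixel_size_um, "x")
    list(stack = stack,
         truth = scene_truth(rows,
                             list(red_green_ratio = red_green_ratio,
                                  n_cells = n_cells,
                                  green_level = green_level),
                             seed, pixel_size_um,
                             masks = list(cells = green > 0)))
  })
}

#' Apply a Poisson-plus-Gaussian camera noise model
#'
#' Each pixel becomes
#' `Poisson(photon_scale * I) / photon_scale + N(0, read_noise_sd) +
#' background_offset`, clipped at zero. Large `photon_scale` with zero read
#' noise approaches the identity.
#'
#' @param stack an [image_stack()].
#' @param photon_scale photons per intensity unit (shot-noise strength).
#' @param read_noise_sd Gaussian read-noise SD (intensity units).
#' @param background_offset constant added background.
#' @param seed RNG seed.
#' @return a noisy [image_stack()] with the same geometry.
#' @export
apply_noise <- function(stack, photon_scale = 100, read_noise_sd = 0.01,
                        background_offset = 0.02, seed = 1) {
  stopifnot(inherits(stack, "ImageStack"), photon_scale > 0,
            read_noise_sd >= 0, background_offset >= 0)
  with_seed(seed, {
    channels <- lapply(stack$channels, function(ch) {
      v <- rpois(length(ch), photon_scale * as.numeric(ch)) / photon_scale
      v <- v + rnorm(length(ch), 0, read_noise_sd) + background_offset
      array(pmax(v, 0), dim = dim(ch))
    })
    image_stack(channels, stack$pixel_size_um, stack$stretch_axis,
                dtype_max = stack$dtype_max)
  })
}
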