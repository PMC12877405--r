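test_that("background peak threshold matches the Gaussian FWHM oracle", {
  set.seed(21)
  # bimodal: background N(100, 10), foreground N(200, 10)
  img <- matrix(c(rnorm(8e4, 100, 10), rnorm(2e4, 200, 10)), 100, 1000)
  thr <- background_peak_threshold(img)
  # closed form: threshold = 100 + 0.2 * (2.3548 * 10)
  expect_equal(thr, 100 + 0.2 * 2 * sqrt(2 * log(2)) * 10, tolerance = 1 / 4.7)

  # symmetric single peak: threshold right of the peak, left of the point
  # where the right flank reaches half maximum
  set.seed(22)
  sym <- matrix(rnorm(5e4, 50, 5), 50, 1000)
  t2 <- background_peak_threshold(sym)
  expect_gt(t2, 50)
  expect_lt(t2, 50 + 0.5 * 2.3548 * 5 + 1)

  # two-level image: first peak at the low level, threshold in between
  two <- matrix(rep(c(10, 200), each = 512), 32, 32)
  t3 <- background_peak_threshold(two)
  expect_gt(t3, 10); expect_lt(t3, 200)

  expect_error(background_peak_threshold(matrix(5, 8, 8)), "degenerate")
})

test_that("cell mask covers the bright plateau and only its blur halo", {
  set.seed(23)
  img <- matrix(rnorm(256 * 256, 100, 3), 256, 256)
  img[60:200, 50:150] <- rnorm(141 * 101, 200, 3)
  truth <- matrix(FALSE, 256, 256); truth[60:200, 50:150] <- TRUE
  m <- cell_mask(img)
  # the plateau is fully inside the mask: the threshold sits just above
  # the background peak, so the ROI is generous but never clips cells
  expect_equal(sum(truth & !m), 0)
  # the mask separates signal from background on average
  expect_gt(mean(img[m]), mean(img[!m]) + 30)
  expect_lt(mean(m), 0.55)

  # uniformly bright image: single population, full frame is cell
  expect_warning(mb <- cell_mask(matrix(150, 64, 64)), "bright")
  expect_true(all(mb))

  expect_error(cell_mask(matrix(0, 32, 32)), "degenerate")
})

test_that("channel spot detection finds blobs and rejects flat fields", {
  expect_equal(n_regions(channel_spots(matrix(5, 64, 64))), 0)

  img <- matrix(0, 128, 128)
  px <- stretchquant:::superellipse_pixels(64, 64, 21, 2.3, 25, c(128, 128))
  img[cbind(px[, "y"], px[, "x"])] <- 1
  sp <- channel_spots(img, min_area_px = 100)
  expect_equal(n_regions(sp), 1)

  # the area rule is strict: a spot of exactly min_area_px is rejected
  a0 <- sp$regions$area_px[1]
  expect_equal(n_regions(channel_spots(img, min_area_px = a0)), 0)
  expect_equal(n_regions(channel_spots(img, min_area_px = a0 - 1)), 1)
})

test_that("overlap is counted per partner spot, never pooled", {
  sc <- make_adhesion_scene(6, overlap_px = 5, seed = 24)
  sa <- segment_puncta(sc$stack$channels$pxn[, , 1], 0.5, 1, 0.183)
  sb <- segment_puncta(sc$stack$channels$vcl[, , 1], 0.5, 1, 0.183)
  flt <- mutual_overlap_filter(sa, sb, 5)
  expect_equal(n_regions(flt$a), 6)
  expect_equal(n_regions(flt$b), 6)
  expect_true(all(flt$pairs$overlap_px == 5))

  sc4 <- make_adhesion_scene(6, overlap_px = 4, seed = 24)
  sa <- segment_puncta(sc4$stack$channels$pxn[, , 1], 0.5, 1, 0.183)
  sb <- segment_puncta(sc4$stack$channels$vcl[, , 1], 0.5, 1, 0.183)
  flt4 <- mutual_overlap_filter(sa, sb, 5)
  expect_equal(n_regions(flt4$a), 0)
  expect_equal(n_regions(flt4$b), 0)

  # one A spot overlapping two B spots by 3 px each: pooled overlap 6
  # would pass, per-partner overlap 3 must not
  A <- matrix(0, 40, 40); A[15:25, 10:30] <- 1
  B <- matrix(0, 40, 40); B[15:17, 10] <- 1; B[10:14, 10] <- 1
  B[23:25, 30] <- 1; B[26:30, 30] <- 1
  la <- label_regions(A > 0); lb <- label_regions(B > 0)
  expect_equal(n_regions(lb), 2)
  flt <- mutual_overlap_filter(la, lb, 5)
  expect_equal(n_regions(flt$a), 0)

  # lone spot with no partner is dropped
  lone <- make_adhesion_scene(0, n_lone = 5, seed = 25)
  sa <- segment_puncta(lone$stack$channels$pxn[, , 1], 0.5, 1, 0.183)
  sb <- segment_puncta(lone$stack$channels$vcl[, , 1], 0.5, 1, 0.183)
  flt <- mutual_overlap_filter(sa, sb, 5)
  expect_equal(n_regions(flt$a), 0)
})

test_that("adhesion assembly follows inclusion-exclusion on union areas", {
  # A spot of 150 px overlapping a B spot of 120 px by exactly 30 px
  A <- matrix(0, 64, 64); A[20:34, 10:19] <- 1      # 15 x 10 = 150
  Bm <- matrix(0, 64, 64); Bm[20:25, 15:34] <- 1    # 6 x 20 = 120
  expect_equal(sum(Bm > 0 & A > 0), 30)             # 6 x 5 overlap
  tab <- build_adhesions(label_regions(A > 0), label_regions(Bm > 0))
  expect_equal(nrow(tab$adhesions), 1)
  expect_equal(tab$adhesions$pxn_area_px, 150)
  expect_equal(tab$adhesions$vcl_area_px, 120)
  expect_equal(tab$adhesions$union_area_px, 240)

  # disjoint spots: components lacking a channel are dropped
  tab0 <- build_adhesions(label_regions(A > 0),
                          label_regions(matrix(FALSE, 64, 64)))
  expect_equal(nrow(tab0$adhesions), 0)
})

test_that("adhesion orientation and areas track the generator truth", {
  sc <- make_adhesion_scene(20, overlap_px = 8, spot_area_px = 200,
                            image_shape = c(384, 384), seed = 26)
  sa <- segment_puncta(sc$stack$channels$pxn[, , 1], 0.5, 1, 0.183)
  sb <- segment_puncta(sc$stack$channels$vcl[, , 1], 0.5, 1, 0.183)
  flt <- mutual_overlap_filter(sa, sb, 5)
  tab <- build_adhesions(flt$a, flt$b, 0.183, "x")
  expect_equal(nrow(tab$adhesions), 20)

  tr <- sc$truth$objects
  j <- nearest_truth(tab$adhesions$centroid_x, tab$adhesions$centroid_y,
                     tr$x, tr$y)
  rel <- abs(tab$adhesions$union_area_px - tr$union_area_px[j]) /
    tr$union_area_px[j]
  expect_lt(max(rel), 0.1)
  expect_lt(max(axial_diff(tab$adhesions$orientation_deg,
                           tr$theta_folded[j])), 3)

  # raising the overlap bound never increases the FA count
  n_prev <- Inf
  for (mo in c(1, 5, 9, 20)) {
    f <- mutual_overlap_filter(sa, sb, mo)
    n <- nrow(build_adhesions(f$a, f$b, 0.183, "x")$adhesions)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("per-image adhesion summaries are consistent", {
  sc <- make_adhesion_scene(12, overlap_px = 6, seed = 27,
                            image_shape = c(384, 384))
  sa <- segment_puncta(sc$stack$channels$pxn[, , 1], 0.5, 1, 0.183)
  sb <- segment_puncta(sc$stack$channels$vcl[, , 1], 0.5, 1, 0.183)
  flt <- mutual_overlap_filter(sa, sb, 5)
  tab <- build_adhesions(flt$a, flt$b, 0.183, "x")
  met <- adhesion_metrics(tab, n_cells = 4)
  expect_equal(met$summary$fa_per_cell, 3)
  expect_gt(met$summary$pxn_coverage_fraction, 0)
  expect_lte(met$summary$pxn_coverage_fraction, 1)
  expect_equal(met$distribution$n_units, 12)
  expect_true(all(tab$adhesions$union_area_px >=
                  pmax(tab$adhesions$pxn_area_px, tab$adhesions$vcl_area_px)))

  # mean FA area: 2 FAs of 200 and 400 px at 0.183 um/px
  fake <- tab
  fake$adhesions <- data.frame(fa_id = 1:2, pxn_area_px = c(200, 400),
                               vcl_area_px = c(200, 400),
                               union_area_px = c(200, 400),
                               union_area_um2 = c(200, 400) * 0.183^2,
                               orientation_deg = c(10, 20),
                               centroid_x = c(1, 2), centroid_y = c(1, 2),
                               multi_partner = FALSE)
  met2 <- adhesion_metrics(fake, 1)
  expect_equal(met2$summary$mean_fa_area_um2, 300 * 0.183^2)
  expect_equal(met2$summary$pxn_coverage_fraction, 1)
})
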