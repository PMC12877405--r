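test_that("all generators are deterministic under a fixed seed", {
  gens <- list(
    function(s) make_fiber_scene(30, seed = s)$stack$channels$actin,
    function(s) make_puncta_scene(8, cluster_pairs = 2,
                                  seed = s)$stack$channels$lc3b,
    function(s) make_adhesion_scene(4, seed = s)$stack$channels$pxn,
    function(s) make_mito_scene(5, seed = s)$stack$channels$tomm20,
    function(s) make_jc1_scene(2, seed = s)$stack$channels$jc1_red)
  for (g in gens) expect_identical(g(11), g(11))
})

test_that("fiber scenes render the requested orientation law", {
  blank <- make_fiber_scene(0, seed = 1)
  expect_equal(sum(blank$stack$channels$actin), 0)
  expect_equal(nrow(blank$truth$objects), 0)

  fx <- make_fiber_scene(50, list(kind = "fixed", theta = 30), seed = 2)
  expect_equal(fx$truth$objects$theta_deg, rep(30, 50))
  expect_equal(fx$truth$objects$theta_folded, rep(30, 50))

  # Monte-Carlo check of the generator itself: uniform law folds to
  # mean 45 degrees within 3 standard errors
  un <- make_fiber_scene(500, list(kind = "uniform"), seed = 3)
  folded <- un$truth$objects$theta_folded
  se <- sd(folded) / sqrt(length(folded))
  expect_lt(abs(mean(folded) - 45), 3 * se)

  expect_error(make_fiber_scene(5, image_shape = c(2, 2), fiber_width = 3),
               "degenerate")
})

test_that("puncta truth records rendered support areas and cluster pairs", {
  blank <- make_puncta_scene(0, n_nuclei = 3, seed = 1)
  expect_equal(sum(blank$stack$channels$lc3b), 0)
  expect_equal(sum(blank$truth$objects$kind == "nucleus"), 3)

  sc <- make_puncta_scene(12, spot_radius_px = 6, cluster_pairs = 0, seed = 4)
  ob <- sc$truth$objects[sc$truth$objects$kind == "punctum", ]
  expect_equal(nrow(ob), 12)
  expect_true(all(ob$rendered_area_px >= 70))
  # isolated spots: support area in the rendered image matches the truth
  img <- sc$stack$channels$lc3b[, , 1]
  expect_equal(sum(img > 0.2), sum(ob$rendered_area_px))

  cl <- make_puncta_scene(8, cluster_pairs = 4, seed = 5)
  ob <- cl$truth$objects[cl$truth$objects$kind == "punctum", ]
  expect_equal(nrow(ob), 8)
  expect_equal(as.integer(table(ob$pair_id)), rep(2L, 4))
  # each pair touches: centre distance below two support radii
  for (p in 1:4) {
    q <- ob[which(ob$pair_id == p), ]
    d <- sqrt(diff(q$x)^2 + diff(q$y)^2)
    expect_lt(d, 2 * 6)
  }
})

test_that("adhesion pairs share exactly the requested overlap", {
  for (ov in c(5, 4)) {
    sc <- make_adhesion_scene(6, overlap_px = ov, seed = 6)
    expect_equal(sc$truth$objects$overlap_px, rep(ov, 6))
    # verify against the rasters, not just the truth table
    a <- sc$stack$channels$pxn[, , 1] > 0.5
    b <- sc$stack$channels$vcl[, , 1] > 0.5
    expect_equal(sum(a & b), 6 * ov)
    expect_true(all(sc$truth$objects$union_area_px ==
                      sc$truth$objects$pxn_area_px +
                      sc$truth$objects$vcl_area_px - ov))
  }

  lone <- make_adhesion_scene(0, n_lone = 10, seed = 7)
  expect_equal(sum(lone$truth$objects$kind == "adhesion_pair"), 0)
  expect_equal(sum(lone$truth$objects$kind == "lone_spot"), 10)
  expect_equal(sum(lone$stack$channels$vcl), 0)
})

test_that("mito branches have consistent length and area truth", {
  blank <- make_mito_scene(0, seed = 1)
  expect_equal(sum(blank$stack$channels$tomm20), 0)

  one <- make_mito_scene(1, list(kind = "fixed", length = 100), wiggle = 0,
                         seed = 2)
  ob <- one$truth$objects
  expect_equal(ob$length_px, 100)
  # rendered support of a straight 3-px-wide branch: about width x length
  expect_gt(ob$area_px, 100 * 2)
  expect_lt(ob$area_px, 100 * 5)

  h1 <- make_mito_scene(20, n_planes = 2, seed = 3)$stack$channels$tomm20
  h2 <- make_mito_scene(20, n_planes = 2, seed = 3)$stack$channels$tomm20
  expect_identical(h1, h2)
})

test_that("jc1 scenes realize the prescribed red/green ratio", {
  sc <- make_jc1_scene(2.5, seed = 8)
  msk <- sc$truth$masks$cells
  r <- sc$stack$channels$jc1_red[, , 1]
  g <- sc$stack$channels$jc1_green[, , 1]
  expect_equal(mean(r[msk]) / mean(g[msk]), 2.5, tolerance = 1e-12)

  one <- make_jc1_scene(1, seed = 9)
  expect_identical(one$stack$channels$jc1_red, one$stack$channels$jc1_green)

  # generator-side measurement under the standard noise model within 2%
  noisy <- apply_noise(sc$stack, photon_scale = 100, read_noise_sd = 0.01,
                       background_offset = 0.02, seed = 10)
  rn <- noisy$channels$jc1_red[, , 1]; gn <- noisy$channels$jc1_green[, , 1]
  expect_equal(mean(rn[msk]) / mean(gn[msk]), 2.5, tolerance = 0.02)
})

test_that("the camera noise model has the stated moments and limits", {
  s <- image_stack(list(a = matrix(0.5, 50, 50)), 1)
  # noise-free limit: huge photon budget, no read noise, no offset
  quiet <- apply_noise(s, photon_scale = 1e7, read_noise_sd = 0,
                       background_offset = 0, seed = 1)
  expect_lt(max(abs(quiet$channels$a - 0.5)), 0.01)

  expect_identical(apply_noise(s, 50, 0.02, 0.1, seed = 3)$channels$a,
                   apply_noise(s, 50, 0.02, 0.1, seed = 3)$channels$a)

  # moment check on a constant plane: var = I / photon_scale + sd^2
  big <- image_stack(list(a = matrix(2, 1000, 1000)), 1)
  n <- apply_noise(big, photon_scale = 50, read_noise_sd = 0.1,
                   background_offset = 0, seed = 4)
  expect_equal(var(as.numeric(n$channels$a)), 2 / 50 + 0.1^2,
               tolerance = 0.05)
})
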