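test_that("tomm20 segmentation keeps tubules and yields thin skeletons", {
  blank <- tomm20_segment_plane(matrix(0, 64, 64))
  expect_equal(sum(blank$mask), 0)
  expect_equal(sum(blank$skeleton), 0)

  sc <- make_mito_scene(1, list(kind = "fixed", length = 100), wiggle = 0,
                        seed = 2)
  seg <- tomm20_segment_plane(sc$stack$channels$tomm20[, , 1])
  expect_equal(n_regions(label_regions(seg$skeleton)), 1)
  # skeleton is a subset of the binary mask
  expect_true(all(!seg$skeleton | seg$mask))
  # thinning is idempotent
  again <- stretchquant:::thin_cpp(
    matrix(as.integer(seg$skeleton), nrow(seg$skeleton))) > 0
  expect_identical(again, seg$skeleton)
})

test_that("single straight branches measure their nominal length", {
  lens <- vapply(1:5, function(s) {
    sc <- make_mito_scene(1, list(kind = "fixed", length = 100), wiggle = 0,
                          seed = s)
    seg <- tomm20_segment_plane(sc$stack$channels$tomm20[, , 1])
    skeleton_length(seg$skeleton)
  }, numeric(1))
  # digitisation bias is angle-dependent; the mean over random branch
  # angles must sit within the dilation-end tolerance
  expect_lt(abs(mean(lens) - 100), 4)
})

test_that("branch counts track truth within 10% with and without noise", {
  sc <- make_mito_scene(20, n_planes = 2, seed = 3)
  truth_per_plane <- as.numeric(table(sc$truth$objects$plane))
  st <- tomm20_stats(sc$stack, sc$truth$masks$cell, n_cells = 2)
  expect_true(all(abs(st$per_plane$n_objects - truth_per_plane) <=
                  0.1 * truth_per_plane))

  noisy <- apply_noise(sc$stack, photon_scale = 25, read_noise_sd = 0.02,
                       background_offset = 0.05, seed = 4)
  st2 <- tomm20_stats(noisy, sc$truth$masks$cell, n_cells = 2)
  expect_true(all(abs(st2$per_plane$n_objects - truth_per_plane) <=
                  0.1 * truth_per_plane))
})

test_that("morphology summaries average planes and divide by cells", {
  # synthetic per-plane results: 6 objects in each of 3 planes, 2 cells
  arr <- array(0, dim = c(128, 128, 3))
  for (k in 1:3) {
    pl <- matrix(0, 128, 128)
    for (i in 1:6)
      pl <- paint_blob(pl, 20 * i, 30 + 20 * k, 40)
    arr[, , k] <- pl
  }
  st <- tomm20_stats(image_stack(list(tomm20 = arr), 0.183), NULL, 2)
  expect_equal(st$per_plane$n_objects, rep(6, 3))
  expect_equal(st$objects_per_cell, 3)
  expect_true(st$mean_area_normalized >= 0 && st$mean_area_normalized <= 1)

  empty <- image_stack(list(tomm20 = array(0, dim = c(32, 32, 2))), 0.183)
  st0 <- tomm20_stats(empty, NULL, 1)
  expect_equal(st0$objects_per_cell, 0)
  expect_equal(st0$mean_area_normalized, 0)
})

test_that("mitotracker intensity is background-corrected and offset-invariant", {
  sc <- make_jc1_scene(1, n_cells = 4, image_shape = c(384, 384),
                       green_level = 250, seed = 6)
  img <- sc$truth$masks$cells * 250 + 50
  st <- image_stack(list(mitotracker = img), 0.18)
  res <- mitotracker_intensity(st)
  expect_equal(res$corrected_intensity, 250, tolerance = 0.02)

  shifted <- image_stack(list(mitotracker = img + 500), 0.18)
  res2 <- mitotracker_intensity(shifted)
  expect_equal(res2$corrected_intensity, res$corrected_intensity,
               tolerance = 1e-8)

  res3 <- mitotracker_intensity(st, control_mean = res$corrected_intensity / 2)
  expect_equal(res3$normalized, 2, tolerance = 0.02)
})

test_that("the small-object removal boundary is inclusive at the bound", {
  # two cells; probe the boundary with the smaller one's exact mask area
  sc <- make_jc1_scene(1, n_cells = 2, image_shape = c(384, 384),
                       green_level = 250, seed = 7)
  img <- sc$truth$masks$cells * 250 + 50
  st <- image_stack(list(mitotracker = img), 0.18)
  base <- mitotracker_intensity(st, min_object_px = 1)
  areas <- sort(label_regions(base$mask)$regions$area_px)
  expect_equal(length(areas), 2)
  a0 <- areas[1]
  keep <- mitotracker_intensity(st, min_object_px = a0)
  drop <- mitotracker_intensity(st, min_object_px = a0 + 1)
  expect_equal(sum(keep$mask), sum(areas))
  expect_equal(sum(drop$mask), areas[2])

  # all objects below the bound is an error with a diagnostic
  expect_error(mitotracker_intensity(st, min_object_px = 1e7),
               "empty cell mask")
})

test_that("jc1 ratios are recovered, scale-invariant and monotone", {
  for (r in c(0.5, 1, 2.5)) {
    sc <- make_jc1_scene(r, seed = 8)
    got <- jc1_ratio(sc$stack)$red_green_ratio
    expect_equal(got, r, tolerance = 0.02)
  }

  # identical channels: ratio exactly 1
  sc <- make_jc1_scene(1, seed = 9)
  expect_equal(jc1_ratio(sc$stack)$red_green_ratio, 1)

  # invariance to a common positive scale factor
  sc <- make_jc1_scene(2, seed = 10)
  scaled <- image_stack(lapply(sc$stack$channels, function(x) x * 7.3),
                        sc$stack$pixel_size_um)
  expect_equal(jc1_ratio(scaled)$red_green_ratio,
               jc1_ratio(sc$stack)$red_green_ratio, tolerance = 1e-10)

  # monotone dose-response over generated ratios
  got <- vapply(c(0.5, 1, 2, 4), function(r)
    jc1_ratio(make_jc1_scene(r, seed = 11)$stack)$red_green_ratio,
    numeric(1))
  expect_true(all(diff(got) > 0))

  expect_error(jc1_ratio(image_stack(list(jc1_red = matrix(1, 16, 16),
                                          jc1_green = matrix(1, 16, 16)),
                                     0.721)),
               "flat")
})
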