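test_that("orientation field recovers axis-aligned stripe directions", {
  f <- orientation_field(stripes_x())
  strong <- f$weight > quantile(f$weight, 0.9)
  expect_lt(axial_diff(axial_mean(f$angle[strong]), 0), 1)

  f90 <- orientation_field(t(stripes_x()))
  strong <- f90$weight > quantile(f90$weight, 0.9)
  expect_lt(axial_diff(axial_mean(f90$angle[strong]), 90), 1)

  # constant image: all weights zero, no orientation signal
  fc <- orientation_field(matrix(1, 16, 16))
  expect_true(all(fc$weight == 0))
  expect_error(orientation_field(matrix(1, 2, 2)))
})

test_that("fixed-angle fiber scenes give the modal angle within 2 degrees", {
  sc <- make_fiber_scene(150, list(kind = "fixed", theta = 30), seed = 2)
  f <- orientation_field(sc$stack$channels$actin[, , 1])
  mode <- stretchquant:::histogram_mode(as.numeric(f$angle),
                                        as.numeric(f$weight))
  expect_lt(axial_diff(mode, 30), 2)
})

test_that("grid main orientations handle homogeneous, blank and split fields", {
  sc <- make_fiber_scene(400, list(kind = "fixed", theta = 60),
                         fiber_length = 60, seed = 3)
  f <- orientation_field(sc$stack$channels$actin[, , 1])
  main <- grid_main_orientations(f, c(5, 3))
  expect_length(main, 15)
  expect_true(all(axial_diff(main, 60) <= 1.5))

  blank <- orientation_field(matrix(0, 60, 100))
  expect_length(grid_main_orientations(blank, c(5, 3)), 0)

  # two-region image: left half at 10 deg, right half at 80 deg
  l <- make_fiber_scene(200, list(kind = "fixed", theta = 10),
                        image_shape = c(120, 120), seed = 4)
  r <- make_fiber_scene(200, list(kind = "fixed", theta = 80),
                        image_shape = c(120, 120), seed = 5)
  img <- cbind(l$stack$channels$actin[, , 1], r$stack$channels$actin[, , 1])
  main <- grid_main_orientations(orientation_field(img), c(2, 1))
  expect_length(main, 2)
  expect_lt(axial_diff(main[1], 10), 2)
  expect_lt(axial_diff(main[2], 80), 2)
})

test_that("folding returns the acute angle to the stretch axis", {
  expect_equal(fold_to_stretch(0), 0)
  expect_equal(fold_to_stretch(135), 45)
  expect_equal(fold_to_stretch(170), 10)
  expect_equal(fold_to_stretch(90), 90)
  expect_equal(fold_to_stretch(0, "y"), 90)
  expect_equal(fold_to_stretch(135, "y"), 45)
  expect_error(fold_to_stretch(10, "z"))
  a <- runif(100, 0, 180)
  expect_true(all(fold_to_stretch(a) >= 0 & fold_to_stretch(a) <= 90))
})

test_that("cumulative distributions are proper ECDFs on [0, 90]", {
  d <- cumulative_distribution(c(45, 45))
  expect_equal(d$mean_angle, 45)
  expect_equal(d$cumulative(44.9), 0)
  expect_equal(d$cumulative(45), 1)

  set.seed(6)
  u <- runif(1e4, 0, 90)
  d <- cumulative_distribution(u)
  grid <- seq(0, 90, by = 0.5)
  expect_lt(max(abs(d$cumulative(grid) - grid / 90)), 0.02)
  expect_equal(d$cumulative(90), 1)
  expect_true(all(diff(d$cumulative(grid)) >= 0))

  expect_error(cumulative_distribution(numeric(0)), "empty")
  expect_error(cumulative_distribution(c(45, 120)))
})

test_that("recovered orientations shift with the scene orientation", {
  # rotation equivariance: the same scene geometry at theta and theta + 25
  # shifts every recovered square orientation by 25 degrees
  base <- make_fiber_scene(300, list(kind = "fixed", theta = 40),
                           fiber_length = 60, seed = 7)
  rot <- make_fiber_scene(300, list(kind = "fixed", theta = 65),
                          fiber_length = 60, seed = 7)
  m1 <- grid_main_orientations(
    orientation_field(base$stack$channels$actin[, , 1]), c(5, 3))
  m2 <- grid_main_orientations(
    orientation_field(rot$stack$channels$actin[, , 1]), c(5, 3))
  expect_true(all(axial_diff(m2 - m1, 25) <= 2))
})

test_that("von Mises orientation scenes recover the concentration centre", {
  recovered <- unlist(lapply(1:20, function(s) {
    sc <- make_fiber_scene(200,
                           list(kind = "von_mises", mu = 75, kappa = 8),
                           seed = 100 + s)
    grid_main_orientations(
      orientation_field(sc$stack$channels$actin[, , 1]), c(5, 3))
  }))
  expect_lt(axial_diff(axial_mean(recovered), 75), 3)
})
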