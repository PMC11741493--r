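test_that("preprocessing maps any non-constant image onto [-1, 1] exactly", {
  set.seed(3)
  x <- array(rnorm(500), c(10, 10, 5))
  out <- preprocess_intensity(x)
  expect_equal(min(out), -1)
  expect_equal(max(out), 1)
  expect_identical(dim(out), dim(x))
  expect_true(all(preprocess_intensity(array(7, c(4, 4, 2))) == 0))
})

test_that("percentile clipping caps outliers at the original P99.75", {
  set.seed(8)
  x <- array(runif(1000), c(10, 10, 10))
  x[1] <- 100  # one extreme outlier
  hi <- quantile(x, 0.9975, type = 7, names = FALSE)
  out <- preprocess_intensity(x)
  # the outlier and every value clipped with it share the maximum output
  expect_equal(out[1], max(out))
  expect_true(all(out[x >= hi] == max(out)))
  # the clip bound is a percentile of the original, far below the outlier
  expect_lt(hi, 2)
})

test_that("the final [-1,1] map is idempotent when clipping is disabled", {
  set.seed(9)
  x <- array(rnorm(200), c(10, 5, 4))
  once <- preprocess_intensity(x, lo_pct = 0, hi_pct = 100)
  twice <- preprocess_intensity(once, lo_pct = 0, hi_pct = 100)
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("calibration windows are ordered and the result deterministic", {
  ph <- shared_phantom()
  img <- synthesize_image(ph$maps, acquisition_params(1535, 212))
  cal1 <- calibrate_segmenter(img, ph$labels, default_structure_ids(),
                              spacing = ph$spec$spacing)
  cal2 <- calibrate_segmenter(img, ph$labels, default_structure_ids(),
                              spacing = ph$spec$spacing)
  expect_identical(cal1, cal2)
  for (s in cal1$structures) expect_lte(s$window[1], s$window[2])
  expect_error(calibrate_segmenter(img, array(0L, dim(img)),
                                   c(missing = 9L), spacing = ph$spec$spacing),
               "empty truth")
})

test_that("segmenting the calibration image recovers each structure well", {
  ph <- shared_phantom()
  img <- synthesize_image(ph$maps, acquisition_params(1535, 212))
  cal <- calibrate_segmenter(img, ph$labels, default_structure_ids(),
                             spacing = ph$spec$spacing)
  seg <- intensity_window_segmenter(cal)
  pred <- seg(img, ph$spec$spacing)
  for (lab in default_structure_ids())
    expect_gte(dice(pred == lab, ph$labels == lab), 0.9)
})

test_that("an unbounded window with a whole-volume prior keeps the largest component", {
  d <- c(10, 10, 4)
  img <- array(0, d)
  img[2:4, 2:4, 1:2] <- 1   # large bright blob (18 voxels)
  img[8:9, 8, 4] <- 1       # small separate blob (2 voxels)
  cal <- structure(list(structures = list(
    blob = list(label = 1L, window = c(-Inf, Inf),
                centroid = c(5, 5, 2.5), radii = c(100, 100, 100))),
    spacing = c(1, 1, 1)), class = "segmenter_calibration")
  pred <- intensity_window_segmenter(cal)(img, c(1, 1, 1))
  # foreground here is every voxel (window unbounded), so the largest
  # 6-connected component is the full volume grid
  expect_true(all(pred == 1L))
})

test_that("segmenter contract checking flags violations", {
  ph <- shared_phantom()
  expect_true(check_segmenter(oracle_segmenter(array(0L, c(8, 8, 4))), 1:4))
  expect_true(check_segmenter(empty_segmenter(), 1:4))
  bad_shape <- function(image, spacing) array(0L, c(2, 2, 2))
  expect_error(check_segmenter(bad_shape, 1:4), "dim")
  bad_label <- function(image, spacing) array(9L, dim(image))
  expect_error(check_segmenter(bad_label, 1:4), "undeclared")
  flaky <- local({
    n <- 0L
    function(image, spacing) {
      n <<- n + 1L
      array(as.integer(n %% 2), dim(image))
    }
  })
  expect_error(check_segmenter(flaky, 1L), "deterministic")
})
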