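test_that("spin-echo signal equation hits its analytic limits", {
  m <- voxel_maps(t1 = 1000, t2 = 100, pd = 1)
  # full recovery, no decay
  expect_equal(as.numeric(synthesize_image(m, acquisition_params(1e9, 0))), 1)
  # TE equal to T2 decays by e^-1
  expect_equal(as.numeric(synthesize_image(m, acquisition_params(1e9, 100))),
               exp(-1))
  # TR equal to T1 recovers to 1 - e^-1
  expect_equal(as.numeric(synthesize_image(m, acquisition_params(1000, 0))),
               1 - exp(-1))
})

test_that("background voxels and invalid params are handled", {
  t1 <- array(c(1000, 0), c(2, 1, 1))
  t2 <- array(c(100, 0), c(2, 1, 1))
  pd <- array(c(1, 5), c(2, 1, 1))  # PD without T1 is still background
  m <- quantitative_maps(t1, t2, pd, spacing = c(1, 1, 1))
  s <- synthesize_image(m, acquisition_params(2000, 30))
  expect_identical(as.numeric(s[2, 1, 1]), 0)
  expect_error(acquisition_params(tr = 100, te = 100), "TE")
  expect_error(
    quantitative_maps(t1, array(0, c(3, 1, 1)), pd, spacing = c(1, 1, 1)),
    "t2")
  expect_warning(
    quantitative_maps(array(100, c(1, 1, 1)), array(200, c(1, 1, 1)),
                      array(1, c(1, 1, 1)), spacing = c(1, 1, 1)),
    "T2 > T1")
})

test_that("signal is monotone decreasing in TE and increasing in TR", {
  set.seed(31)
  dims <- c(6, 6, 3)
  m <- quantitative_maps(array(runif(prod(dims), 200, 2000), dims),
                         array(runif(prod(dims), 20, 180), dims),
                         array(runif(prod(dims), 10, 100), dims),
                         spacing = c(1, 1, 2))
  for (k in 1:20) {
    tr <- runif(1, 300, 6000)
    te <- sort(runif(2, 5, min(250, tr - 1)))
    s_lo <- synthesize_image(m, acquisition_params(tr, te[1]))
    s_hi <- synthesize_image(m, acquisition_params(tr, te[2]))
    expect_true(all(s_hi <= s_lo + 1e-12))
    trs <- sort(runif(2, 300, 6000))
    s_short <- synthesize_image(m, acquisition_params(trs[1], te[1]))
    s_long <- synthesize_image(m, acquisition_params(trs[2], te[1]))
    expect_true(all(s_long >= s_short - 1e-12))
  }
})

test_that("TE=0 with TR of 50 max T1 recovers gain * b1 * PD", {
  set.seed(5)
  dims <- c(5, 4, 3)
  t1 <- array(runif(prod(dims), 300, 1800), dims)
  m <- quantitative_maps(t1, array(runif(prod(dims), 30, 150), dims),
                         array(runif(prod(dims), 5, 90), dims),
                         spacing = c(1, 1, 1))
  m <- apply_b1_bias(m, amplitude = 0.15, seed = 3)
  s <- synthesize_image(m, acquisition_params(50 * max(t1), 0), gain = 2.5)
  expect_equal(as.numeric(s), as.numeric(2.5 * m$b1 * m$pd), tolerance = 1e-8)
})

test_that("signal is exactly linear in gain and in PD", {
  ph <- shared_phantom()
  p <- acquisition_params(1500, 80)
  s1 <- synthesize_image(ph$maps, p, gain = 1)
  s2 <- synthesize_image(ph$maps, p, gain = 2)
  expect_identical(as.numeric(s2), as.numeric(2 * s1))
  m2 <- ph$maps
  m2$pd <- 2 * m2$pd
  expect_identical(as.numeric(synthesize_image(m2, p)), as.numeric(2 * s1))
})

test_that("output geometry matches the input maps at every grid point", {
  ph <- shared_phantom()
  for (pt in list(c(100, 5), c(1000, 40), c(5000, 200))) {
    s <- synthesize_image(ph$maps, acquisition_params(pt[1], pt[2]))
    expect_identical(dim(s), dim(ph$maps$t1))
    expect_identical(attr(s, "spacing"), ph$maps$spacing)
  }
})

test_that("inversion recovery nulls at TI = T1 log(2) and matches arithmetic", {
  m <- voxel_maps(t1 = 1000, t2 = 100, pd = 1)
  s <- synthesize_ir_image(m, acquisition_params(1e9, 0, ti = 1000 * log(2)))
  expect_equal(as.numeric(s), 0, tolerance = 1e-9)
  # direct scalar evaluation of the IR signal, frozen from arithmetic:
  # |2 * (1 - 2 e^{-200/1000} + e^{-4000/1000}) * e^{-50/100}| = 0.7510619
  m2 <- voxel_maps(t1 = 1000, t2 = 100, pd = 2)
  s2 <- synthesize_ir_image(m2, acquisition_params(4000, 50, ti = 200))
  expect_equal(as.numeric(s2),
               abs(2 * (1 - 2 * exp(-0.2) + exp(-4)) * exp(-0.5)))
  expect_equal(as.numeric(s2), 0.7510619, tolerance = 1e-6)
  expect_error(synthesize_ir_image(m2, acquisition_params(4000, 50)), "ti")
})

test_that("12-bit quantization spans 0..4095 and is monotone", {
  set.seed(2)
  x <- array(rnorm(64), c(4, 4, 4))
  q <- quantize_12bit(x)
  expect_identical(range(q), c(0L, 4095L))
  expect_true(all(diff(q[order(x)]) >= 0))
  expect_true(all(quantize_12bit(array(3, c(2, 2, 2))) == 0L))
})
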