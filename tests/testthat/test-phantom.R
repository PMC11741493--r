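one_structure_spec <- function(noise = c(t1 = 0, t2 = 0, pd = 0),
                               radii = c(10, 10, 10), shape = c(40, 40, 40),
                               spacing = c(1, 1, 1)) {
  phantom_spec(
    shape = shape, spacing = spacing,
    structures = data.frame(name = "blob", label = 1L, tissue = "parotid",
                            cx = 0, cy = 0, cz = 0,
                            rx = radii[1], ry = radii[2], rz = radii[3]),
    head_radii = c(18, 18, 18), noise_sigma = noise)
}

test_that("noiseless phantom carries exact tissue values inside structures", {
  ph <- build_phantom(one_structure_spec(), seed = 1)
  tt <- default_tissue_table()
  inside <- ph$labels == 1L
  expect_true(any(inside))
  expect_true(all(ph$maps$t1[inside] == tt$t1[tt$tissue == "parotid"]))
  expect_true(all(ph$maps$t2[inside] == tt$t2[tt$tissue == "parotid"]))
  expect_true(all(ph$maps$pd[inside] == tt$pd[tt$tissue == "parotid"]))
  # outside the head everything is exactly background
  outside <- ph$maps$pd == 0
  expect_true(all(ph$maps$t1[outside] == 0))
})

test_that("noise changes maps between seeds but never the labels", {
  spec <- one_structure_spec(noise = c(t1 = 30, t2 = 5, pd = 2))
  a <- build_phantom(spec, seed = 1)
  b <- build_phantom(spec, seed = 2)
  expect_false(identical(a$maps$t1, b$maps$t1))
  expect_identical(a$labels, b$labels)
  # and full determinism for one seed
  a2 <- build_phantom(spec, seed = 1)
  expect_identical(a$maps, a2$maps)
})

test_that("labelled ellipsoid volume matches the analytic volume within 5%", {
  ph <- build_phantom(one_structure_spec(), seed = 1)
  count <- sum(ph$labels == 1L)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(count - analytic) / analytic, 0.05)
})

test_that("overlapping structures are rejected naming the pair", {
  bad <- data.frame(name = c("a", "b"), label = 1:2,
                    tissue = "parotid",
                    cx = c(0, 4), cy = 0, cz = 0, rx = 6, ry = 6, rz = 6)
  spec <- phantom_spec(shape = c(40, 40, 40), spacing = c(1, 1, 1),
                       structures = bad, head_radii = c(15, 15, 15),
                       noise_sigma = c(t1 = 0, t2 = 0, pd = 0))
  expect_error(build_phantom(spec, seed = 1), "'a' and 'b'")
})

test_that("unperturbed bilateral labels are mirror-symmetric", {
  ph <- shared_phantom()
  flipped <- ph$labels[rev(seq_len(dim(ph$labels)[1])), , ]
  swap <- c(2L, 1L, 4L, 3L)  # left <-> right partners
  remapped <- array(0L, dim(flipped))
  for (k in 1:4) remapped[flipped == k] <- swap[k]
  expect_identical(remapped, ph$labels)
})

test_that("zero perturbation reproduces the truth for every rater", {
  ph <- shared_phantom()
  st <- simulate_raters(ph$labels, 1L, n_raters = 3, perturbation_mm = 0,
                        seed = 9, spacing = ph$spec$spacing)
  for (m in st$masks) expect_identical(m, ph$labels == 1L)
})

test_that("perturbed raters stay close to truth, connected, and deterministic", {
  ph <- shared_phantom()
  st <- simulate_raters(ph$labels, 1L, n_raters = 3, perturbation_mm = 1,
                        seed = 7, spacing = ph$spec$spacing)
  truth <- ph$labels == 1L
  for (m in st$masks) {
    expect_gt(dice(m, truth), 0.7)
    lab <- synthsweep:::cpp_label_components(m, dim(m))
    expect_identical(max(lab), 1L)  # one connected component
  }
  st2 <- simulate_raters(ph$labels, 1L, n_raters = 3, perturbation_mm = 1,
                         seed = 7, spacing = ph$spec$spacing)
  expect_identical(st$masks, st2$masks)
})

test_that("B1 bias field honours amplitude bounds and lateral asymmetry", {
  ph <- shared_phantom()
  m0 <- apply_b1_bias(ph$maps, 0, seed = 3)
  expect_true(all(m0$b1 == 1))
  m <- apply_b1_bias(ph$maps, 0.2, seed = 3)
  expect_gte(min(m$b1), 0.8)
  expect_lte(max(m$b1), 1.2)
  flipped <- m$b1[rev(seq_len(dim(m$b1)[1])), , ]
  expect_false(isTRUE(all.equal(flipped, m$b1)))
})
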