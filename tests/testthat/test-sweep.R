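tiny_grid <- function() {
  sweep_grid(tr_values = c(1000, 2000), te_values = c(20, 100),
             anchor = acquisition_params(1535, 212))
}

test_that("contrast regions follow the TR/TE inequalities", {
  expect_identical(classify_region(5254, 145), "T2W")
  expect_identical(classify_region(1000, 40), "PDW")   # boundary case
  expect_identical(classify_region(900, 60), "MIXED")
  expect_identical(classify_region(999, 40), "T1W")
  expect_identical(classify_region(1000, 40.5), "T2W")
  expect_error(classify_region(0, 10))
})

test_that("the default grid yields 216 points, 72 per used region", {
  g <- build_grid(sweep_grid())
  expect_equal(nrow(g), 216)
  expect_equal(unname(table(g$region)[c("T1W", "T2W", "PDW")]),
               c(72L, 72L, 72L), ignore_attr = TRUE)
  g_all <- build_grid(sweep_grid(include_mixed = TRUE))
  expect_equal(nrow(g_all), 18 * 16)
  # deterministic TR-major ordering
  expect_true(!is.unsorted(g$tr))
  expect_identical(g, build_grid(sweep_grid()))
})

test_that("grid validation rejects bad axes and impossible points", {
  expect_error(sweep_grid(tr_values = numeric(0)), "empty")
  expect_error(sweep_grid(tr_values = c(200, 100)), "increasing")
  # enumeration is unconstrained, but a TE >= TR point cannot be synthesized
  pts <- build_grid(sweep_grid(tr_values = c(30), te_values = c(5, 35),
                               include_mixed = TRUE))
  expect_equal(nrow(pts), 2)
  expect_error(check_grid_feasible(pts), "TR=30.*TE=35")
  ph <- shared_phantom()
  expect_error(
    run_sweep(ph$maps, empty_segmenter(),
              sweep_grid(tr_values = c(30), te_values = c(5, 35)),
              ph$labels, default_structure_ids()),
    "TE < TR")
  # a TE >= TR combination confined to the excluded mixed region is fine
  g <- build_grid(sweep_grid(tr_values = c(100), te_values = c(5, 200)))
  expect_equal(nrow(g), 1)
  expect_silent(check_grid_feasible(g))
})

test_that("an oracle segmenter scores perfectly at every grid point", {
  ph <- shared_phantom()
  rec <- run_sweep(ph$maps, oracle_segmenter(ph$labels), tiny_grid(),
                   ph$labels, default_structure_ids())
  expect_equal(nrow(rec), 4 * 4)
  expect_true(all(rec$dsc == 1))
  expect_true(all(rec$hd95 == 0))
  expect_true(all(rec$hd95_defined))
})

test_that("degenerate and crashing segmenters become failure sentinels", {
  ph <- shared_phantom()
  rec <- run_sweep(ph$maps, empty_segmenter(), tiny_grid(),
                   ph$labels, default_structure_ids())
  expect_true(all(rec$dsc == 0))
  expect_true(all(!rec$hd95_defined))
  crashy <- function(image, spacing) stop("boom")
  rec2 <- run_sweep(ph$maps, crashy, tiny_grid(), ph$labels,
                    default_structure_ids())
  expect_equal(nrow(rec2), 16)
  expect_true(all(grepl("boom", rec2$failure)))
  misaligned <- function(image, spacing) array(0L, c(2, 2, 2))
  rec3 <- run_sweep(ph$maps, misaligned, tiny_grid(), ph$labels,
                    default_structure_ids())
  expect_true(all(grepl("misaligned", rec3$failure)))
})

test_that("sweeps are deterministic and account for every grid point", {
  ph <- shared_phantom()
  img <- synthesize_image(ph$maps, acquisition_params(1535, 212))
  cal <- calibrate_segmenter(img, ph$labels, default_structure_ids(),
                             spacing = ph$spec$spacing)
  seg <- intensity_window_segmenter(cal)
  a <- run_sweep(ph$maps, seg, tiny_grid(), ph$labels, default_structure_ids())
  b <- run_sweep(ph$maps, seg, tiny_grid(), ph$labels, default_structure_ids())
  expect_identical(a, b)
  expect_equal(nrow(a), nrow(build_grid(tiny_grid())) * 4)
})

test_that("region summaries aggregate correctly, excluding undefined HD95", {
  rec <- data.frame(
    structure = "s1", tr = c(1500, 2000, 3000), te = 100, region = "T2W",
    dsc = c(0.8, 0.9, 0.7), hd95 = c(2, 4, NA),
    hd95_defined = c(TRUE, TRUE, FALSE), failure = NA_character_,
    delta_tr = 0, delta_te = 0)
  s <- summarize_regions(rec)
  expect_equal(s$dsc_mean, 0.8)
  expect_equal(s$dsc_median, 0.8)
  expect_equal(s$dsc_min, 0.7)
  expect_equal(s$dsc_max, 0.9)
  expect_equal(s$hd95_mean, 3)
  expect_equal(s$n_hd95_undefined, 1)
  expect_equal(s$n, 3)
  s_mean <- summarize_regions(rec, statistic = "mean")
  expect_false("dsc_median" %in% names(s_mean))
})

test_that("IOV exceedance counts better-than-threshold fractions inclusively", {
  thr <- iov_thresholds(dsc_cutoff = c(s1 = 0.8), hd95_cutoff = c(s1 = 3))
  rec <- data.frame(
    structure = "s1", tr = seq(1500, 2400, by = 100), te = 100,
    region = "T2W",
    dsc = c(0.85, 0.9, 0.8, 0.95, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2),
    hd95 = c(1, 2, 3, 4, 5, 6, 7, 8, NA, NA),
    hd95_defined = c(rep(TRUE, 8), FALSE, FALSE),
    failure = NA_character_, delta_tr = 0, delta_te = 0)
  ex <- iov_exceedance(rec, thr)
  all_row <- ex[ex$region == "ALL", ]
  expect_equal(all_row$dsc_exceedance, 0.4)    # 4 of 10 at or above 0.8
  expect_equal(all_row$hd95_exceedance, 0.3)   # 3 of 10 at or below 3 mm
  # bound thresholds
  loose <- iov_thresholds(dsc_cutoff = c(s1 = 1e-9), hd95_cutoff = c(s1 = 1e9))
  expect_true(all(iov_exceedance(rec, loose)$dsc_exceedance == 1))
  expect_error(iov_exceedance(transform(rec, structure = "s2"), thr), "s2")
})

test_that("relative offsets subtract the anchor acquisition", {
  rec <- data.frame(structure = "s1", tr = c(1535, 1500, 5000),
                    te = c(212, 200, 5), region = "T2W", dsc = 1,
                    hd95 = 0, hd95_defined = TRUE, failure = NA_character_)
  out <- relative_offsets(rec, acquisition_params(1535, 212))
  expect_equal(out$delta_tr, c(0, -35, 3465))
  expect_equal(out$delta_te, c(0, -12, -207))
})
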