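#' Contrast-region classification of a (TR, TE) point
#'
#' Partition of acquisition-parameter space into weighting regions:
#' * `T1W`: TR < 1000 ms and TE <= 40 ms
#' * `T2W`: TR >= 1000 ms and TE > 40 ms
#' * `PDW`: TR >= 1000 ms and TE <= 40 ms
#' * `MIXED`: TR < 1000 ms and TE > 40 ms (rarely used clinically and
#'   excluded from sweeps by default)
#'
#' @param tr,te repetition and echo times in ms (vectorized).
#' @return character vector of region codes.
#' @examples
#' classify_region(5254, 145)  # "T2W"
#' classify_region(1000, 40)   # "PDW" (boundary case)
#' classify_region(900, 60)    # "MIXED"
#' @export
classify_region <- function(tr, te) {
  if (any(tr <= 0) || any(te < 0)) stop("need tr > 0 and te >= 0", call. = FALSE)
  ifelse(tr < 1000,
         ifelse(te <= 40, "T1W", "MIXED"),
         ifelse(te > 40, "T2W", "PDW"))
}

#' Default sweep TR and TE values
#'
#' The 18-point TR list (100..1000 ms by 100, then 1500..5000 by 500) and the
#' 16-point TE list (5..40 ms by 5, then 60..200 by 20). With the mixed region
#' excluded these yield 216 grid points, 72 per used region.
#'
#' @return numeric vector of ms values.
#' @export
default_tr_values <- function() c(seq(100, 1000, by = 100), seq(1500, 5000, by = 500))

#' @rdname default_tr_values
#' @export
default_te_values <- function() c(seq(5, 40, by = 5), seq(60, 200, by = 20))

#' Sweep grid definition
#'
#' @param tr_values,te_values strictly increasing positive ms values.
#' @param include_mixed keep mixed-region grid points (default `FALSE`).
#' @param anchor [acquisition_params] the deltas are reported against: the
#'   acquisition the segmentation model was calibrated or trained at
#'   (default TR = 1535 ms, TE = 212 ms).
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(tr_values = default_tr_values(),
                       te_values = default_te_values(),
                       include_mixed = FALSE,
                       anchor = acquisition_params(1535, 212)) {
  check_axis <- function(v, nm) {
    if (length(v) == 0) stop("`", nm, "` is empty", call. = FALSE)
    if (any(v <= 0) || is.unsorted(v, strictly = TRUE))
      stop("`", nm, "` must be strictly increasing positive ms values",
           call. = FALSE)
  }
  check_axis(tr_values, "tr_values")
  check_axis(te_values, "te_values")
  stopifnot(inherits(anchor, "acquisition_params"))
  structure(list(tr_values = as.numeric(tr_values),
                 te_values = as.numeric(te_values),
                 include_mixed = isTRUE(include_mixed), anchor = anchor),
            class = "sweep_grid")
}

#' Enumerate the grid points of a sweep
#'
#' Cartesian product of the TR and TE lists in deterministic TR-major order,
#' classified into contrast regions, with mixed-region points dropped unless
#' `include_mixed` is set. Enumeration itself places no TE < TR constraint;
#' points that would actually be synthesized are checked by [run_sweep()]
#' (and by config validation) via [check_grid_feasible()].
#'
#' @param grid a [sweep_grid].
#' @return data.frame with columns `tr`, `te`, `region`.
#' @export
build_grid <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  pts <- expand.grid(te = grid$te_values, tr = grid$tr_values,
                     KEEP.OUT.ATTRS = FALSE)[, c("tr", "te")]
  pts$region <- classify_region(pts$tr, pts$te)
  if (!grid$include_mixed) pts <- pts[pts$region != "MIXED", , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Check that every grid point to be synthesized satisfies TE < TR
#'
#' The echo cannot outlast the repetition interval; a grid point violating
#' this can be enumerated (e.g. in the excluded mixed region) but never
#' synthesized.
#'
#' @param pts data.frame from [build_grid()].
#' @return `pts` invisibly; error naming the first offending point otherwise.
#' @export
check_grid_feasible <- function(pts) {
  bad <- pts$te >= pts$tr
  if (any(bad)) {
    i <- which(bad)[1]
    stop("grid point TR=", pts$tr[i], " ms, TE=", pts$te[i],
         " ms violates TE < TR", call. = FALSE)
  }
  invisible(pts)
}

#' Run the segmentation sensitivity sweep
#'
#' For every grid point: synthesize the contrast-weighted image, run the
#' segmenter, and score each structure against its ground-truth mask with
#' DSC and HD95. Segmenter exceptions, misaligned outputs and empty
#' predictions never abort the sweep; they are recorded as failure sentinels
#' (DSC 0, HD95 undefined) so the grid stays rectangular.
#'
#' @param maps a [quantitative_maps] object.
#' @param segmenter function `(image, spacing) -> integer label volume`.
#' @param grid a [sweep_grid].
#' @param truth_labels integer label volume of consensus ground truth.
#' @param structures named integer vector mapping structure id to label.
#' @param gain scanner gain passed to [synthesize_image()].
#' @param verbose log one line per grid point.
#' @return data.frame of metric records with columns `structure`, `tr`, `te`,
#'   `region`, `dsc`, `hd95`, `hd95_defined`, `delta_tr`, `delta_te`,
#'   `failure` (NA or a reason string).
#' @export
run_sweep <- function(maps, segmenter, grid, truth_labels, structures,
                      gain = 1, verbose = FALSE) {
  stopifnot(inherits(maps, "quantitative_maps"), inherits(grid, "sweep_grid"))
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("`structures` must be a named integer vector", call. = FALSE)
  pts <- check_grid_feasible(build_grid(grid))
  truths <- lapply(structures, function(lab) truth_labels == lab)
  rows <- vector("list", nrow(pts) * length(structures))
  r <- 0L
  for (i in seq_len(nrow(pts))) {
    tr <- pts$tr[i]; te <- pts$te[i]
    img <- synthesize_image(maps, acquisition_params(tr, te), gain = gain)
    pred <- tryCatch(segmenter(img, maps$spacing), error = function(e) e)
    fail_all <- NULL
    if (inherits(pred, "error")) {
      fail_all <- paste0("segmenter error: ", conditionMessage(pred))
    } else if (!identical(dim(pred), dim(truth_labels))) {
      fail_all <- "segmenter returned misaligned output"
    }
    if (verbose)
      message(sprintf("[sweep %3d/%d] TR=%g TE=%g (%s)%s", i, nrow(pts), tr, te,
                      pts$region[i], if (is.null(fail_all)) "" else " FAILED"))
    for (nm in names(structures)) {
      r <- r + 1L
      if (!is.null(fail_all)) {
        rows[[r]] <- data.frame(structure = nm, tr = tr, te = te,
                                region = pts$region[i], dsc = 0,
                                hd95 = NA_real_, hd95_defined = FALSE,
                                failure = fail_all)
        next
      }
      mp <- metric_pair(pred == structures[[nm]], truths[[nm]], maps$spacing)
      rows[[r]] <- data.frame(structure = nm, tr = tr, te = te,
                              region = pts$region[i], dsc = mp$dsc,
                              hd95 = mp$hd95, hd95_defined = mp$hd95_defined,
                              failure = if (mp$hd95_defined) NA_character_
                                        else "empty or disjoint prediction")
    }
  }
  records <- do.call(rbind, rows)
  relative_offsets(records, grid$anchor)
}

#' Populate relative TR/TE offsets from the anchor acquisition
#'
#' `delta_tr = tr - anchor$tr`, `delta_te = te - anchor$te` (ms); the anchor
#' is the acquisition closest to the segmentation model's training contrast.
#'
#' @param records metric records from [run_sweep()].
#' @param anchor an [acquisition_params].
#' @return `records` with `delta_tr`, `delta_te` columns set.
#' @export
relative_offsets <- function(records, anchor) {
  stopifnot(inherits(anchor, "acquisition_params"))
  records$delta_tr <- records$tr - anchor$tr
  records$delta_te <- records$te - anchor$te
  records
}

#' Per-region summary statistics
#'
#' Mean, median, minimum and maximum of DSC and HD95 for every structure and
#' contrast region, with grid-point counts. Undefined HD95 values are
#' excluded from the HD95 statistics and counted separately.
#'
#' @param records metric records from [run_sweep()].
#' @param statistic `"mean"`, `"median"` or `"both"` — which central
#'   statistic columns to report alongside min/max.
#' @return data.frame with one row per structure x region.
#' @export
summarize_regions <- function(records, statistic = c("both", "mean", "median")) {
  statistic <- match.arg(statistic)
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  groups <- unique(records[, c("structure", "region")])
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    g <- records[records$structure == groups$structure[k] &
                   records$region == groups$region[k], ]
    h <- g$hd95[g$hd95_defined]
    row <- data.frame(structure = groups$structure[k],
                      region = groups$region[k], n = nrow(g),
                      dsc_mean = mean(g$dsc), dsc_median = median(g$dsc),
                      dsc_min = min(g$dsc), dsc_max = max(g$dsc),
                      hd95_mean = if (length(h)) mean(h) else NA_real_,
                      hd95_median = if (length(h)) median(h) else NA_real_,
                      hd95_min = if (length(h)) min(h) else NA_real_,
                      hd95_max = if (length(h)) max(h) else NA_real_,
                      n_hd95_undefined = sum(!g$hd95_defined))
    row
  })
  out <- do.call(rbind, rows)
  if (statistic == "mean")
    out <- out[, setdiff(names(out), c("dsc_median", "hd95_median"))]
  if (statistic == "median")
    out <- out[, setdiff(names(out), c("dsc_mean", "hd95_mean"))]
  out[order(out$structure, out$region), , drop = FALSE]
}

#' Interobserver-variability thresholds
#'
#' Per-structure DSC and HD95 cutoffs marking the level of human
#' interobserver agreement; automated results at least this good are
#' clinically interchangeable with a human contour. Defaults: DSC
#' 0.83 / 0.84 / 0.75 / 0.78 and HD95 4.9 / 5.1 / 3.1 / 3.1 mm for left
#' parotid / right parotid / left submandibular / right submandibular.
#'
#' @param dsc_cutoff,hd95_cutoff named numeric vectors (one entry per
#'   structure; DSC cutoffs in (0, 1], HD95 cutoffs in mm > 0).
#' @return An object of class `iov_thresholds`.
#' @export
iov_thresholds <- function(
    dsc_cutoff = c(parotid_l = 0.83, parotid_r = 0.84,
                   submandibular_l = 0.75, submandibular_r = 0.78),
    hd95_cutoff = c(parotid_l = 4.9, parotid_r = 5.1,
                    submandibular_l = 3.1, submandibular_r = 3.1)) {
  if (!identical(sort(names(dsc_cutoff)), sort(names(hd95_cutoff))))
    stop("dsc_cutoff and hd95_cutoff must cover the same structures",
         call. = FALSE)
  if (any(dsc_cutoff <= 0) || any(dsc_cutoff > 1))
    stop("DSC cutoffs must lie in (0, 1]", call. = FALSE)
  if (any(hd95_cutoff <= 0))
    stop("HD95 cutoffs must be positive mm", call. = FALSE)
  structure(list(dsc_cutoff = dsc_cutoff, hd95_cutoff = hd95_cutoff),
            class = "iov_thresholds")
}

#' IOV exceedance fractions
#'
#' Fraction of grid points at which the segmenter performs at least as well
#' as human interobserver variability: DSC >= the structure's DSC cutoff
#' (inclusive), and HD95 defined and <= the structure's HD95 cutoff
#' (inclusive; undefined HD95 never exceeds). Reported per structure overall
#' (`region = "ALL"`) and restricted to each contrast region.
#'
#' @param records metric records from [run_sweep()].
#' @param thresholds an [iov_thresholds].
#' @return data.frame with columns `structure`, `region`, `n`,
#'   `dsc_exceedance`, `hd95_exceedance` (fractions in `[0, 1]`).
#' @export
iov_exceedance <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "iov_thresholds"))
  missing <- setdiff(unique(records$structure), names(thresholds$dsc_cutoff))
  if (length(missing))
    stop("no IOV threshold for structure(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  one <- function(g, structure, region) {
    dc <- thresholds$dsc_cutoff[[structure]]
    hc <- thresholds$hd95_cutoff[[structure]]
    data.frame(structure = structure, region = region, n = nrow(g),
               dsc_exceedance = mean(g$dsc >= dc),
               hd95_exceedance = mean(g$hd95_defined & !is.na(g$hd95) &
                                        g$hd95 <= hc))
  }
  rows <- list()
  for (s in unique(records$structure)) {
    gs <- records[records$structure == s, ]
    rows[[length(rows) + 1L]] <- one(gs, s, "ALL")
    for (rg in unique(gs$region))
      rows[[length(rows) + 1L]] <- one(gs[gs$region == rg, ], s, rg)
  }
  do.call(rbind, rows)
}

#' Heatmap of a sweep metric over the TR/TE grid
#'
#' One tile per grid point (TE on x, TR on y), faceted by structure, with the
#' anchor acquisition marked. Undefined HD95 tiles are left blank.
#'
#' @param records metric records from [run_sweep()].
#' @param metric `"dsc"` or `"hd95"`.
#' @param anchor optional [acquisition_params] to mark.
#' @return A ggplot object.
#' @export
plot_sweep <- function(records, metric = c("dsc", "hd95"), anchor = NULL) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep requires ggplot2", call. = FALSE)
  df <- records
  df$value <- df[[metric]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$te),
                                        y = factor(.data$tr),
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~structure) +
    ggplot2::scale_fill_viridis_c(name = toupper(metric),
                                  direction = if (metric == "dsc") 1 else -1) +
    ggplot2::labs(x = "TE (ms)", y = "TR (ms)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
  if (!is.null(anchor))
    p <- p + ggplot2::annotate("point",
                               x = which.min(abs(sort(unique(df$te)) - anchor$te)),
                               y = which.min(abs(sort(unique(df$tr)) - anchor$tr)),
                               shape = 8, colour = "gold", size = 3)
  p
}
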