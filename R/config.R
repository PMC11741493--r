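#' Default run configuration
#'
#' The configuration used when a config file omits a key (or for an empty
#' file): the standard 18 x 16 TR/TE sweep with the mixed region excluded,
#' anchor TR = 1535 / TE = 212 ms, the default IOV thresholds, the packaged
#' phantom, three simulated raters at 1 mm perturbation, and the calibrated
#' intensity-window segmenter.
#'
#' @return Nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "synthsweep_output",
    phantom = list(shape = c(64L, 64L, 16L), spacing = c(2, 2, 5),
                   noise_sigma = c(t1 = 30, t2 = 5, pd = 2),
                   b1_amplitude = 0),
    raters = list(n_raters = 3L, perturbation_mm = 2),
    staple = list(max_iter = 100L, tol = 1e-7, threshold = 0.5),
    grid = list(tr_values = default_tr_values(),
                te_values = default_te_values(),
                include_mixed = FALSE,
                anchor_tr = 1535, anchor_te = 212),
    thresholds = list(
      dsc = c(parotid_l = 0.83, parotid_r = 0.84,
              submandibular_l = 0.75, submandibular_r = 0.78),
      hd95 = c(parotid_l = 4.9, parotid_r = 5.1,
               submandibular_l = 3.1, submandibular_r = 3.1)),
    segmenter = list(name = "intensity_window")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, overlays it on [default_config()], and validates the
#' result. Unknown keys at any level are rejected by name; a grid whose
#' retained points would violate TE < TR is rejected naming the point.
#'
#' @param path path to a YAML file; an empty file yields the full defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  check_keys <- function(u, d, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown key: ", prefix, unknown[1], call. = FALSE)
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]])) && is.list(u[[k]]))
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
    }
  }
  check_keys(user, defaults)
  cfg <- modifyList(defaults, user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  g <- sweep_grid(cfg$grid$tr_values, cfg$grid$te_values,
                  include_mixed = isTRUE(cfg$grid$include_mixed),
                  anchor = acquisition_params(cfg$grid$anchor_tr,
                                              cfg$grid$anchor_te))
  check_grid_feasible(build_grid(g))  # retained TE >= TR points are named
  iov_thresholds(unlist(cfg$thresholds$dsc), unlist(cfg$thresholds$hd95))
  if (cfg$raters$n_raters < 1)
    stop("raters.n_raters must be >= 1", call. = FALSE)
  if (cfg$phantom$b1_amplitude < 0 || cfg$phantom$b1_amplitude >= 1)
    stop("phantom.b1_amplitude must be in [0, 1)", call. = FALSE)
  if (!cfg$segmenter$name %in% c("intensity_window", "oracle", "empty"))
    stop("segmenter.name must be one of intensity_window, oracle, empty",
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

# named substream so each pipeline stage has an independent reproducible seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 1009L)
}

#' Run the full pipeline on the packaged phantom
#'
#' End-to-end demonstration of the method: build the phantom, simulate three
#' raters per structure, fuse them with STAPLE into a consensus ground truth,
#' calibrate the intensity-window segmenter at the anchor acquisition, run
#' the 216-point sweep, and write the records, region summaries, exceedance
#' table, rater performance and a provenance record to `output_dir`.
#' Heatmap PNGs are written when ggplot2 is available.
#'
#' @param seed global integer seed; all stage randomness is derived from it
#'   through named substreams.
#' @param output_dir output directory (created if needed); `NULL` runs the
#'   pipeline without writing any files.
#' @param config a `run_config` (default: [default_config()] validated).
#' @param verbose log progress.
#' @return Invisibly, a list with `records`, `summary`, `exceedance`,
#'   `consensus_labels`, `staple_results` and `output_dir`.
#' @export
run_demo <- function(seed = 1L, output_dir = tempfile("synthsweep_demo"),
                     config = NULL, verbose = interactive()) {
  cfg <- if (is.null(config)) validate_config(default_config()) else config
  cfg$seed <- as.integer(seed)
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    if (verbose) message("[demo] ", name)
    tryCatch(expr, error = function(e)
      stop("demo failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  spec <- default_phantom_spec(shape = cfg$phantom$shape,
                               spacing = cfg$phantom$spacing,
                               noise_sigma = cfg$phantom$noise_sigma)
  ph <- stage("phantom", build_phantom(spec, seed = substream_seed(seed, "phantom")))
  maps <- ph$maps
  if (cfg$phantom$b1_amplitude > 0)
    maps <- stage("b1", apply_b1_bias(maps, cfg$phantom$b1_amplitude,
                                      seed = substream_seed(seed, "b1")))

  structures <- stats::setNames(as.integer(spec$structures$label),
                                spec$structures$name)
  staple_results <- list()
  consensus_labels <- array(0L, dim(ph$labels))
  stage("raters+staple", {
    for (nm in names(structures)) {
      stack <- simulate_raters(ph$labels, structures[[nm]],
                               n_raters = cfg$raters$n_raters,
                               perturbation_mm = cfg$raters$perturbation_mm,
                               seed = substream_seed(seed, paste0("raters_", nm)),
                               spacing = spec$spacing)
      res <- staple(stack, max_iter = cfg$staple$max_iter,
                    tol = cfg$staple$tol, threshold = cfg$staple$threshold)
      staple_results[[nm]] <- res
      consensus_labels[res$consensus & consensus_labels == 0L] <-
        structures[[nm]]
    }
  })

  grid <- sweep_grid(cfg$grid$tr_values, cfg$grid$te_values,
                     include_mixed = isTRUE(cfg$grid$include_mixed),
                     anchor = acquisition_params(cfg$grid$anchor_tr,
                                                 cfg$grid$anchor_te))
  segmenter <- stage("calibrate", switch(
    cfg$segmenter$name,
    oracle = oracle_segmenter(consensus_labels),
    empty = empty_segmenter(),
    intensity_window = {
      anchor_img <- synthesize_image(maps, grid$anchor)
      intensity_window_segmenter(
        calibrate_segmenter(anchor_img, consensus_labels, structures,
                            spacing = spec$spacing))
    }))

  records <- stage("sweep",
                   run_sweep(maps, segmenter, grid, consensus_labels,
                             structures, verbose = verbose))
  summary_tab <- stage("summarize", summarize_regions(records))
  thresholds <- iov_thresholds(unlist(cfg$thresholds$dsc),
                               unlist(cfg$thresholds$hd95))
  exceed <- stage("exceedance", iov_exceedance(records, thresholds))

  if (!is.null(output_dir)) stage("write", {
    out_records <- records
    names(out_records) <- c("structure", "tr_ms", "te_ms", "region", "dsc",
                            "hd95_mm", "hd95_defined", "failure",
                            "delta_tr_ms", "delta_te_ms")
    write.csv(out_records, file.path(output_dir, "sweep_records.csv"),
              row.names = FALSE)
    write.csv(summary_tab, file.path(output_dir, "region_summary.csv"),
              row.names = FALSE)
    write.csv(exceed, file.path(output_dir, "iov_exceedance.csv"),
              row.names = FALSE)
    perf <- do.call(rbind, lapply(names(staple_results), function(nm)
      data.frame(structure = nm,
                 rater = names(staple_results[[nm]]$sensitivity),
                 sensitivity = staple_results[[nm]]$sensitivity,
                 specificity = staple_results[[nm]]$specificity,
                 row.names = NULL)))
    write.csv(perf, file.path(output_dir, "rater_performance.csv"),
              row.names = FALSE)
    prov <- list(package = "synthsweep",
                 version = as.character(packageVersion("synthsweep")),
                 seed = cfg$seed, config = unclass(cfg))
    yaml::write_yaml(prov, file.path(output_dir, "provenance.yaml"))
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      for (m in c("dsc", "hd95")) {
        try({
          p <- plot_sweep(records, m, anchor = grid$anchor)
          ggplot2::ggsave(file.path(output_dir, paste0("heatmap_", m, ".png")),
                          p, width = 8, height = 6, dpi = 120)
        }, silent = TRUE)
      }
    }
  })
  invisible(list(records = records, summary = summary_tab,
                 exceedance = exceed, consensus_labels = consensus_labels,
                 staple_results = staple_results, output_dir = output_dir))
}
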