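#' Intensity preprocessing chain
#'
#' The normalization applied to every synthetic image before segmentation:
#' clip to the `lo_pct`/`hi_pct` percentiles for outlier removal, z-score
#' standardize (population standard deviation, i.e. divide by n), then map
#' the observed post-clip minimum/maximum linearly onto `[-1, 1]`. A constant
#' image maps to all zeros (degenerate rule: its range is empty).
#'
#' @param image numeric array.
#' @param lo_pct,hi_pct clipping percentiles (of the original image).
#' @return numeric array of the same shape with min -1 and max +1 (unless
#'   constant).
#' @export
preprocess_intensity <- function(image, lo_pct = 0.25, hi_pct = 99.75) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  bounds <- quantile(image, c(lo_pct, hi_pct) / 100, type = 7, names = FALSE)
  x <- pmin(pmax(image, bounds[1]), bounds[2])
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) return(array(0, dim(image)))
  x <- (x - mu) / sdev
  rng <- range(x)
  out <- 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
  array(out, dim(image))
}

#' Calibrate the intensity-window segmenter at anchor contrast
#'
#' Emulates a model trained at one acquisition: from the anchor image and the
#' true labels, record for each structure (a) the `[P5, P95]` window of its
#' preprocessed intensities and (b) an ellipsoidal spatial prior — the true
#' mask's centroid with per-axis extents inflated by 20%.
#'
#' @param image intensity volume synthesized at the anchor acquisition
#'   parameters.
#' @param labels integer label volume of the true structures.
#' @param structures named integer vector mapping structure id to label
#'   (default: every nonzero label, named `structure_<label>`).
#' @param spacing voxel spacing in mm.
#' @return An object of class `segmenter_calibration`.
#' @export
calibrate_segmenter <- function(image, labels, structures = NULL,
                                spacing = attr(image, "spacing")) {
  if (is.null(structures)) {
    labs <- sort(unique(labels[labels > 0]))
    structures <- stats::setNames(as.integer(labs), paste0("structure_", labs))
  }
  if (is.null(spacing)) stop("`spacing` required", call. = FALSE)
  pre <- preprocess_intensity(image)
  cal <- lapply(names(structures), function(nm) {
    lab <- structures[[nm]]
    inside <- labels == lab
    if (!any(inside)) stop("empty truth for structure '", nm, "'", call. = FALSE)
    win <- quantile(pre[inside], c(0.05, 0.95), type = 7, names = FALSE)
    coords <- voxel_coords_mm(inside, spacing)
    centroid <- colMeans(coords)
    ext <- apply(abs(sweep(coords, 2, centroid)), 2, max)
    ext <- pmax(ext, spacing)  # at least one voxel
    list(label = as.integer(lab), window = win,
         centroid = centroid, radii = ext * 1.2)
  })
  names(cal) <- names(structures)
  structure(list(structures = cal, spacing = as.numeric(spacing)),
            class = "segmenter_calibration")
}

#' Calibrated intensity-window segmenter
#'
#' A deterministic toy segmenter satisfying the plug-in contract: for each
#' calibrated structure it keeps voxels whose preprocessed intensity falls in
#' the structure's window, intersects them with the ellipsoidal spatial
#' prior, and retains the largest 6-connected component. An empty result is
#' allowed (the sweep records it as a failure).
#'
#' The segmenter deliberately depends on absolute image contrast: moving the
#' acquisition parameters away from the calibration contrast degrades it,
#' which is exactly the sensitivity the sweep is built to measure. It is a
#' test harness, not a model of any clinical network.
#'
#' @param calibration a `segmenter_calibration` from [calibrate_segmenter()].
#' @return A function `(image, spacing) -> integer label volume` usable as
#'   the `segmenter` argument of [run_sweep()].
#' @export
intensity_window_segmenter <- function(calibration) {
  stopifnot(inherits(calibration, "segmenter_calibration"))
  function(image, spacing) {
    pre <- preprocess_intensity(image)
    d <- dim(image)
    coords <- list(
      x = array(rep(seq_len(d[1]) * spacing[1], times = d[2] * d[3]), d),
      y = array(rep(rep(seq_len(d[2]) * spacing[2], each = d[1]), times = d[3]), d),
      z = array(rep(seq_len(d[3]) * spacing[3], each = d[1] * d[2]), d))
    out <- array(0L, d)
    for (nm in names(calibration$structures)) {
      s <- calibration$structures[[nm]]
      prior <- (coords$x - s$centroid[1])^2 / s$radii[1]^2 +
        (coords$y - s$centroid[2])^2 / s$radii[2]^2 +
        (coords$z - s$centroid[3])^2 / s$radii[3]^2 <= 1
      cand <- prior & pre >= s$window[1] & pre <= s$window[2]
      if (!any(cand)) next
      lab <- cpp_label_components(cand, d)
      out[lab == 1L & out == 0L] <- s$label
    }
    out
  }
}

#' Oracle and degenerate segmenters
#'
#' `oracle_segmenter` always returns the supplied ground-truth labels
#' (perfect agreement at every grid point); `empty_segmenter` always returns
#' an all-background volume (total failure at every grid point). Both are
#' test instruments for the sweep engine.
#'
#' @param labels integer label volume to return.
#' @return A segmenter function `(image, spacing) -> labels`.
#' @export
oracle_segmenter <- function(labels) {
  force(labels)
  function(image, spacing) {
    stopifnot(identical(dim(image), dim(labels)))
    labels
  }
}

#' @rdname oracle_segmenter
#' @export
empty_segmenter <- function() {
  function(image, spacing) array(0L, dim(image))
}

#' Check a segmenter against the plug-in contract
#'
#' Runs the candidate on an 8 x 8 x 4 smoke volume and verifies: the output
#' shape equals the input shape, every output label is 0 or one of the
#' declared structure labels, and two identical calls agree (determinism).
#'
#' @param segmenter function `(image, spacing) -> integer label volume`.
#' @param structure_labels integer labels the segmenter may emit.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_segmenter <- function(segmenter, structure_labels) {
  d <- c(8L, 8L, 4L)
  smoke <- array(seq_len(prod(d)) / prod(d), d)
  sp <- c(1, 1, 1)
  out1 <- segmenter(smoke, sp)
  if (!identical(dim(out1), d))
    stop("segmenter contract violation: output dim (",
         paste(dim(out1), collapse = "x"), ") != input dim (",
         paste(d, collapse = "x"), ")", call. = FALSE)
  bad <- setdiff(unique(as.vector(out1)), c(0L, as.integer(structure_labels)))
  if (length(bad))
    stop("segmenter contract violation: undeclared label(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  out2 <- segmenter(smoke, sp)
  if (!identical(out1, out2))
    stop("segmenter contract violation: output is not deterministic",
         call. = FALSE)
  invisible(TRUE)
}
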