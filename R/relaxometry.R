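#' Quantitative relaxometry maps
#'
#' Bundle co-registered quantitative T1, T2 and proton-density (PD) volumes
#' with their voxel spacing, the physical state from which contrast-weighted
#' images are synthesized. An optional multiplicative B1 transmit-field volume
#' models radiofrequency inhomogeneity.
#'
#' All volumes must share one shape. T1 and T2 are in milliseconds; PD is in
#' arbitrary units; zero T1 or zero PD marks background. Voxels with
#' T2 > T1 where both are positive are physically implausible but can arise
#' from noisy map fitting, so they trigger a warning rather than an error.
#'
#' @param t1 3D array of longitudinal relaxation times (ms, >= 0).
#' @param t2 3D array of transverse relaxation times (ms, >= 0).
#' @param pd 3D array of proton density (arbitrary units, >= 0).
#' @param spacing numeric vector of per-axis voxel spacing in mm (one entry
#'   per array axis, all > 0).
#' @param b1 optional multiplicative transmit-inhomogeneity volume
#'   (dimensionless); `NULL` means uniform 1.
#' @return An object of class `quantitative_maps`.
#' @examples
#' m <- quantitative_maps(array(1000, c(2, 2, 2)), array(100, c(2, 2, 2)),
#'                        array(1, c(2, 2, 2)), spacing = c(1, 1, 1))
#' @export
quantitative_maps <- function(t1, t2, pd, spacing, b1 = NULL) {
  for (nm in c("t1", "t2", "pd")) {
    v <- get(nm)
    if (!is.array(v) || length(dim(v)) != 3L)
      stop("`", nm, "` must be a 3D array", call. = FALSE)
  }
  if (!identical(dim(t1), dim(t2)))
    stop("shape mismatch: t2 map has dim (", paste(dim(t2), collapse = "x"),
         ") but t1 map has (", paste(dim(t1), collapse = "x"), ")", call. = FALSE)
  if (!identical(dim(t1), dim(pd)))
    stop("shape mismatch: pd map has dim (", paste(dim(pd), collapse = "x"),
         ") but t1 map has (", paste(dim(t1), collapse = "x"), ")", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values", call. = FALSE)
  if (any(t1 < 0) || any(t2 < 0) || any(pd < 0))
    stop("relaxation times and proton density must be non-negative", call. = FALSE)
  if (!is.null(b1)) {
    if (!identical(dim(b1), dim(t1)))
      stop("shape mismatch: b1 field has dim (", paste(dim(b1), collapse = "x"),
           ") but t1 map has (", paste(dim(t1), collapse = "x"), ")", call. = FALSE)
  }
  bad <- sum(t1 > 0 & t2 > 0 & t2 > t1)
  if (bad > 0)
    warning(bad, " voxel(s) have T2 > T1; physically implausible but kept ",
            "(noisy map fits can violate this)", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, pd = pd,
                 spacing = as.numeric(spacing), b1 = b1),
            class = "quantitative_maps")
}

#' @export
print.quantitative_maps <- function(x, ...) {
  cat("<quantitative_maps> ", paste(dim(x$t1), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " mm",
      if (!is.null(x$b1)) ", with B1 field" else "", "\n", sep = "")
  invisible(x)
}

#' Acquisition parameters for one synthetic contrast
#'
#' One point on the TR/TE sweep grid: a repetition time, an echo time, and an
#' optional inversion time for inversion-recovery synthesis.
#'
#' @param tr repetition time in ms (> 0).
#' @param te echo time in ms (>= 0, strictly less than `tr`).
#' @param ti optional inversion time in ms (> 0 and < `tr`); `NULL` for
#'   plain spin-echo synthesis.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr, te, ti = NULL) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive ms value", call. = FALSE)
  if (!is.numeric(te) || length(te) != 1L || !is.finite(te) || te < 0)
    stop("`te` must be a single non-negative ms value", call. = FALSE)
  if (te >= tr)
    stop("TE (", te, " ms) must be strictly less than TR (", tr, " ms)",
         call. = FALSE)
  if (!is.null(ti)) {
    if (!is.numeric(ti) || length(ti) != 1L || !is.finite(ti) || ti <= 0 || ti >= tr)
      stop("`ti` must be a single ms value in (0, TR)", call. = FALSE)
  }
  structure(list(tr = as.numeric(tr), te = as.numeric(te),
                 ti = if (is.null(ti)) NULL else as.numeric(ti)),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("<acquisition_params> TR=", x$tr, " ms, TE=", x$te, " ms",
      if (!is.null(x$ti)) paste0(", TI=", x$ti, " ms") else "", "\n", sep = "")
  invisible(x)
}

#' Synthesize a spin-echo contrast-weighted image
#'
#' Evaluates the saturation-recovery spin-echo signal model voxelwise:
#' \deqn{S = g \cdot B_1 \cdot PD \cdot (1 - e^{-TR/T_1}) \cdot e^{-TE/T_2}}
#' This is the canonical synthetic-MR model; commercial synthesis engines use
#' proprietary variants (slice-profile and echo-train corrections unknown), so
#' treat this as a documented approximation with the same TR/TE contrast
#' behaviour. Background voxels (PD = 0 or T1 = 0) map to exactly 0.
#'
#' @param maps a [quantitative_maps] object.
#' @param params an [acquisition_params] object (TI, if present, is ignored;
#'   use [synthesize_ir_image] for inversion recovery).
#' @param gain positive scalar scanner gain.
#' @return A numeric 3D array with the maps' shape; attribute `spacing`
#'   carries the voxel spacing in mm.
#' @examples
#' m <- quantitative_maps(array(1000, c(1, 1, 1)), array(100, c(1, 1, 1)),
#'                        array(1, c(1, 1, 1)), spacing = c(1, 1, 1))
#' synthesize_image(m, acquisition_params(tr = 1000, te = 0))  # 1 - exp(-1)
#' @export
synthesize_image <- function(maps, params, gain = 1) {
  stopifnot(inherits(maps, "quantitative_maps"),
            inherits(params, "acquisition_params"))
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("`gain` must be a single positive scalar", call. = FALSE)
  t1 <- maps$t1; t2 <- maps$t2; pd <- maps$pd
  tissue <- pd > 0 & t1 > 0
  recov <- array(0, dim(t1))
  recov[tissue] <- 1 - exp(-params$tr / t1[tissue])
  decay <- array(0, dim(t1))
  # TE = 0 gives no decay even where T2 = 0; elsewhere T2 = 0 kills the echo
  pos_t2 <- tissue & t2 > 0
  decay[pos_t2] <- exp(-params$te / t2[pos_t2])
  if (params$te == 0) decay[tissue] <- ifelse(t2[tissue] > 0, decay[tissue], 1)
  s <- gain * pd * recov * decay
  if (!is.null(maps$b1)) s <- s * maps$b1
  s[!tissue] <- 0
  attr(s, "spacing") <- maps$spacing
  s
}

#' Synthesize an inversion-recovery contrast-weighted image
#'
#' Magnitude inversion-recovery spin-echo signal:
#' \deqn{S = |g \cdot B_1 \cdot PD \cdot (1 - 2e^{-TI/T_1} + e^{-TR/T_1})
#'   \cdot e^{-TE/T_2}|}
#' The null point for a tissue sits at \eqn{TI = T_1 \ln 2}. Provided as an
#' optional extension; the TR/TE sweep uses [synthesize_image].
#'
#' @inheritParams synthesize_image
#' @param params an [acquisition_params] with a non-`NULL` `ti`.
#' @return A numeric 3D array (magnitude signal, >= 0).
#' @export
synthesize_ir_image <- function(maps, params, gain = 1) {
  stopifnot(inherits(maps, "quantitative_maps"),
            inherits(params, "acquisition_params"))
  if (is.null(params$ti))
    stop("inversion-recovery synthesis requires `ti` in the acquisition params",
         call. = FALSE)
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("`gain` must be a single positive scalar", call. = FALSE)
  t1 <- maps$t1; t2 <- maps$t2; pd <- maps$pd
  tissue <- pd > 0 & t1 > 0
  recov <- array(0, dim(t1))
  recov[tissue] <- 1 - 2 * exp(-params$ti / t1[tissue]) +
    exp(-params$tr / t1[tissue])
  decay <- array(0, dim(t1))
  pos_t2 <- tissue & t2 > 0
  decay[pos_t2] <- exp(-params$te / t2[pos_t2])
  if (params$te == 0) decay[tissue] <- ifelse(t2[tissue] > 0, decay[tissue], 1)
  s <- gain * pd * recov * decay
  if (!is.null(maps$b1)) s <- s * maps$b1
  s <- abs(s)
  s[!tissue] <- 0
  attr(s, "spacing") <- maps$spacing
  s
}

#' Quantize a floating-point image to unsigned 12-bit integers
#'
#' Linear rescale of the observed intensity range to `[0, 4095]`, rounded.
#' Off by default throughout the package: segmenter preprocessing
#' re-normalizes intensities anyway, so quantization only adds realism.
#'
#' @param image numeric array.
#' @return Integer array of the same shape, values in 0..4095.
#' @export
quantize_12bit <- function(image) {
  rng <- range(image)
  if (rng[1] == rng[2]) return(array(0L, dim(image)))
  q <- array(as.integer(round((image - rng[1]) / (rng[2] - rng[1]) * 4095)),
             dim(image))
  attr(q, "spacing") <- attr(image, "spacing")
  q
}
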