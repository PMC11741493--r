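#' Dice similarity coefficient
#'
#' Volume overlap between two binary masks: \eqn{2|A \cap B| / (|A| + |B|)}.
#' Convention for degenerate inputs: both masks empty gives 1 (perfect
#' agreement on "nothing"), exactly one empty gives 0.
#'
#' @param a,b binary 3D arrays of one common shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_binary_pair(a, b)
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Surface voxels of a binary mask
#'
#' A mask voxel belongs to the surface when at least one of its six
#' face-adjacent neighbours (6-connectivity) is background; voxels on the
#' volume edge count their out-of-volume neighbours as background.
#'
#' @param mask binary 3D array.
#' @return logical array of the same shape; empty mask gives an empty surface.
#' @export
surface_voxels <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  m <- array(mask != 0, d)
  if (!any(m)) return(array(FALSE, d))
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx <- vector("list", 3); for (k in 1:3) idx[[k]] <- seq_len(d[k])
    src <- idx; dst <- idx
    if (by == 1L) { dst[[ax]] <- seq_len(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
    else { dst[[ax]] <- 2:d[ax]; src[[ax]] <- seq_len(d[ax] - 1L) }
    shifted <- array(FALSE, d)  # out-of-volume neighbours are background
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    acc & shifted
  }
  for (ax in 1:3) for (by in c(1L, -1L)) interior <- shift_and(interior, ax, by)
  m & !interior
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Surface-to-surface distance between two masks in physical units. For each
#' surface voxel center of A the Euclidean mm distance to the nearest surface
#' voxel center of B is collected, and vice versa; HD95 is the 95th percentile
#' (linear interpolation between order statistics) of the pooled multiset of
#' both directed distance sets. The pooled convention is symmetric by
#' construction; the directed-max variant (max of the two directed 95th
#' percentiles) is available via `directed_max = TRUE`.
#'
#' An empty mask makes the metric undefined; this raises a condition of class
#' `synthsweep_undefined_metric`, which the sweep layer catches and records
#' as a failure sentinel.
#'
#' @param a,b binary 3D arrays of one common shape.
#' @param spacing per-axis voxel spacing in mm.
#' @param percentile percentile of the surface-distance distribution
#'   (default 95).
#' @param directed_max if `TRUE`, use the maximum of the two directed
#'   percentiles instead of the pooled percentile.
#' @return scalar distance in mm; 0 for identical masks.
#' @export
hd95 <- function(a, b, spacing, percentile = 95, directed_max = FALSE) {
  check_binary_pair(a, b)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values", call. = FALSE)
  if (!any(a != 0) || !any(b != 0))
    stop(undefined_metric_condition(
      paste0("hd95 undefined: ", if (!any(a != 0)) "first" else "second",
             " mask is empty")))
  sa <- voxel_coords_mm(surface_voxels(a), spacing)
  sb <- voxel_coords_mm(surface_voxels(b), spacing)
  dab <- cpp_nn_distances(sa, sb)
  dba <- cpp_nn_distances(sb, sa)
  p <- percentile / 100
  if (directed_max)
    max(quantile(dab, p, type = 7, names = FALSE),
        quantile(dba, p, type = 7, names = FALSE))
  else
    quantile(c(dab, dba), p, type = 7, names = FALSE)
}

#' Both agreement metrics at once
#'
#' @inheritParams hd95
#' @return list with `dsc`, `hd95` (NA when undefined) and `hd95_defined`.
#' @export
metric_pair <- function(a, b, spacing) {
  d <- dice(a, b)
  h <- tryCatch(hd95(a, b, spacing),
                synthsweep_undefined_metric = function(e) NA_real_)
  list(dsc = d, hd95 = h, hd95_defined = !is.na(h))
}

undefined_metric_condition <- function(msg) {
  structure(class = c("synthsweep_undefined_metric", "error", "condition"),
            list(message = msg, call = NULL))
}

check_binary_pair <- function(a, b) {
  if (is.null(dim(a)) || is.null(dim(b)) || !identical(dim(a), dim(b)))
    stop("masks must be arrays of one common shape", call. = FALSE)
  invisible(TRUE)
}
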