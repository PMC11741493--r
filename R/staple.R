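#' Aligned rater mask stack
#'
#' Binary masks from R raters contouring the same structure on the same grid;
#' the input to [staple()].
#'
#' @param masks list of logical/0-1 3D arrays with one common shape.
#' @param ids character rater identifiers (defaults to `rater1..R`).
#' @param spacing per-axis voxel spacing in mm.
#' @return An object of class `rater_stack`.
#' @export
rater_stack <- function(masks, ids = NULL, spacing = c(1, 1, 1)) {
  if (!is.list(masks) || length(masks) < 1)
    stop("need at least one rater mask", call. = FALSE)
  d <- dim(masks[[1]])
  masks <- lapply(seq_along(masks), function(j) {
    m <- masks[[j]]
    if (!identical(dim(m), d))
      stop("rater mask ", j, " shape differs from rater 1", call. = FALSE)
    if (is.logical(m)) return(m)
    if (!all(m %in% c(0, 1)))
      stop("rater mask ", j, " is not binary", call. = FALSE)
    array(m == 1, d)
  })
  if (is.null(ids)) ids <- paste0("rater", seq_along(masks))
  stopifnot(length(ids) == length(masks))
  structure(list(masks = masks, ids = as.character(ids),
                 spacing = as.numeric(spacing)),
            class = "rater_stack")
}

#' @export
print.rater_stack <- function(x, ...) {
  cat("<rater_stack> ", length(x$masks), " raters, ",
      paste(dim(x$masks[[1]]), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

#' STAPLE consensus from multiple raters
#'
#' Simultaneous truth and performance level estimation: an EM algorithm that
#' alternates between estimating the per-voxel posterior probability of the
#' hidden true segmentation (E-step) and each rater's sensitivity p and
#' specificity q (M-step).
#'
#' E-step, voxel i with prior \eqn{\pi_i}:
#' \deqn{W_i = a_i / (a_i + b_i),\quad
#'   a_i = \pi_i \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}},\quad
#'   b_i = (1-\pi_i) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}}
#' M-step:
#' \deqn{p_j = \sum_{i: D_{ij}=1} W_i / \sum_i W_i,\quad
#'   q_j = \sum_{i: D_{ij}=0} (1-W_i) / \sum_i (1-W_i)}
#'
#' Computation is restricted to the bounding box of the union of rater masks
#' dilated by 5 voxels; voxels outside are background with W = 0. This crop
#' rule is fixed because the specificity estimate depends on how much
#' background is included, and a fixed rule keeps results reproducible.
#'
#' @param stack a [rater_stack] (or list of binary arrays).
#' @param prior scalar prior probability of foreground, or a volume of
#'   per-voxel priors; `NULL` (default) uses the mean rater foreground
#'   fraction inside the crop.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the absolute change of
#'   `mean(p) + mean(q)` between iterations.
#' @param threshold posterior threshold for the binary consensus; ties
#'   (W exactly at the threshold) count as foreground.
#' @return list of class `staple_result`: `probability` (W volume),
#'   `consensus` (logical volume), `sensitivity` and `specificity` (per
#'   rater, named), `iterations`, `converged`, `log_likelihood` (trace,
#'   computed inside the crop).
#' @export
staple <- function(stack, prior = NULL, max_iter = 100, tol = 1e-7,
                   threshold = 0.5) {
  if (is.list(stack) && !inherits(stack, "rater_stack"))
    stack <- rater_stack(stack)
  stopifnot(inherits(stack, "rater_stack"))
  masks <- stack$masks
  R <- length(masks)
  shape <- dim(masks[[1]])
  union_mask <- Reduce(`|`, masks)
  if (!any(union_mask)) stop("all rater masks are empty", call. = FALSE)

  # crop: union bounding box dilated 5 voxels
  idx <- which(union_mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 5L, 1L)
  hi <- pmin(apply(idx, 2, max) + 5L, shape)
  crop <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  D <- vapply(masks, function(m) as.numeric(crop(m)), numeric(prod(hi - lo + 1L)))
  n <- nrow(D)

  if (is.null(prior)) {
    pri <- mean(D)
  } else if (length(prior) == 1L) {
    pri <- as.numeric(prior)
  } else {
    stopifnot(identical(dim(prior), shape))
    pri <- as.numeric(crop(prior))
  }
  pri <- pmin(pmax(pri, 1e-12), 1 - 1e-12)

  p <- rep(0.99999, R)
  q <- rep(0.99999, R)
  W <- numeric(n)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  prev_stat <- mean(p) + mean(q)
  while (it < max_iter) {
    it <- it + 1L
    # E-step in log space for numerical safety
    la <- log(pri) + D %*% log(p) + (1 - D) %*% log1p(-p)
    lb <- log1p(-pri) + D %*% log1p(-q) + (1 - D) %*% log(q)
    mx <- pmax(la, lb)
    a <- exp(la - mx); b <- exp(lb - mx)
    W <- as.numeric(a / (a + b))
    ll_trace <- c(ll_trace, sum(mx + log(a + b)))
    # M-step
    sw <- sum(W); swc <- n - sw
    p <- as.numeric(crossprod(D, W)) / sw
    q <- as.numeric(crossprod(1 - D, 1 - W)) / swc
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    stat <- mean(p) + mean(q)
    if (abs(stat - prev_stat) < tol) { converged <- TRUE; break }
    prev_stat <- stat
  }

  Wvol <- array(0, shape)
  Wvol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- W
  consensus <- Wvol >= threshold
  names(p) <- names(q) <- stack$ids
  structure(list(probability = Wvol, consensus = consensus,
                 sensitivity = p, specificity = q,
                 iterations = it, converged = converged,
                 log_likelihood = ll_trace,
                 threshold = threshold, spacing = stack$spacing),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat("<staple_result> ", length(x$sensitivity), " raters, ",
      x$iterations, " iterations",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      "  sensitivity: ", paste(sprintf("%.4f", x$sensitivity), collapse = " "),
      "\n  specificity: ", paste(sprintf("%.4f", x$specificity), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Write STAPLE outputs to disk
#'
#' Posterior probability as float NIfTI, binary consensus as uint8 NIfTI, and
#' the per-rater performance table as CSV.
#'
#' @param result a `staple_result`.
#' @param prob_path,consensus_path,performance_path output file paths; any
#'   may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_staple_result <- function(result, prob_path = NULL,
                                consensus_path = NULL,
                                performance_path = NULL) {
  stopifnot(inherits(result, "staple_result"))
  if (!is.null(prob_path))
    write_volume(result$probability, prob_path, result$spacing, "float")
  if (!is.null(consensus_path))
    write_volume(result$consensus, consensus_path, result$spacing, "uint8")
  if (!is.null(performance_path))
    write.csv(data.frame(rater = names(result$sensitivity),
                         sensitivity = result$sensitivity,
                         specificity = result$specificity,
                         row.names = NULL),
              performance_path, row.names = FALSE)
  invisible(c(prob_path, consensus_path, performance_path))
}
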