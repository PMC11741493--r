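#' Phantom specification
#'
#' Describes a digital head-and-neck phantom: a head ellipsoid filled with
#' muscle-like tissue and a fat-like rim, containing bilateral ellipsoidal
#' salivary-gland-like structures with distinct T1/T2/PD. The phantom stands
#' in for patient relaxometry scans so the full sweep pipeline runs with no
#' external data.
#'
#' Tissue parameters default to literature-plausible 3T values; only the
#' contrast *ordering* between structures and background matters for
#' exercising the method. Proton density is deliberately nearly equal across
#' glands and muscle so PD-weighted contrast is poor — the failure mode the
#' sweep is designed to expose.
#'
#' @param shape integer vector of 3 voxel counts.
#' @param spacing per-axis voxel spacing in mm.
#' @param tissue_table data.frame with columns `tissue`, `t1`, `t2`, `pd`
#'   (ms, ms, a.u., all > 0).
#' @param structures data.frame with columns `name`, `label` (integer id),
#'   `tissue`, `cx`, `cy`, `cz` (center, mm, origin at the volume center,
#'   x = left-right), `rx`, `ry`, `rz` (radii, mm). Bilateral pairs should
#'   mirror about x = 0.
#' @param head_radii head ellipsoid radii in mm (x, y, z).
#' @param fat_rim_frac fraction of the head radii inside which tissue is
#'   muscle-like; the shell outside it is fat-like.
#' @param noise_sigma named vector `c(t1=, t2=, pd=)` of Gaussian noise
#'   standard deviations added to each quantitative map (map units) inside
#'   tissue.
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()] for the packaged defaults,
#'   [build_phantom()] to realize the maps and labels.
#' @export
phantom_spec <- function(shape = c(240, 240, 16), spacing = c(0.5, 0.5, 5),
                         tissue_table = default_tissue_table(),
                         structures = default_structures(),
                         head_radii = c(58, 58, 70),
                         fat_rim_frac = 0.88,
                         noise_sigma = c(t1 = 30, t2 = 5, pd = 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("`shape` must be 3 voxel counts >= 4", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values", call. = FALSE)
  req <- c("tissue", "t1", "t2", "pd")
  if (!all(req %in% names(tissue_table)))
    stop("tissue_table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(tissue_table$t1 <= 0 | tissue_table$t2 <= 0 | tissue_table$pd <= 0))
    stop("all tissue parameters must be > 0", call. = FALSE)
  sreq <- c("name", "label", "tissue", "cx", "cy", "cz", "rx", "ry", "rz")
  if (!all(sreq %in% names(structures)))
    stop("structures needs columns ", paste(sreq, collapse = ", "), call. = FALSE)
  if (anyDuplicated(structures$label))
    stop("structure labels must be unique", call. = FALSE)
  miss <- setdiff(structures$tissue, tissue_table$tissue)
  if (length(miss))
    stop("structure tissue(s) missing from tissue_table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  # every structure ellipsoid must fit inside the head ellipsoid (sufficient
  # check: center offset plus radius along each axis within the head radius)
  for (k in seq_len(nrow(structures))) {
    s <- structures[k, ]
    if (any(abs(c(s$cx, s$cy, s$cz)) + c(s$rx, s$ry, s$rz) > head_radii))
      stop("structure '", s$name, "' extends outside the head ellipsoid",
           call. = FALSE)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 tissue_table = tissue_table, structures = structures,
                 head_radii = as.numeric(head_radii),
                 fat_rim_frac = fat_rim_frac,
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

#' Default tissue parameter table
#'
#' Literature-plausible 3T relaxation values for the phantom's tissue classes.
#' These are phantom defaults, not measurements.
#'
#' @return data.frame with columns `tissue`, `t1` (ms), `t2` (ms), `pd` (a.u.).
#' @export
default_tissue_table <- function() {
  data.frame(
    tissue = c("muscle", "fat", "parotid", "submandibular"),
    t1 = c(1400, 400, 1100, 1300),
    t2 = c(40, 130, 120, 100),
    pd = c(80, 95, 82, 81)
  )
}

#' Default structure geometry
#'
#' Bilateral parotid-like and submandibular-like ellipsoids, mirror-symmetric
#' about the mid-sagittal plane (x = 0). Centers and radii in mm.
#'
#' @return data.frame usable as the `structures` argument of [phantom_spec()].
#' @export
default_structures <- function() {
  data.frame(
    name = c("parotid_l", "parotid_r", "submandibular_l", "submandibular_r"),
    label = 1:4,
    tissue = c("parotid", "parotid", "submandibular", "submandibular"),
    cx = c(40, -40, 16, -16),
    cy = c(-4, -4, 26, 26),
    cz = c(5, 5, -18, -18),
    rx = c(10, 10, 8, 8),
    ry = c(15, 15, 10, 10),
    rz = c(20, 20, 13, 13)
  )
}

#' Packaged default phantom specification
#'
#' A 64 x 64 x 16 voxel grid at 2 x 2 x 5 mm spacing (128 x 128 x 80 mm field
#' of view) — large enough for mm-realistic gland sizes while keeping a full
#' 216-point sweep fast on one CPU.
#'
#' @param shape,spacing override the default geometry.
#' @param ... passed through to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(shape = c(64, 64, 16),
                                 spacing = c(2, 2, 5), ...) {
  phantom_spec(shape = shape, spacing = spacing, ...)
}

# voxel-center physical coordinates (mm), origin at the volume center;
# reflection i -> n+1-i maps x -> -x exactly for any parity
axis_coords <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp

phantom_coord_grids <- function(shape, spacing) {
  x <- axis_coords(shape[1], spacing[1])
  y <- axis_coords(shape[2], spacing[2])
  z <- axis_coords(shape[3], spacing[3])
  list(x = array(rep(x, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
       z = array(rep(z, each = shape[1] * shape[2]), shape))
}

ellipsoid_mask <- function(g, center, radii) {
  (g$x - center[1])^2 / radii[1]^2 +
    (g$y - center[2])^2 / radii[2]^2 +
    (g$z - center[3])^2 / radii[3]^2 <= 1
}

#' Build the phantom maps and label volume
#'
#' Realizes a [phantom_spec]: fills the head with tissue parameters, carves
#' the structures, assigns one integer label per structure, and adds Gaussian
#' noise to the quantitative maps (never to the labels). Background outside
#' the head ellipsoid stays exactly 0 on all maps.
#'
#' @param spec a `phantom_spec`.
#' @param seed integer seed; the result is fully deterministic given it.
#' @return list with `maps` ([quantitative_maps]) and `labels` (integer 3D
#'   array, 0 = no structure).
#' @export
build_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_coord_grids(spec$shape, spec$spacing)
  head <- ellipsoid_mask(g, c(0, 0, 0), spec$head_radii)
  inner <- ellipsoid_mask(g, c(0, 0, 0), spec$head_radii * spec$fat_rim_frac)

  tis <- spec$tissue_table
  row_of <- function(tissue) tis[match(tissue, tis$tissue), ]
  t1 <- array(0, spec$shape); t2 <- array(0, spec$shape); pd <- array(0, spec$shape)
  fill <- function(mask, tissue) {
    r <- row_of(tissue)
    t1[mask] <<- r$t1; t2[mask] <<- r$t2; pd[mask] <<- r$pd
  }
  fill(head & !inner, "fat")
  fill(inner, "muscle")

  labels <- array(0L, spec$shape)
  masks <- vector("list", nrow(spec$structures))
  for (k in seq_len(nrow(spec$structures))) {
    s <- spec$structures[k, ]
    masks[[k]] <- ellipsoid_mask(g, c(s$cx, s$cy, s$cz), c(s$rx, s$ry, s$rz))
  }
  for (a in seq_along(masks)) for (b in seq_along(masks)) {
    if (a < b && any(masks[[a]] & masks[[b]]))
      stop("structures overlap: '", spec$structures$name[a], "' and '",
           spec$structures$name[b], "'", call. = FALSE)
  }
  for (k in seq_along(masks)) {
    s <- spec$structures[k, ]
    fill(masks[[k]], s$tissue)
    labels[masks[[k]]] <- as.integer(s$label)
  }

  sg <- spec$noise_sigma
  if (any(sg > 0)) {
    with_seed(seed, {
      n <- sum(head)
      if (sg[["t1"]] > 0) t1[head] <- pmax(t1[head] + rnorm(n, 0, sg[["t1"]]), 1)
      if (sg[["t2"]] > 0) t2[head] <- pmax(t2[head] + rnorm(n, 0, sg[["t2"]]), 1)
      if (sg[["pd"]] > 0) pd[head] <- pmax(pd[head] + rnorm(n, 0, sg[["pd"]]), 0.1)
    })
  }
  maps <- quantitative_maps(t1, t2, pd, spacing = spec$spacing)
  list(maps = maps, labels = labels)
}

#' Simulate rater contours for one structure
#'
#' Emulates independent human raters re-contouring a known truth: each rater's
#' mask is the truth expanded or contracted by a signed distance offset drawn
#' from N(0, `perturbation_mm`), with an additional smooth Gaussian boundary
#' jitter field (s.d. half the perturbation), then reduced to its largest
#' connected component so rater masks stay topologically simple.
#'
#' @param labels integer label volume from [build_phantom()].
#' @param structure_label integer id of the structure to contour.
#' @param n_raters number of raters (>= 1).
#' @param perturbation_mm boundary perturbation magnitude in mm; 0 reproduces
#'   the truth exactly for every rater.
#' @param seed integer seed; output is byte-identical across runs for a fixed
#'   seed.
#' @param spacing voxel spacing in mm.
#' @return A [rater_stack] of `n_raters` binary masks.
#' @export
simulate_raters <- function(labels, structure_label, n_raters = 3,
                            perturbation_mm = 1, seed = 1L,
                            spacing = c(2, 2, 5)) {
  if (n_raters < 1) stop("`n_raters` must be >= 1", call. = FALSE)
  truth <- labels == structure_label
  if (!any(truth)) stop("structure ", structure_label, " not present", call. = FALSE)
  if (perturbation_mm == 0) {
    masks <- replicate(n_raters, truth, simplify = FALSE)
    return(rater_stack(masks, ids = paste0("rater", seq_len(n_raters)),
                       spacing = spacing))
  }
  sd_field <- signed_distance(truth, spacing,
                              margin_mm = 4 * perturbation_mm + 2 * max(spacing))
  masks <- with_seed(seed, {
    lapply(seq_len(n_raters), function(j) {
      offset <- rnorm(1, 0, perturbation_mm)
      jitter <- smooth_noise_field(dim(truth), sigma_vox = c(2, 2, 1))
      jitter <- jitter * (perturbation_mm / 2)
      m <- sd_field <= offset + jitter
      lab <- cpp_label_components(m, dim(m))
      m <- lab == 1L  # largest component
      if (!any(m))
        stop("perturbation ", perturbation_mm,
             " mm emptied rater ", j, "'s mask", call. = FALSE)
      m
    })
  })
  rater_stack(masks, ids = paste0("rater", seq_len(n_raters)), spacing = spacing)
}

# signed Euclidean distance (mm) to the mask boundary: for voxels inside the
# mask, minus the distance to the nearest background voxel center; outside,
# plus the distance to the nearest mask voxel center. Thresholding at 0
# reproduces the mask exactly, and offsets below one voxel spacing round
# symmetrically. Voxels beyond margin_mm of the mask bounding box are
# assigned +margin so rater thresholds never reach them.
signed_distance <- function(mask, spacing, margin_mm) {
  fg_surf <- voxel_coords_mm(surface_voxels(mask), spacing)
  bg_surf <- voxel_coords_mm(surface_voxels(!mask), spacing)
  box <- bounding_box_mask(mask, spacing, margin_mm)
  out <- array(margin_mm, dim(mask))
  out_idx <- which(box & !mask)
  if (length(out_idx))
    out[out_idx] <- cpp_nn_distances(
      sweep_cols(arrayInd(out_idx, dim(mask)), spacing), fg_surf)
  in_idx <- which(mask)
  out[in_idx] <- -cpp_nn_distances(
    sweep_cols(arrayInd(in_idx, dim(mask)), spacing), bg_surf)
  out
}

voxel_coords_mm <- function(mask, spacing) {
  sweep_cols(arrayInd(which(mask), dim(mask)), spacing)
}

sweep_cols <- function(m, spacing) {
  m <- m * rep(spacing, each = nrow(m))
  storage.mode(m) <- "double"
  m
}

bounding_box_mask <- function(mask, spacing, margin_mm) {
  idx <- which(mask, arr.ind = TRUE)
  pad <- ceiling(margin_mm / spacing)
  out <- array(FALSE, dim(mask))
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, dim(mask))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  out
}

# white noise smoothed by a separable Gaussian, rescaled to unit s.d.
smooth_noise_field <- function(shape, sigma_vox) {
  a <- array(rnorm(prod(shape)), shape)
  a <- gaussian_smooth3d(a, sigma_vox)
  a / sd(a)
}

gaussian_smooth3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2)); k <- k / sum(k)
    a <- convolve_axis(a, k, ax)
  }
  a
}

# replicate-padded 1D convolution along one axis of a 3D array
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1])
  r <- (length(k) - 1L) / 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  out <- matrix(0, nrow = nrow(m), ncol = ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
  b <- array(out, db)
  aperm(b, order(perm))
}

#' Apply a smooth B1 transmit bias field to quantitative maps
#'
#' Sets the maps' multiplicative B1 field to a smooth low-order polynomial in
#' normalized coordinates, scaled into `[1 - amplitude, 1 + amplitude]`. The
#' polynomial always carries a nonzero left-right linear term, so the field is
#' asymmetric about the mid-sagittal plane — the lateral-asymmetry artifact
#' produced by inconsistent head-and-neck coil placement.
#'
#' @param maps a [quantitative_maps] object.
#' @param amplitude bias amplitude in `[0, 1)`; 0 yields a uniform field of 1.
#' @param seed integer seed for the polynomial coefficients.
#' @return The maps with `b1` set.
#' @export
apply_b1_bias <- function(maps, amplitude, seed = 1L) {
  stopifnot(inherits(maps, "quantitative_maps"))
  if (amplitude < 0 || amplitude >= 1)
    stop("`amplitude` must be in [0, 1)", call. = FALSE)
  shape <- dim(maps$t1)
  if (amplitude == 0) {
    maps$b1 <- array(1, shape)
    return(maps)
  }
  g <- phantom_coord_grids(shape, maps$spacing)
  xn <- g$x / max(abs(g$x)); yn <- g$y / max(abs(g$y)); zn <- g$z / max(abs(g$z))
  f <- with_seed(seed, {
    co <- runif(5, -1, 1)
    co[1] <- sign(co[1] + (co[1] == 0)) * max(abs(co[1]), 0.3)  # keep L-R term
    co[1] * xn + co[2] * xn^2 + co[3] * yn + co[4] * zn + co[5] * xn * yn
  })
  f <- f / max(abs(f))
  maps$b1 <- 1 + amplitude * f
  maps
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
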