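# Independent oracles used by the metric tests: exhaustive all-pairs surface
# distances in plain R (no shared code with the package's nearest-neighbour
# implementation beyond surface extraction).

surface_coords_mm <- function(mask, spacing) {
  idx <- arrayInd(which(surface_voxels(mask)), dim(mask))
  t(t(idx) * spacing)
}

brute_force_hd <- function(a, b, spacing, p = 0.95, directed_max = FALSE) {
  A <- surface_coords_mm(a, spacing)
  B <- surface_coords_mm(b, spacing)
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D <- sqrt(pmax(D2, 0))
  dab <- apply(D, 1, min)
  dba <- apply(D, 2, min)
  if (directed_max)
    max(quantile(dab, p, type = 7, names = FALSE),
        quantile(dba, p, type = 7, names = FALSE))
  else
    quantile(c(dab, dba), p, type = 7, names = FALSE)
}

set_formula_dice <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  if (length(A) == 0 && length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

random_mask <- function(dims, p = 0.3) array(runif(prod(dims)) < p, dims)
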