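#' Read quantitative maps from NIfTI-1 files
#'
#' Loads T1, T2 and PD volumes, takes voxel spacing from the T1 header, and
#' verifies that the three affines agree elementwise beyond a tolerance of
#' 1e-4 (maps fitted from one acquisition are inherently co-registered; a
#' larger disagreement indicates mismatched files).
#'
#' @param t1_path,t2_path,pd_path paths to NIfTI volumes (ms, ms, a.u.).
#' @param b1_path optional path to a multiplicative B1 field volume.
#' @return A [quantitative_maps] object.
#' @export
read_quantitative_maps <- function(t1_path, t2_path, pd_path, b1_path = NULL) {
  vols <- lapply(c(t1 = t1_path, t2 = t2_path, pd = pd_path), RNifti::readNifti)
  affines <- lapply(vols, function(v) unclass(RNifti::xform(v)))
  for (nm in c("t2", "pd")) {
    if (max(abs(affines[[nm]] - affines[["t1"]])) > 1e-4)
      stop("affine of ", nm, " map disagrees with t1 map beyond 1e-4; ",
           "maps are not co-registered", call. = FALSE)
  }
  spacing <- RNifti::pixdim(vols$t1)[1:3]
  b1 <- if (!is.null(b1_path)) as_volume(RNifti::readNifti(b1_path)) else NULL
  quantitative_maps(as_volume(vols$t1), as_volume(vols$t2),
                    as_volume(vols$pd), spacing = spacing, b1 = b1)
}

#' Write a volume as NIfTI-1
#'
#' @param volume numeric or integer 3D array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param spacing per-axis voxel spacing in mm.
#' @param datatype NIfTI datatype, e.g. `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing, datatype = "float") {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' Values must be 0/1 after rounding; anything else is rejected.
#'
#' @param path NIfTI file path.
#' @return list with `mask` (logical 3D array) and `spacing` (mm).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  v <- as_volume(img)
  if (!all(v %in% c(0, 1)))
    stop("mask at ", path, " is not binary", call. = FALSE)
  list(mask = array(v == 1, dim(v)), spacing = RNifti::pixdim(img)[1:3])
}

# strip niftiImage class/attrs down to a plain 3D array
as_volume <- function(img) {
  array(as.numeric(img), dim(img)[1:3])
}
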