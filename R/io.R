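#' Write a volume to a NIfTI-1 file
#'
#' Volumes are written as double precision so that read-back is exact.
#'
#' @param vol Numeric array (3-D or 4-D).
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param voxel_size Voxel size in mm, one value per spatial dimension (a
#'   single value is used isotropically).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  if (!all(is.finite(vol))) stop("volume contains non-finite values")
  nd <- length(dim(vol))
  if (is.null(dim(vol)) || nd < 3L) stop("'vol' must be a 3-D or 4-D array")
  vs <- rep_len(as.numeric(voxel_size), 3L)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(vs, rep(1, nd - 3L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a NIfTI file.
#' @return A plain numeric array with attributes \code{voxel_size} (mm) and
#'   \code{affine} (the 4x4 voxel-to-world matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to parse NIfTI file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  out <- as.array(img)
  attr(out, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(out))))]
  attr(out, "affine") <- structure(RNifti::xform(img), class = NULL)
  out
}
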