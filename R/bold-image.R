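#' BOLD image container
#'
#' A `bold_image` bundles a 4D voxel time-series array with the acquisition
#' geometry the analysis needs: isotropic voxel size, repetition time, a 3D
#' brain mask, and an ordered provenance record of the preprocessing steps
#' already applied.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param tr_s positive scalar, repetition time in seconds.
#' @param mask 3D logical array matching the spatial dimensions; `NULL` means
#'   all voxels are in-brain.
#' @param provenance character vector of applied processing steps, in order.
#'
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(data, voxel_size_mm = 3, tr_s = 2, mask = NULL,
                       provenance = character()) {
  if (length(dim(data)) != 4L) stopf("`data` must be a 4D array")
  sp <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!identical(dim(mask), sp))
    stopf("mask dimensions (%s) do not match data (%s)",
          paste(dim(mask), collapse = "x"), paste(sp, collapse = "x"))
  if (dim(data)[4] < 2L) stopf("need at least 2 time points")
  if (voxel_size_mm <= 0 || tr_s <= 0)
    stopf("voxel_size_mm and tr_s must be positive")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 mask = array(as.logical(mask), sp),
                 provenance = as.character(provenance)),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %d x %d x %d voxels x %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %g mm isotropic, TR: %g s\n",
              x$voxel_size_mm, x$tr_s))
  cat(sprintf("  in-mask voxels: %d / %d\n", sum(x$mask), prod(d[1:3])))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

n_volumes <- function(bold) dim(bold$data)[4]

# in-mask time series as a (time x voxels) matrix, column order = linear
# index order of in-mask voxels
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  m <- matrix(bold$data, prod(d[1:3]), d[4])
  t(m[as.vector(bold$mask), , drop = FALSE])
}

# write a (time x voxels) matrix back into the in-mask voxels of `bold`
bold_set_matrix <- function(bold, mat, step = NULL) {
  d <- dim(bold$data)
  m <- matrix(bold$data, prod(d[1:3]), d[4])
  m[as.vector(bold$mask), ] <- t(mat)
  bold$data <- array(m, d)
  if (!is.null(step)) bold$provenance <- c(bold$provenance, step)
  bold
}

#' Read / write BOLD volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti}. The voxel size is taken from / written to
#' the NIfTI header; the repetition time from `pixdim[4]`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param bold a [bold_image].
#' @param mask optional 3D logical mask attached on read.
#' @return `read_bold()` returns a [bold_image]; `write_bold()` the path,
#'   invisibly.
#' @export
read_bold <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_image(array(as.numeric(img), dim(img)),
             voxel_size_mm = pd[1],
             tr_s = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2,
             mask = mask)
}

#' @rdname read_bold
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(rep(bold$voxel_size_mm, 3), bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# write a single 3D map as NIfTI
write_map_nifti <- function(map, voxel_size_mm, path) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
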