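#' Voxel-wise functional connectivity density
#'
#' For every in-mask voxel \eqn{i}, computes the weighted connectivity
#' density: the sum of Pearson correlations \eqn{r(i,j)} over all other
#' in-mask voxels \eqn{j} with \eqn{r(i,j) > r_{thr}} (only positive
#' suprathreshold correlations contribute; the self-correlation is always
#' excluded). The sum is split by Euclidean center-to-center distance into
#'
#' * local FCD: partners with \eqn{d \le} `local_radius_mm` (on a 3 mm
#'   isotropic grid, the 3 mm sphere holds the seed plus its 6 face
#'   neighbors),
#' * distant FCD: partners with \eqn{d >} `distant_radius_mm`,
#' * a gap band (`local_radius_mm` \eqn{< d \le} `distant_radius_mm`)
#'   assigned to neither, which guarantees the two indices cannot overlap.
#'
#' Total = local + gap + distant at every voxel. The all-pairs correlation
#' matrix is processed in voxel blocks of bounded size and never fully
#' materialized; results are independent of `block_size`.
#'
#' @param bold a [bold_image] with at least 3 time points and at least 2
#'   in-mask voxels. Every in-mask voxel must have nonzero temporal
#'   variance.
#' @param r_threshold correlation threshold (default 0.25, strict `>`).
#' @param local_radius_mm,distant_radius_mm distance band edges in mm;
#'   `local_radius_mm < distant_radius_mm`.
#' @param block_size voxels per block of the streamed computation.
#' @return An object of class `fcd_maps`: 3D maps `total`, `local`, `gap`,
#'   `distant` (zero outside the mask) plus the parameters, mask and
#'   normalization/smoothing state.
#' @export
compute_fcd <- function(bold, r_threshold = 0.25, local_radius_mm = 3.0,
                        distant_radius_mm = 25.0, block_size = 256L) {
  if (local_radius_mm >= distant_radius_mm)
    stopf("local_radius_mm must be smaller than distant_radius_mm")
  nt <- n_volumes(bold)
  if (nt < 3L) stopf("need at least 3 time points")
  idx <- which(bold$mask)
  if (length(idx) < 2L) stopf("need at least 2 in-mask voxels")
  Y <- bold_matrix(bold)  # time x voxels
  Y <- sweep(Y, 2, colMeans(Y))
  nrm <- sqrt(colSums(Y^2))
  if (any(nrm == 0))
    stopf(paste("in-mask voxel(s) with zero temporal variance (first at",
                "linear index %d); correlation is undefined there --",
                "remove them from the brain mask"),
          idx[which(nrm == 0)[1]])
  Z <- sweep(Y, 2, nrm, `/`)
  coords <- voxel_coords_mm(dim(bold$mask), bold$voxel_size_mm)[, idx,
                                                                drop = FALSE]
  sums <- fcd_sums_cpp(Z, coords, r_threshold, local_radius_mm,
                       distant_radius_mm, as.integer(block_size))
  as_map <- function(v) {
    m <- array(0, dim(bold$mask))
    m[idx] <- v
    m
  }
  structure(list(total = as_map(sums$total), local = as_map(sums$local),
                 gap = as_map(sums$gap), distant = as_map(sums$distant),
                 r_threshold = r_threshold,
                 local_radius_mm = local_radius_mm,
                 distant_radius_mm = distant_radius_mm,
                 normalized = FALSE, smoothed_fwhm_mm = NULL,
                 brain_mask = bold$mask,
                 voxel_size_mm = bold$voxel_size_mm),
            class = "fcd_maps")
}

#' @export
print.fcd_maps <- function(x, ...) {
  cat(sprintf("<fcd_maps> %s grid, %d in-mask voxels\n",
              paste(dim(x$total), collapse = "x"), sum(x$brain_mask)))
  cat(sprintf("  r > %g; local <= %g mm, distant > %g mm\n", x$r_threshold,
              x$local_radius_mm, x$distant_radius_mm))
  cat(sprintf("  normalized: %s; smoothed: %s\n", x$normalized,
              if (is.null(x$smoothed_fwhm_mm)) "no"
              else paste0(x$smoothed_fwhm_mm, " mm FWHM")))
  for (m in c("total", "local", "distant"))
    cat(sprintf("  %-8s in-mask mean %.4f\n", m,
                mean(x[[m]][x$brain_mask])))
  invisible(x)
}

#' Normalize FCD maps by the global mean
#'
#' Divides each map by its own in-mask mean connectivity density, so the
#' normalized in-mask mean is exactly 1. With `divisor = "total"`, all three
#' maps are divided by the total map's mean instead (configurable because
#' either reading of "global mean connectivity density" is defensible;
#' per-map is the default).
#'
#' @param maps an `fcd_maps` object.
#' @param divisor `"per_map"` or `"total"`.
#' @return normalized `fcd_maps`.
#' @export
normalize_fcd <- function(maps, divisor = c("per_map", "total")) {
  divisor <- match.arg(divisor)
  msk <- maps$brain_mask
  total_mean <- mean(maps$total[msk])
  for (m in c("total", "local", "gap", "distant")) {
    g <- if (divisor == "per_map") mean(maps[[m]][msk]) else total_mean
    if (g <= 0)
      stopf("in-mask mean of the %s map is not positive; cannot normalize", m)
    maps[[m]] <- maps[[m]] / g
    maps[[m]][!msk] <- 0
  }
  maps$normalized <- TRUE
  maps
}

# 1D Gaussian kernel for a given FWHM in voxels; normalized to sum 1
gaussian_kernel_1d <- function(fwhm_vox) {
  sigma <- fwhm_vox / sqrt(8 * log(2))
  h <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along one axis with kernel k (zero padding)
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  h <- (length(k) - 1L) / 2L
  n <- d[axis]
  K <- matrix(0, n, n)
  for (o in -h:h) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[o + h + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- K %*% matrix(a, da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Gaussian smoothing of a 3D map
#'
#' Separable 3D Gaussian smoothing with the kernel size given as
#' full-width-at-half-maximum (FWHM = SD * sqrt(8 ln 2)). Smoothing is
#' mask-renormalized: the map and the mask are smoothed with the same kernel
#' and their ratio is taken inside the mask, which prevents attenuation at
#' the brain edge and keeps constant maps exactly constant. `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param map 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param mask 3D logical array; `NULL` smooths the full volume.
#' @return smoothed 3D array (zero outside the mask).
#' @export
smooth_map <- function(map, fwhm_mm = 8.0, voxel_size_mm = 3.0,
                       mask = NULL) {
  if (fwhm_mm < 0) stopf("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(map)
  if (is.null(mask)) mask <- array(TRUE, dim(map))
  k <- gaussian_kernel_1d(fwhm_mm / voxel_size_mm)
  num <- map * mask
  den <- mask * 1
  for (ax in 1:3) {
    num <- convolve_axis(num, k, ax)
    den <- convolve_axis(den, k, ax)
  }
  out <- array(0, dim(map))
  inside <- mask & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' Smooth all FCD maps
#'
#' Applies [smooth_map()] with the same kernel to the total, local, gap and
#' distant maps (group-analysis stage; the canonical kernel is 8 mm FWHM).
#'
#' @param maps an `fcd_maps` object.
#' @param fwhm_mm kernel FWHM in mm.
#' @return smoothed `fcd_maps`.
#' @export
smooth_fcd <- function(maps, fwhm_mm = 8.0) {
  for (m in c("total", "local", "gap", "distant"))
    maps[[m]] <- smooth_map(maps[[m]], fwhm_mm, maps$voxel_size_mm,
                            maps$brain_mask)
  maps$smoothed_fwhm_mm <- fwhm_mm
  maps
}

#' Write FCD maps as NIfTI-1 with a JSON sidecar
#'
#' Writes `<prefix>_totalFCD.nii.gz`, `<prefix>_lFCD.nii.gz` and
#' `<prefix>_dFCD.nii.gz` plus `<prefix>_fcd.json` recording the parameters
#' and processing state.
#'
#' @param maps an `fcd_maps` object.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_fcd_maps <- function(maps, prefix) {
  paths <- c(
    total = paste0(prefix, "_totalFCD.nii.gz"),
    local = paste0(prefix, "_lFCD.nii.gz"),
    distant = paste0(prefix, "_dFCD.nii.gz"))
  write_map_nifti(maps$total, maps$voxel_size_mm, paths["total"])
  write_map_nifti(maps$local, maps$voxel_size_mm, paths["local"])
  write_map_nifti(maps$distant, maps$voxel_size_mm, paths["distant"])
  meta <- list(r_threshold = maps$r_threshold,
               local_radius_mm = maps$local_radius_mm,
               distant_radius_mm = maps$distant_radius_mm,
               normalized = maps$normalized,
               smoothed_fwhm_mm = maps$smoothed_fwhm_mm,
               voxel_size_mm = maps$voxel_size_mm)
  jsonlite::write_json(meta, paste0(prefix, "_fcd.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(c(paths, json = paste0(prefix, "_fcd.json")))
}
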