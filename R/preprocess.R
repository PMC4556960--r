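#' Motion trace accessor
#'
#' Splits a 6-column motion-parameter matrix (three translations in mm,
#' three rotations in degrees, one row per retained volume) into its two
#' blocks.
#'
#' @param motion numeric matrix, volumes x 6.
#' @return list with `translations_mm` and `rotations_deg` matrices.
#' @export
motion_trace <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion trace must have 6 columns")
  if (nrow(motion) < 1L) stopf("motion trace is empty")
  list(translations_mm = motion[, 1:3, drop = FALSE],
       rotations_deg = motion[, 4:6, drop = FALSE])
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes (signal-equilibration scans) from a BOLD run.
#'
#' @param bold a [bold_image].
#' @param n number of leading volumes to discard (default 10).
#' @return the shortened [bold_image], with provenance appended.
#' @export
discard_initial_volumes <- function(bold, n = 10L) {
  nt <- n_volumes(bold)
  if (n >= nt) stopf("cannot discard %d of %d volumes", n, nt)
  if (n > 0L) {
    bold$data <- bold$data[, , , -seq_len(n), drop = FALSE]
    bold$provenance <- c(bold$provenance, sprintf("discard_initial:%d", n))
  }
  bold
}

#' Per-voxel linear detrending
#'
#' Removes the least-squares line (intercept + slope over scan time) from
#' every in-mask voxel series; the residual series have exactly zero mean and
#' zero linear trend. Masked-out voxels are untouched.
#'
#' @param bold a [bold_image] with at least 3 time points.
#' @return detrended [bold_image].
#' @export
detrend_linear <- function(bold) {
  nt <- n_volumes(bold)
  if (nt < 3L) stopf("detrending needs at least 3 time points")
  Y <- bold_matrix(bold)
  tt <- seq_len(nt) - (nt + 1) / 2  # centered time, orthogonal to intercept
  slope <- crossprod(tt, Y) / sum(tt^2)
  Y <- sweep(Y, 2, colMeans(Y)) - outer(tt, drop(slope))
  bold_set_matrix(bold, Y, "detrend_linear")
}

# ideal (boxcar) frequency-domain filter on the columns of a T x n matrix;
# DFT bins with low_hz <= |f| <= high_hz are kept, all others zeroed
fft_band_filter <- function(x, tr_s, low_hz, high_hz) {
  nt <- nrow(x)
  f <- pmin(seq_len(nt) - 1L, nt - (seq_len(nt) - 1L)) / (nt * tr_s)
  keep <- f >= low_hz & f <= high_hz
  X <- mvfft(x)
  X[!keep, ] <- 0
  Re(mvfft(X, inverse = TRUE)) / nt
}

#' Temporal bandpass filtering
#'
#' Ideal (boxcar) frequency-domain filter, the contract used by classic
#' resting-state toolboxes: DFT bins whose frequency lies inside
#' `[low_hz, high_hz]` are kept exactly, all others (including the DC
#' component) are zeroed. Output length is unchanged and the operation is
#' idempotent.
#'
#' @param bold a [bold_image].
#' @param low_hz,high_hz passband edges in Hz; require
#'   `0 <= low_hz < high_hz <= 1 / (2 * tr_s)`.
#' @return filtered [bold_image].
#' @export
bandpass_filter <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  nyquist <- 1 / (2 * bold$tr_s)
  if (low_hz < 0 || low_hz >= high_hz)
    stopf("require 0 <= low_hz < high_hz")
  if (high_hz > nyquist)
    stopf("high_hz (%g) exceeds the Nyquist frequency (%g Hz)",
          high_hz, nyquist)
  Y <- fft_band_filter(bold_matrix(bold), bold$tr_s, low_hz, high_hz)
  bold_set_matrix(bold, Y, sprintf("bandpass:%g-%g", low_hz, high_hz))
}

#' Nuisance regression
#'
#' Removes spurious variance by ordinary least squares: each in-mask voxel
#' series is replaced by its residual after regression on an intercept, the
#' six rigid-body motion parameters, the mean cerebrospinal-fluid signal, the
#' mean white-matter signal and (optionally) the global mean over the brain
#' mask. Nuisance means are computed from the current (i.e. already
#' filtered) data over the supplied masks; masked-out voxels never
#' contribute. Residuals are orthogonal to every regressor.
#'
#' @param bold a [bold_image].
#' @param motion volumes x 6 motion-parameter matrix, or `NULL` to omit.
#' @param csf_mask,wm_mask 3D logical masks, or `NULL` to omit that
#'   regressor.
#' @param use_global include global-signal regression (the default, matching
#'   common practice, but deliberately exposed because the step is
#'   controversial).
#' @return residualized [bold_image].
#' @export
regress_nuisance <- function(bold, motion = NULL, csf_mask = NULL,
                             wm_mask = NULL, use_global = TRUE) {
  nt <- n_volumes(bold)
  Y <- bold_matrix(bold)
  X <- matrix(1, nt, 1)
  cn <- "intercept"
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) stopf("motion trace must have 6 columns")
    if (nrow(motion) != nt)
      stopf("motion trace has %d rows but data has %d volumes",
            nrow(motion), nt)
    X <- cbind(X, motion)
    cn <- c(cn, paste0("motion", 1:6))
  }
  mean_over <- function(m) {
    if (sum(m) == 0) stopf("tissue mask is empty")
    d <- dim(bold$data)
    colMeans(matrix(bold$data, prod(d[1:3]), d[4])[as.vector(m), ,
                                                   drop = FALSE])
  }
  if (!is.null(csf_mask)) { X <- cbind(X, mean_over(csf_mask)); cn <- c(cn, "csf") }
  if (!is.null(wm_mask)) { X <- cbind(X, mean_over(wm_mask)); cn <- c(cn, "wm") }
  if (use_global) { X <- cbind(X, mean_over(bold$mask)); cn <- c(cn, "global") }
  colnames(X) <- cn
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- cn[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stopf("nuisance design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  Y <- Y - X %*% qr.coef(qrX, Y)
  bold_set_matrix(bold, Y, sprintf("regress_nuisance:%s",
                                   paste(cn[-1], collapse = "+")))
}

#' Motion-based subject exclusion
#'
#' Flags a run for exclusion when head motion exceeds 1.0 mm in any
#' translation or 1.0 degree in any rotation at any volume (strict
#' inequalities: motion of exactly 1.0 mm is retained).
#'
#' @param motion volumes x 6 motion matrix.
#' @param max_trans_mm,max_rot_deg exclusion limits.
#' @return logical: `TRUE` if the subject should be excluded.
#' @export
motion_excluded <- function(motion, max_trans_mm = 1.0, max_rot_deg = 1.0) {
  tr <- motion_trace(motion)
  any(abs(tr$translations_mm) > max_trans_mm) ||
    any(abs(tr$rotations_deg) > max_rot_deg)
}

#' Framewise displacement
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the six motion parameters, with rotations converted from
#' degrees to mm of arc on a 50 mm sphere. The first volume has FD 0 by
#' convention.
#'
#' @param motion volumes x 6 motion matrix.
#' @param rotation_radius_mm sphere radius for the rotation-to-mm conversion.
#' @return numeric vector of per-volume FD values (mm).
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  tr <- motion_trace(motion)
  mm <- cbind(tr$translations_mm,
              tr$rotations_deg * pi / 180 * rotation_radius_mm)
  if (nrow(mm) == 1L) return(0)
  c(0, rowSums(abs(diff(mm))))
}

#' Count motion spikes
#'
#' Number of volumes whose framewise displacement exceeds `fd_threshold_mm`
#' (strictly).
#'
#' @param motion volumes x 6 motion matrix.
#' @param fd_threshold_mm positive FD threshold in mm (default 0.5).
#' @return integer spike count.
#' @export
count_motion_spikes <- function(motion, fd_threshold_mm = 0.5) {
  if (fd_threshold_mm <= 0) stopf("fd_threshold_mm must be positive")
  sum(framewise_displacement(motion) > fd_threshold_mm)
}

#' Standard preprocessing pipeline
#'
#' Applies, in the fixed order the analysis assumes: initial-volume
#' discarding, per-voxel linear detrending, ideal bandpass filtering, and
#' nuisance regression. The motion trace is truncated to the retained
#' volumes. The applied steps are recorded in the returned image's
#' provenance.
#'
#' @param bold a [bold_image].
#' @param motion volumes x 6 motion matrix (full length; leading rows are
#'   dropped along with the discarded volumes), or `NULL`.
#' @param n_discard,low_hz,high_hz,csf_mask,wm_mask,use_global stage
#'   parameters, see the individual steps.
#' @return list with `bold` (preprocessed) and `motion` (truncated trace).
#' @export
preprocess_bold <- function(bold, motion = NULL, n_discard = 10L,
                            low_hz = 0.01, high_hz = 0.08, csf_mask = NULL,
                            wm_mask = NULL, use_global = TRUE) {
  bold <- discard_initial_volumes(bold, n_discard)
  if (!is.null(motion) && n_discard > 0L)
    motion <- motion[-seq_len(n_discard), , drop = FALSE]
  bold <- detrend_linear(bold)
  bold <- bandpass_filter(bold, low_hz, high_hz)
  bold <- regress_nuisance(bold, motion = motion, csf_mask = csf_mask,
                           wm_mask = wm_mask, use_global = use_global)
  list(bold = bold, motion = motion)
}
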