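#' Family-wise error calibration experiment
#'
#' Repeatedly simulates effect-free cohorts (all group multipliers equal to
#' 1, so group labels are exchangeable), runs each through the standard
#' pipeline (preprocessing, FCD, per-map normalization, smoothing,
#' covariate-adjusted ANOVA, cluster-extent correction), and reports the
#' fraction of replicates with at least one surviving cluster. With a
#' calibrated extent threshold this fraction should match `alpha`.
#'
#' The default problem size (three groups of 8, a 12-voxel cube at 3 mm,
#' 100 volumes) keeps one replicate around a second so that hundreds of
#' replicates run on a desk machine; the cluster-extent threshold is
#' computed once (same mask and parameters for every replicate) with the
#' ANOVA-field null model.
#'
#' @param n_replicates number of simulated cohorts.
#' @param group_size subjects per group.
#' @param grid_shape,n_volumes cohort geometry.
#' @param voxel_p,alpha,connectivity,n_iterations cluster-correction
#'   parameters.
#' @param smooth_fwhm_mm smoothing kernel applied to the subject maps and
#'   assumed by the null.
#' @param which map component tested.
#' @param seed root seed.
#' @return list with `fwer`, logical `hits` per replicate, the
#'   `extent_threshold` used, and the binomial 95% band around `alpha`.
#' @export
null_calibration <- function(n_replicates = 500L, group_size = 8L,
                             grid_shape = c(12L, 12L, 12L),
                             n_volumes = 100L, voxel_p = 0.05,
                             alpha = 0.05, connectivity = 18L,
                             n_iterations = 1000L, smooth_fwhm_mm = 8.0,
                             which = "total", seed = 1L) {
  mask <- array(TRUE, grid_shape)
  spec <- connectivity_spec(
    grid_shape = grid_shape, n_volumes = n_volumes,
    hub_seeds = list(
      hub_seed(c(2L, 2L, grid_shape[3] %/% 2L), "subcortical", pair = 1L),
      hub_seed(grid_shape - c(1L, 1L, grid_shape[3] %/% 2L + 1L) + c(0L, 0L, 1L),
               "subcortical", pair = 1L)),
    local_coupling = 0.9, distant_coupling = 0.3)
  cc <- cohort_config(group_size, group_size, group_size, spec = spec,
                      effects = list(control = group_effects("control"),
                                     nonHE = group_effects("nonHE"),
                                     MHE = group_effects("MHE")))
  seeds <- derive_seeds(seed, n_replicates + 1L)
  mc <- monte_carlo_extent_threshold(
    mask, voxel_p, smooth_fwhm_mm, spec$voxel_size_mm, connectivity,
    alpha, n_iterations, seed = seeds[1L], null_model = "anova",
    groups = rep(c("control", "nonHE", "MHE"), each = group_size),
    n_covariates = 3L)
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_cohort(cc, seed = seeds[r + 1L])
    keep <- which(sim$records$included)
    maps <- vector("list", length(keep))
    for (ii in seq_along(keep)) {
      i <- keep[ii]
      pp <- preprocess_bold(sim$bold[[i]], sim$motion[[i]])
      f <- normalize_fcd(compute_fcd(pp$bold))
      maps[[ii]] <- smooth_map(f[[which]], smooth_fwhm_mm,
                               spec$voxel_size_mm, mask)
    }
    recs <- sim$records[keep, ]
    covs <- data.frame(age_y = recs$age_y,
                       sex01 = as.integer(recs$sex == "M"),
                       education_y = recs$education_y)
    an <- one_way_anova(maps, recs$group, mask, covs)
    cl <- extract_clusters(an, voxel_p, mc$extent_threshold, connectivity,
                           spec$voxel_size_mm)
    hits[r] <- nrow(cl) > 0L
  }
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_replicates)
  list(fwer = mean(hits), hits = hits,
       extent_threshold = mc$extent_threshold,
       binom_band = c(alpha - half, alpha + half), alpha = alpha,
       n_replicates = n_replicates)
}

# planted-effect cohort used by the recovery experiment: one long-range
# subcortical pair plus two unpaired local hubs on a 14-voxel cube. Regions
# use a 6 mm radius (33 voxels) so the planted effects are spatially
# extended enough to form clusters, and seeds sit so that cross-pair member
# distances stay beyond the 25 mm distant radius.
recovery_cohort <- function(group_size, n_volumes) {
  spec <- connectivity_spec(
    grid_shape = c(14L, 14L, 14L), n_volumes = n_volumes,
    hub_seeds = list(
      hub_seed(c(3L, 3L, 7L), "subcortical", pair = 1L),
      hub_seed(c(12L, 12L, 7L), "subcortical", pair = 1L),
      hub_seed(c(3L, 12L, 7L), "cortical"),
      hub_seed(c(12L, 3L, 7L), "cortical")),
    local_coupling = c(0.9, 0.9, 0.6, 0.6), distant_coupling = 0.3,
    region_radius_mm = 6)
  cohort_config(
    group_size, group_size, group_size, spec = spec,
    effects = list(
      control = group_effects("control"),
      nonHE = group_effects("nonHE", local_coupling_multiplier = 0.6),
      MHE = group_effects("MHE", local_coupling_multiplier = 0.6,
                          distant_subcortical_multiplier = 1.8)))
}

#' Planted-effect recovery experiment
#'
#' Simulates cohorts with the package's canonical planted group pattern --
#' a shared local-coupling deficit in both patient groups (multiplier 0.6)
#' and an MHE-only distant-coupling increase at the two subcortical hubs
#' (multiplier 1.8, planted cross-correlation 0.54 vs 0.30) -- and checks
#' whether the pipeline's ANOVA + post-hoc contrasts recover the expected
#' qualitative pattern in each replicate:
#'
#' 1. local FCD: an ANOVA cluster overlaps the planted hub regions, the
#'    control > non-HE and control > MHE contrasts survive there, and
#'    no MHE vs non-HE cluster survives there (no local difference between
#'    patient groups);
#' 2. distant FCD: MHE > control and MHE > non-HE clusters overlap the
#'    subcortical pair regions, and no non-HE > control increase survives
#'    there.
#'
#' @param n_replicates number of simulated cohorts.
#' @param group_size subjects per group.
#' @param n_volumes volumes per subject (10 are discarded).
#' @param voxel_p,alpha,connectivity,n_iterations,smooth_fwhm_mm analysis
#'   parameters.
#' @param seed root seed.
#' @return list with `recovery_rate`, the per-check success rates
#'   (`checks`), and the per-replicate outcome matrix.
#' @export
pattern_recovery <- function(n_replicates = 50L, group_size = 10L,
                             n_volumes = 250L, voxel_p = 0.05,
                             alpha = 0.05, connectivity = 18L,
                             n_iterations = 1000L, smooth_fwhm_mm = 8.0,
                             seed = 1L) {
  cc <- recovery_cohort(group_size, n_volumes)
  spec <- cc$spec
  mask <- array(TRUE, spec$grid_shape)
  vs <- spec$voxel_size_mm
  regions <- hub_regions(spec)
  local_vox <- sort(unique(unlist(regions)))       # all planted regions
  subcort_vox <- sort(unique(unlist(regions[1:2])))  # the distant pair
  seeds <- derive_seeds(seed, n_replicates + 2L)
  groups <- rep(c("control", "nonHE", "MHE"), each = group_size)
  mc3 <- monte_carlo_extent_threshold(
    mask, voxel_p, smooth_fwhm_mm, vs, connectivity, alpha, n_iterations,
    seed = seeds[1L], null_model = "anova", groups = groups,
    n_covariates = 3L)
  mc2 <- monte_carlo_extent_threshold(
    mask, voxel_p, smooth_fwhm_mm, vs, connectivity, alpha, n_iterations,
    seed = seeds[2L], null_model = "anova",
    groups = rep(c("a", "b"), each = group_size), n_covariates = 3L)

  check_names <- c("local_anova_at_hubs", "local_control_gt_nonhe",
                   "local_control_gt_mhe", "local_no_mhe_nonhe_diff",
                   "distant_mhe_gt_control", "distant_mhe_gt_nonhe",
                   "distant_no_nonhe_increase")
  checks <- matrix(NA, n_replicates, length(check_names),
                   dimnames = list(NULL, check_names))
  # an effect "appears at" a planted site when a surviving cluster peaks
  # within one smoothing-kernel width of it: smoothing legitimately
  # displaces statistic peaks into the low-variance halo around a planted
  # region, while false-positive clusters peak anywhere in the volume
  # (same rule for expected and null contrasts)
  site_coords <- function(vox)
    t(lin_to_ijk(vox, spec$grid_shape) - 1) * vs
  peaks_at <- function(cl, site_xyz, tol_mm = smooth_fwhm_mm) {
    if (nrow(cl) == 0L) return(FALSE)
    for (i in seq_len(nrow(cl))) {
      d2 <- colSums((site_xyz - c(cl$peak_x_mm[i], cl$peak_y_mm[i],
                                  cl$peak_z_mm[i]))^2)
      if (min(d2) <= tol_mm^2) return(TRUE)
    }
    FALSE
  }
  local_xyz <- site_coords(local_vox)
  subcort_xyz <- site_coords(subcort_vox)
  overlaps <- function(cl, vox)
    peaks_at(cl, if (identical(vox, local_vox)) local_xyz else subcort_xyz)
  surviving <- function(stat, alt, thr)
    extract_clusters(stat, voxel_p, thr, connectivity, vs,
                     alternative = alt)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_cohort(cc, seed = seeds[r + 2L])
    keep <- which(sim$records$included)
    maps_l <- vector("list", length(keep))
    maps_d <- vector("list", length(keep))
    for (ii in seq_along(keep)) {
      i <- keep[ii]
      # global-signal regression off: with planted shared latents the
      # global mean is itself group-dependent, and removing it leaks the
      # planted couplings into diffuse secondary group differences (the
      # classic GSR artifact; see the methods vignette)
      pp <- preprocess_bold(sim$bold[[i]], sim$motion[[i]],
                            use_global = FALSE)
      # unnormalized maps: the generator produces scale-calibrated subjects
      # (unit-variance series), and on sparse synthetic maps any
      # global-mean divisor carries the planted mass itself, coupling the
      # planted deficits into a whole-brain offset that masquerades as a
      # group effect (see the methods vignette)
      f <- compute_fcd(pp$bold)
      maps_l[[ii]] <- smooth_map(f$local, smooth_fwhm_mm, vs, mask)
      maps_d[[ii]] <- smooth_map(f$distant, smooth_fwhm_mm, vs, mask)
    }
    recs <- sim$records[keep, ]
    gr <- recs$group
    covs <- data.frame(age_y = recs$age_y,
                       sex01 = as.integer(recs$sex == "M"),
                       education_y = recs$education_y)

    an_l <- one_way_anova(maps_l, gr, mask, covs)
    cl_l <- surviving(an_l, "two.sided", mc3$extent_threshold)
    checks[r, "local_anova_at_hubs"] <- overlaps(cl_l, local_vox)
    sig_l <- attr(cl_l, "label_map") > 0L
    if (any(sig_l)) {
      ph <- function(pair) posthoc_t(maps_l, gr, pair, sig_l, mask, covs)
      checks[r, "local_control_gt_nonhe"] <- overlaps(
        surviving(ph(c("control", "nonHE")), "greater",
                  mc2$extent_threshold), local_vox)
      checks[r, "local_control_gt_mhe"] <- overlaps(
        surviving(ph(c("control", "MHE")), "greater",
                  mc2$extent_threshold), local_vox)
      checks[r, "local_no_mhe_nonhe_diff"] <- !overlaps(
        surviving(ph(c("MHE", "nonHE")), "two.sided",
                  mc2$extent_threshold), local_vox)
    } else {
      checks[r, c("local_control_gt_nonhe", "local_control_gt_mhe")] <- FALSE
      checks[r, "local_no_mhe_nonhe_diff"] <- TRUE
    }

    an_d <- one_way_anova(maps_d, gr, mask, covs)
    cl_d <- surviving(an_d, "two.sided", mc3$extent_threshold)
    sig_d <- attr(cl_d, "label_map") > 0L
    if (any(sig_d)) {
      phd <- function(pair) posthoc_t(maps_d, gr, pair, sig_d, mask, covs)
      checks[r, "distant_mhe_gt_control"] <- overlaps(
        surviving(phd(c("MHE", "control")), "greater",
                  mc2$extent_threshold), subcort_vox)
      checks[r, "distant_mhe_gt_nonhe"] <- overlaps(
        surviving(phd(c("MHE", "nonHE")), "greater",
                  mc2$extent_threshold), subcort_vox)
      checks[r, "distant_no_nonhe_increase"] <- !overlaps(
        surviving(phd(c("nonHE", "control")), "greater",
                  mc2$extent_threshold), subcort_vox)
    } else {
      checks[r, c("distant_mhe_gt_control", "distant_mhe_gt_nonhe")] <- FALSE
      checks[r, "distant_no_nonhe_increase"] <- TRUE
    }
  }
  success <- apply(checks, 1, all)
  list(recovery_rate = mean(success), checks = colMeans(checks),
       outcome = checks, n_replicates = n_replicates,
       extent_thresholds = c(anova = mc3$extent_threshold,
                             posthoc = mc2$extent_threshold))
}
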