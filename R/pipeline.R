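#' Pipeline configuration
#'
#' All tunable parameters of the analysis, with defaults set to the
#' canonical values of the method: 10 discarded volumes, 0.01-0.08 Hz
#' passband, global-signal regression on, 1.0 mm / 1.0 degree motion
#' exclusion, correlation threshold r = 0.25, 3 mm local radius, 25 mm
#' distant radius, per-map global-mean normalization, 8 mm smoothing,
#' voxel-level p < 0.05 with alpha = 0.05 cluster-extent correction
#' (18-connectivity, 1000 Monte-Carlo iterations), and a 0.05 family level
#' for the regional correlations. Unknown keys are rejected; the object
#' serializes losslessly to YAML via [write_fcd_config()].
#'
#' @param ... named overrides of any default.
#' @return object of class `fcd_config` (a validated named list).
#' @export
fcd_config <- function(...) {
  defaults <- list(
    # cohort / acquisition
    n_control = 103L, n_nonhe = 69L, n_mhe = 34L,
    grid_shape = c(20L, 20L, 20L), voxel_size_mm = 3, n_volumes = 250L,
    tr_s = 2,
    # preprocessing
    n_discard = 10L, low_hz = 0.01, high_hz = 0.08, use_global = TRUE,
    max_trans_mm = 1.0, max_rot_deg = 1.0, fd_threshold_mm = 0.5,
    # FCD metric
    r_threshold = 0.25, local_radius_mm = 3.0, distant_radius_mm = 25.0,
    normalize_divisor = "per_map", smooth_fwhm_mm = 8.0,
    # group inference
    voxel_p = 0.05, alpha = 0.05, connectivity = 18L,
    n_iterations = 1000L,
    # regional correlations
    correlation_alpha = 0.05)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  stopifnot(cfg$low_hz >= 0, cfg$low_hz < cfg$high_hz,
            cfg$r_threshold > 0, cfg$local_radius_mm < cfg$distant_radius_mm,
            cfg$voxel_p > 0, cfg$voxel_p < 1, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$connectivity %in% c(6L, 18L, 26L))
  structure(cfg, class = "fcd_config")
}

#' Read / write a pipeline configuration
#'
#' YAML serialization of an [fcd_config()]. Reading validates the keys, so
#' a file with unknown keys is rejected; a write/read round trip returns an
#' identical configuration.
#'
#' @param config an `fcd_config`.
#' @param path file path.
#' @return `read_fcd_config()` returns an `fcd_config`;
#'   `write_fcd_config()` the path, invisibly.
#' @export
write_fcd_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_fcd_config
#' @export
read_fcd_config <- function(path) {
  vals <- yaml::read_yaml(path)
  ints <- c("n_control", "n_nonhe", "n_mhe", "grid_shape", "n_volumes",
            "n_discard", "connectivity", "n_iterations")
  for (k in intersect(ints, names(vals))) vals[[k]] <- as.integer(vals[[k]])
  do.call(fcd_config, vals)
}

stage <- function(name, subject = NULL, expr) {
  tryCatch(expr, error = function(e) {
    who <- if (is.null(subject)) "" else sprintf(" (subject %s)", subject)
    stopf("pipeline stage '%s'%s failed: %s", name, who,
          conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage end-to-end on a synthetic cohort: simulation,
#' motion quality control, preprocessing, FCD mapping with normalization
#' and smoothing, covariate-adjusted ANOVA with Monte-Carlo cluster-extent
#' correction and post-hoc contrasts for each map type, regional
#' correlations within each patient group, and the demographic table. All
#' outputs (CSV/TSV tables, optional NIfTI maps, provenance log) go to
#' `out_dir`; re-running with the same configuration and seed reproduces
#' them exactly.
#'
#' @param config an [fcd_config()].
#' @param seed root seed for the run.
#' @param out_dir output directory.
#' @param cohort optional [cohort_config()]; by default one is built from
#'   the configuration's cohort and grid settings with the default hub
#'   layout.
#' @param write_nifti also write per-subject FCD maps as NIfTI (off by
#'   default to keep runs light).
#' @return list with `records`, `table1`, per-map-type `anova` cluster
#'   tables, `posthoc` results and `correlations`, invisibly.
#' @export
run_pipeline <- function(config = fcd_config(), seed = 1L, out_dir,
                         cohort = NULL, write_nifti = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    if (any(config$grid_shape < 17L))
      stopf(paste("the default hub layout needs a grid of at least 17",
                  "voxels per axis; pass a custom `cohort`"))
    cohort <- cohort_config(
      n_control = config$n_control, n_nonhe = config$n_nonhe,
      n_mhe = config$n_mhe,
      spec = connectivity_spec(
        grid_shape = config$grid_shape,
        voxel_size_mm = config$voxel_size_mm,
        n_volumes = config$n_volumes, tr_s = config$tr_s,
        hub_seeds = default_hub_layout(),
        local_coupling = c(0.9, 0.9, 0.9, 0.9, 0.6, 0.6),
        distant_coupling = 0.3))
  }

  sim <- stage("simulate", NULL, simulate_cohort(cohort, seed = seed))
  records <- sim$records
  records$n_spikes <- vapply(sim$motion, function(m)
    as.integer(count_motion_spikes(m, config$fd_threshold_mm)), integer(1))
  keep <- which(records$included)

  maps <- vector("list", length(keep))
  names(maps) <- records$subject_id[keep]
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    id <- records$subject_id[i]
    pp <- stage("preprocess", id, preprocess_bold(
      sim$bold[[i]], sim$motion[[i]], n_discard = config$n_discard,
      low_hz = config$low_hz, high_hz = config$high_hz,
      use_global = config$use_global))
    m <- stage("fcd", id, {
      f <- compute_fcd(pp$bold, r_threshold = config$r_threshold,
                       local_radius_mm = config$local_radius_mm,
                       distant_radius_mm = config$distant_radius_mm)
      f <- normalize_fcd(f, divisor = config$normalize_divisor)
      smooth_fcd(f, config$smooth_fwhm_mm)
    })
    if (write_nifti) {
      dir.create(file.path(out_dir, "fcd"), showWarnings = FALSE)
      write_fcd_maps(m, file.path(out_dir, "fcd", id))
    }
    maps[[ii]] <- m
  }
  recs <- records[keep, ]
  groups <- recs$group
  covs <- data.frame(age_y = recs$age_y, sex01 = as.integer(recs$sex == "M"),
                     education_y = recs$education_y)
  mask <- maps[[1]]$brain_mask

  null_thr <- stage("cluster_null", NULL, monte_carlo_extent_threshold(
    mask, voxel_p = config$voxel_p,
    smoothness_fwhm_mm = config$smooth_fwhm_mm,
    voxel_size_mm = config$voxel_size_mm,
    connectivity = config$connectivity, alpha = config$alpha,
    n_iterations = config$n_iterations, seed = seed + 1L,
    null_model = "anova", groups = groups, n_covariates = 3L))

  jsonlite::write_json(
    list(voxel_p = null_thr$voxel_p, alpha = null_thr$alpha,
         n_iterations = null_thr$n_iterations,
         smoothness_fwhm_mm = null_thr$smoothness_fwhm_mm,
         connectivity = null_thr$connectivity,
         null_model = null_thr$null_model, seed = null_thr$seed,
         extent_threshold = null_thr$extent_threshold,
         max_cluster_sizes = null_thr$max_cluster_sizes),
    file.path(out_dir, "cluster_null.json"), auto_unbox = TRUE)

  results <- list(records = records, cluster_null = null_thr,
                  anova = list(), posthoc = list(), correlations = list())
  pairs <- list(c("control", "nonHE"), c("control", "MHE"),
                c("nonHE", "MHE"))
  for (mt in c("total", "local", "distant")) {
    an <- stage(paste0("anova_", mt), NULL, one_way_anova(
      maps, groups, mask, covariates = covs, which = mt))
    cl <- extract_clusters(an, config$voxel_p, null_thr$extent_threshold,
                           config$connectivity, config$voxel_size_mm)
    results$anova[[mt]] <- cl
    write.csv(as.data.frame(cl),
              file.path(out_dir, sprintf("anova_%sFCD_clusters.csv", mt)),
              row.names = FALSE)
    sig_mask <- attr(cl, "label_map") > 0L
    if (any(sig_mask)) for (pr in pairs) {
      key <- sprintf("%s_%s_vs_%s", mt, pr[1], pr[2])
      results$posthoc[[key]] <- stage(paste0("posthoc_", key), NULL,
        posthoc_t(maps, groups, pr, sig_mask, mask, covariates = covs,
                  which = mt))
    }
    if (nrow(cl) > 0L) {
      rm_mat <- extract_region_means(maps, attr(cl, "label_map"), which = mt)
      for (g in c("nonHE", "MHE")) {
        gsel <- groups == g
        if (sum(gsel) < 6L) next
        clin <- cbind(recs[gsel, c("age_y", "education_y", "nct_a_s",
                                   "dst_score", "ammonia_umol_l")],
                      sex01 = as.integer(recs$sex[gsel] == "M"))
        cors <- stage(paste0("correlate_", mt, "_", g), NULL,
          correlate_regions(rm_mat[gsel, , drop = FALSE], clin,
                            variables = c("nct_a_s", "dst_score",
                                          "ammonia_umol_l"),
                            alpha = config$correlation_alpha))
        results$correlations[[paste(mt, g, sep = "_")]] <- cors
        write.csv(cors, file.path(out_dir,
                                  sprintf("correlations_%sFCD_%s.csv",
                                          mt, g)), row.names = FALSE)
      }
    }
  }
  results$table1 <- stage("table1", NULL, build_table1(records))
  write.csv(as.data.frame(results$table1),
            file.path(out_dir, "table1.csv"), row.names = FALSE)
  write.table(records, file.path(out_dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_fcd_config(config, cfg_path)
  prov <- c(sprintf("fcdmap %s", as.character(utils::packageVersion("fcdmap"))),
            sprintf("seed: %d", seed),
            sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
            sprintf("subjects simulated: %d, included: %d",
                    nrow(records), length(keep)),
            sprintf("extent threshold: %d voxels",
                    null_thr$extent_threshold))
  writeLines(prov, file.path(out_dir, "provenance.log"))
  invisible(results)
}
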