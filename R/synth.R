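#' Hub seed specification
#'
#' A hub is a small spherical region (the seed voxel plus its neighborhood
#' within `region_radius_mm`) whose member voxels share a latent band-limited
#' signal. Hubs carrying the same `pair` id additionally share a second
#' latent, which plants long-range (distant) correlation between the two
#' regions.
#'
#' @param voxel integer triple, seed voxel index (1-based).
#' @param role `"cortical"` or `"subcortical"`; selects which distant-coupling
#'   multiplier of [group_effects()] applies.
#' @param pair optional pair id (integer); hubs sharing an id are coupled at
#'   long range. `NA` for a purely local hub.
#' @export
hub_seed <- function(voxel, role = c("cortical", "subcortical"), pair = NA) {
  role <- match.arg(role)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L) stopf("`voxel` must be an integer triple")
  list(voxel = voxel, role = role, pair = pair)
}

#' Synthetic-acquisition specification
#'
#' Defines the grid, timing and planted correlation structure of a synthetic
#' resting-state acquisition. The signal model is a latent-mixture with an
#' analytically known correlation structure: a member voxel of hub \eqn{h}
#' (belonging to pair \eqn{p}) is
#' \deqn{x = \sqrt{c_d}\, v_p + \sqrt{c_l - c_d}\, u_h + \sqrt{1 - c_l}\,
#'   \epsilon,}
#' where \eqn{v_p}, \eqn{u_h} and \eqn{\epsilon} are independent unit-variance
#' band-limited Gaussian series. Hence the planted pairwise correlation is
#' \eqn{c_l} within a hub region and \eqn{\sqrt{c_{d,i} c_{d,j}}} between
#' members of paired regions; background voxels are independent noise. All
#' latent signals are band-limited inside the analysis passband so that
#' bandpass filtering preserves the planted structure. The model requires
#' \eqn{c_d \le c_l \le 1} after group multipliers are applied.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_volumes number of volumes (>= 2).
#' @param tr_s repetition time, seconds.
#' @param hub_seeds list of [hub_seed()] entries.
#' @param local_coupling within-region pairwise correlation in \[0,1\]; scalar
#'   or one value per hub.
#' @param distant_coupling between-region pairwise correlation in \[0,1\] for
#'   paired hubs; scalar or one value per hub.
#' @param noise_sd positive scale of the generated series.
#' @param signal_band two frequencies (Hz) bounding the latent passband.
#' @param region_radius_mm radius of the hub neighborhood driven by the hub
#'   latent.
#' @param min_pair_distance_mm paired seeds closer than this raise an error
#'   when a distant effect is requested (the planted effect would fall inside
#'   the local/distant gap band).
#' @param motion_sd_mm,motion_sd_deg per-volume random-walk step of the
#'   simulated motion trace.
#' @param n_motion_spikes,spike_amplitude_mm number and size of injected
#'   abrupt displacements.
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(grid_shape = c(20L, 20L, 20L),
                              voxel_size_mm = 3,
                              n_volumes = 250L,
                              tr_s = 2,
                              hub_seeds = list(),
                              local_coupling = 0.6,
                              distant_coupling = 0.3,
                              noise_sd = 1,
                              signal_band = c(0.01, 0.08),
                              region_radius_mm = 3,
                              min_pair_distance_mm = 25,
                              motion_sd_mm = 0.02,
                              motion_sd_deg = 0.02,
                              n_motion_spikes = 0L,
                              spike_amplitude_mm = 0.3) {
  grid_shape <- as.integer(grid_shape)
  nh <- length(hub_seeds)
  local_coupling <- rep_len(local_coupling, max(nh, 1L))
  distant_coupling <- rep_len(distant_coupling, max(nh, 1L))
  if (n_volumes < 2L) stopf("n_volumes must be >= 2")
  if (voxel_size_mm <= 0 || tr_s <= 0 || noise_sd <= 0)
    stopf("voxel_size_mm, tr_s and noise_sd must be positive")
  if (any(local_coupling < 0 | local_coupling > 1) ||
      any(distant_coupling < 0 | distant_coupling > 1))
    stopf("couplings must lie in [0, 1]")
  for (h in hub_seeds) {
    if (any(h$voxel < 1L) || any(h$voxel > grid_shape))
      stopf("hub seed (%s) lies outside the %s grid",
            paste(h$voxel, collapse = ","),
            paste(grid_shape, collapse = "x"))
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_volumes = as.integer(n_volumes), tr_s = tr_s,
                 hub_seeds = hub_seeds, local_coupling = local_coupling,
                 distant_coupling = distant_coupling, noise_sd = noise_sd,
                 signal_band = signal_band,
                 region_radius_mm = region_radius_mm,
                 min_pair_distance_mm = min_pair_distance_mm,
                 motion_sd_mm = motion_sd_mm, motion_sd_deg = motion_sd_deg,
                 n_motion_spikes = as.integer(n_motion_spikes),
                 spike_amplitude_mm = spike_amplitude_mm),
            class = "connectivity_spec")
}

#' Group-level perturbations of planted couplings
#'
#' Multipliers applied to the spec's couplings for one diagnostic group:
#' `local_coupling_multiplier` rescales the within-region correlation of all
#' hubs (the shared patient deficit), and the two distant multipliers rescale
#' the between-region correlation of cortical vs subcortical hub pairs (the
#' MHE-specific redistribution, with opposite directions). The control group
#' must keep all multipliers at 1.
#'
#' @param group `"control"`, `"nonHE"` or `"MHE"`.
#' @param local_coupling_multiplier,distant_cortical_multiplier,distant_subcortical_multiplier
#'   nonnegative multipliers.
#' @return An object of class `group_effects`.
#' @export
group_effects <- function(group = c("control", "nonHE", "MHE"),
                          local_coupling_multiplier = 1,
                          distant_cortical_multiplier = 1,
                          distant_subcortical_multiplier = 1) {
  group <- match.arg(group)
  m <- c(local_coupling_multiplier, distant_cortical_multiplier,
         distant_subcortical_multiplier)
  if (any(m < 0)) stopf("multipliers must be >= 0")
  if (group == "control" && any(m != 1))
    stopf("control group multipliers must all be 1")
  structure(list(group = group,
                 local_coupling_multiplier = local_coupling_multiplier,
                 distant_cortical_multiplier = distant_cortical_multiplier,
                 distant_subcortical_multiplier = distant_subcortical_multiplier),
            class = "group_effects")
}

# per-hub effective couplings after applying group multipliers; validates the
# mixture constraint c_d <= c_l <= 1
effective_couplings <- function(spec, effects) {
  nh <- length(spec$hub_seeds)
  if (nh == 0L) return(list(local = numeric(0), distant = numeric(0)))
  cl <- spec$local_coupling[seq_len(nh)] * effects$local_coupling_multiplier
  cd <- numeric(nh)
  for (i in seq_len(nh)) {
    h <- spec$hub_seeds[[i]]
    if (is.na(h$pair)) next
    mult <- if (h$role == "cortical") effects$distant_cortical_multiplier
            else effects$distant_subcortical_multiplier
    cd[i] <- spec$distant_coupling[i] * mult
  }
  if (any(cl > 1) || any(cd > cl + 1e-12))
    stopf(paste("effective couplings violate the mixture constraint",
                "distant <= local <= 1 (local: %s; distant: %s)"),
          paste(signif(cl, 3), collapse = ","),
          paste(signif(cd, 3), collapse = ","))
  list(local = cl, distant = pmin(cd, cl))
}

#' Closed-form planted correlations
#'
#' The population correlations implied by the generator's latent-mixture
#' model, used as the oracle for recovery tests: within a hub region every
#' voxel pair correlates at the effective local coupling; members of two
#' paired regions correlate at the geometric mean of the two effective
#' distant couplings.
#'
#' @param spec a [connectivity_spec()].
#' @param effects a [group_effects()].
#' @return list with `within` (per hub) and `between` (data frame of hub
#'   pairs with their planted cross-correlation).
#' @export
planted_correlations <- function(spec, effects = group_effects("control")) {
  eff <- effective_couplings(spec, effects)
  pairs <- data.frame(hub_i = integer(), hub_j = integer(), r = numeric())
  nh <- length(spec$hub_seeds)
  if (nh >= 2L) {
    ids <- vapply(spec$hub_seeds, function(h) as.integer(h$pair %||% NA), 1L)
    for (i in seq_len(nh - 1L)) for (j in seq(i + 1L, nh)) {
      if (!is.na(ids[i]) && !is.na(ids[j]) && ids[i] == ids[j])
        pairs <- rbind(pairs, data.frame(
          hub_i = i, hub_j = j, r = sqrt(eff$distant[i] * eff$distant[j])))
    }
  }
  list(within = eff$local, between = pairs)
}

# member voxel linear indices of each hub region (seed + neighborhood)
hub_regions <- function(spec) {
  dims <- spec$grid_shape
  vs <- spec$voxel_size_mm
  lapply(spec$hub_seeds, function(h) {
    r <- ceiling(spec$region_radius_mm / vs)
    off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    off <- off[rowSums((off * vs)^2) <= spec$region_radius_mm^2, ,
               drop = FALSE]
    v <- sweep(off, 2, h$voxel, `+`)
    keep <- v[, 1] >= 1 & v[, 1] <= dims[1] & v[, 2] >= 1 &
      v[, 2] <= dims[2] & v[, 3] >= 1 & v[, 3] <= dims[3]
    v <- v[keep, , drop = FALSE]
    as.integer(v[, 1] + dims[1] * (v[, 2] - 1) +
                 dims[1] * dims[2] * (v[, 3] - 1))
  })
}

# unit-variance band-limited Gaussian series, one per column, synthesized
# directly in the frequency domain: in-band DFT bins get iid complex
# Gaussian coefficients (Hermitian-symmetric), all others are zero. This is
# distributionally identical to ideal-bandpass-filtered white noise (flat
# in-band spectrum) at half the FFT cost. The DC bin is excluded whenever
# band[1] > 0, so columns have exactly zero mean.
band_limited_noise <- function(n_series, n_volumes, tr_s, band) {
  Tn <- n_volumes
  f <- pmin(seq_len(Tn) - 1L, Tn - (seq_len(Tn) - 1L)) / (Tn * tr_s)
  kept <- which(f >= band[1] & f <= band[2]) - 1L  # 0-based bin indices
  pos <- kept[kept >= 1L & kept <= Tn %/% 2L]
  if (length(pos) == 0L)
    stopf("no DFT bins inside the band [%g, %g] Hz at %d volumes",
          band[1], band[2], Tn)
  X <- matrix(0 + 0i, Tn, n_series)
  for (k in pos) {
    if (Tn %% 2L == 0L && k == Tn %/% 2L) {  # Nyquist bin is real
      X[k + 1L, ] <- rnorm(n_series)
    } else {
      co <- complex(real = rnorm(n_series), imaginary = rnorm(n_series))
      X[k + 1L, ] <- co
      X[Tn - k + 1L, ] <- Conj(co)
    }
  }
  if (0L %in% kept) X[1L, ] <- rnorm(n_series)
  x <- Re(mvfft(X, inverse = TRUE)) / Tn
  if (band[1] <= 0) x <- sweep(x, 2, colMeans(x))
  sdx <- sqrt(colSums(x^2) / (Tn - 1))
  sdx[sdx == 0] <- 1
  x * rep(1 / sdx, each = Tn)
}

#' Simulate one subject's BOLD volume and motion trace
#'
#' Draws a 4D volume from the latent-mixture model of [connectivity_spec()]
#' under the group perturbations of [group_effects()], plus a 6-parameter
#' rigid-body motion trace (random walk with optional injected spikes).
#' Deterministic given `seed`.
#'
#' @param spec a [connectivity_spec()].
#' @param effects a [group_effects()].
#' @param seed integer seed for this subject.
#' @return list with elements `bold` (a [bold_image]) and `motion` (matrix,
#'   volumes x 6: three translations in mm, three rotations in degrees).
#' @export
simulate_subject_bold <- function(spec, effects = group_effects("control"),
                                  seed = 1L) {
  eff <- effective_couplings(spec, effects)
  dims <- spec$grid_shape
  nvox <- prod(dims)
  Tn <- spec$n_volumes
  coords <- voxel_coords_mm(dims, spec$voxel_size_mm)

  # distant effects must stay outside the excluded gap band
  nh <- length(spec$hub_seeds)
  if (nh >= 2L) {
    ids <- vapply(spec$hub_seeds, function(h) as.integer(h$pair %||% NA), 1L)
    for (i in seq_len(nh - 1L)) for (j in seq(i + 1L, nh)) {
      if (is.na(ids[i]) || is.na(ids[j]) || ids[i] != ids[j]) next
      if (eff$distant[i] > 0 && eff$distant[j] > 0) {
        d <- sqrt(sum((spec$voxel_size_mm *
                         (spec$hub_seeds[[i]]$voxel -
                            spec$hub_seeds[[j]]$voxel))^2))
        if (d < spec$min_pair_distance_mm)
          stopf(paste("hub pair %d-%d is %.1f mm apart (< %g mm): a planted",
                      "distant effect would fall inside the gap band"),
                i, j, d, spec$min_pair_distance_mm)
      }
    }
  }

  seeds <- derive_seeds(seed, 2L)
  bold <- with_seed(seeds[1L], {
    pair_ids <- unique(stats::na.omit(vapply(
      spec$hub_seeds, function(h) as.integer(h$pair %||% NA), 1L)))
    u <- if (nh) band_limited_noise(nh, Tn, spec$tr_s, spec$signal_band)
    v <- if (length(pair_ids))
      band_limited_noise(length(pair_ids), Tn, spec$tr_s, spec$signal_band)
    noise <- band_limited_noise(nvox, Tn, spec$tr_s, spec$signal_band)

    dat <- noise  # T x nvox
    regions <- hub_regions(spec)
    for (i in seq_len(nh)) {
      h <- spec$hub_seeds[[i]]
      cl <- eff$local[i]; cd <- eff$distant[i]
      w_v <- sqrt(cd); w_u <- sqrt(max(cl - cd, 0)); w_e <- sqrt(max(1 - cl, 0))
      mem <- regions[[i]]
      shared <- (if (w_v > 0) w_v * v[, match(as.integer(h$pair), pair_ids)]
                 else 0) +
        (if (w_u > 0) w_u * u[, i] else 0)
      dat[, mem] <- shared + w_e * noise[, mem, drop = FALSE]
    }
    dat <- 100 + spec$noise_sd * dat
    bold_image(array(t(dat), c(dims, Tn)),
               voxel_size_mm = spec$voxel_size_mm, tr_s = spec$tr_s,
               provenance = "simulated")
  })
  list(bold = bold, motion = simulate_motion_trace(spec, seeds[2L]))
}

# 6-parameter rigid-body motion trace: slow random walk plus optional
# injected spikes; deterministic given seed and independent of the BOLD
# stream so that phenotype-only cohort draws reproduce the same traces
simulate_motion_trace <- function(spec, seed) {
  Tn <- spec$n_volumes
  with_seed(seed, {
    motion <- cbind(
      apply(matrix(rnorm(3 * Tn, 0, spec$motion_sd_mm), Tn, 3), 2, cumsum),
      apply(matrix(rnorm(3 * Tn, 0, spec$motion_sd_deg), Tn, 3), 2, cumsum))
    colnames(motion) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                          "rot_x_deg", "rot_y_deg", "rot_z_deg")
    if (spec$n_motion_spikes > 0L) {
      at <- sample(2:Tn, min(spec$n_motion_spikes, Tn - 1L))
      ax <- sample(1:3, length(at), replace = TRUE)
      for (k in seq_along(at))
        motion[at[k], ax[k]] <- motion[at[k], ax[k]] + spec$spike_amplitude_mm
    }
    motion
  })
}

#' Default synthetic hub layout
#'
#' A desk-scale arrangement on the default 20-voxel (3 mm) grid: one
#' long-range "cortical" pair, one long-range "subcortical" pair (both with
#' 59 mm seed separation, safely beyond the 25 mm distant radius), and two
#' unpaired local hubs. Paired regions use a high within-region coupling so
#' that group distant-multipliers up to 1.8 respect the mixture constraint.
#'
#' @return list of [hub_seed()] entries; pair regions first.
#' @export
default_hub_layout <- function() {
  list(hub_seed(c(3L, 3L, 10L), "cortical", pair = 1L),
       hub_seed(c(17L, 17L, 10L), "cortical", pair = 1L),
       hub_seed(c(3L, 17L, 10L), "subcortical", pair = 2L),
       hub_seed(c(17L, 3L, 10L), "subcortical", pair = 2L),
       hub_seed(c(10L, 10L, 4L), "cortical"),
       hub_seed(c(10L, 10L, 16L), "cortical"))
}

#' Cohort simulation configuration
#'
#' Group sizes default to the study design (103 controls, 69 non-HE, 34 MHE
#' before motion exclusion). Phenotype scores are drawn from normal
#' distributions; controls use the published control means/SDs (NCT-A
#' 44.06 +/- 10.66 s, DST 46.83 +/- 12.51), and the two patient groups use
#' means/SDs chosen so that their 69/34 mixture reproduces the published
#' all-patient summaries (NCT-A 54.38 +/- 20.02 s, DST 35.52 +/- 11.80).
#' Group effect multipliers default to a shared local-coupling deficit in
#' both patient groups and an MHE-only distant perturbation (subcortical
#' increase, cortical decrease); no published effect sizes in FCD units
#' exist, so these are free generator parameters.
#'
#' @param n_control,n_nonhe,n_mhe group sizes (each >= 2).
#' @param spec a [connectivity_spec()]; defaults to the default hub layout
#'   with local coupling 0.6 at unpaired hubs and 0.9 at paired hubs.
#' @param effects named list of [group_effects()] for `control`, `nonHE`,
#'   `MHE`.
#' @param phenotypes named list (per group) of lists with elements
#'   `age = c(mean, sd)`, `education = c(mean, sd)`, `male_p`,
#'   `nct_a = c(mean, sd)`, `dst = c(mean, sd)`, `ammonia = c(mean, sd)` or
#'   `NULL`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 103L, n_nonhe = 69L, n_mhe = 34L,
                          spec = NULL, effects = NULL, phenotypes = NULL) {
  if (min(n_control, n_nonhe, n_mhe) < 2L)
    stopf("all group sizes must be >= 2")
  if (is.null(spec))
    spec <- connectivity_spec(hub_seeds = default_hub_layout(),
                              local_coupling = c(0.9, 0.9, 0.9, 0.9, 0.6, 0.6),
                              distant_coupling = 0.3)
  if (is.null(effects))
    effects <- list(
      control = group_effects("control"),
      nonHE = group_effects("nonHE", local_coupling_multiplier = 0.6),
      MHE = group_effects("MHE", local_coupling_multiplier = 0.6,
                          distant_cortical_multiplier = 0.5,
                          distant_subcortical_multiplier = 1.8))
  defaults <- list(
    control = list(age = c(47.43, 10.09), education = c(10.97, 3.18),
                   male_p = 72 / 103, nct_a = c(44.06, 10.66),
                   dst = c(46.83, 12.51), ammonia = NULL),
    nonHE = list(age = c(47.99, 10.27), education = c(10.45, 3.11),
                 male_p = 81 / 103, nct_a = c(47, 12), dst = c(39, 10),
                 ammonia = c(53.34, 34.34)),
    MHE = list(age = c(47.99, 10.27), education = c(10.45, 3.11),
               male_p = 81 / 103, nct_a = c(69, 18), dst = c(28, 9),
               ammonia = c(53.34, 34.34)))
  phenotypes <- phenotypes %||% defaults
  for (g in names(phenotypes)) for (nm in c("age", "education", "nct_a",
                                            "dst", "ammonia")) {
    p <- phenotypes[[g]][[nm]]
    if (!is.null(p) && p[2] <= 0)
      stopf("phenotype SD for %s/%s must be positive", g, nm)
  }
  structure(list(n_control = as.integer(n_control),
                 n_nonhe = as.integer(n_nonhe), n_mhe = as.integer(n_mhe),
                 spec = spec, effects = effects, phenotypes = phenotypes),
            class = "cohort_config")
}

#' Simulate a full cohort
#'
#' Draws phenotypes, motion traces and (optionally) BOLD volumes for three
#' groups. All randomness derives from the single root `seed` through
#' per-subject child streams, so any subject can be regenerated
#' independently. With `out_dir` set, writes the phenotype table (TSV),
#' per-subject motion traces (TSV) and BOLD volumes (NIfTI-1).
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed.
#' @param generate_bold if `FALSE`, only phenotypes and motion are produced.
#' @param out_dir optional output directory for fixtures.
#' @return list with `records` (data frame, one row per subject), `bold`
#'   (list of [bold_image] or `NULL`s) and `motion` (list of matrices).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            generate_bold = TRUE, out_dir = NULL) {
  groups <- rep(c("control", "nonHE", "MHE"),
                c(config$n_control, config$n_nonhe, config$n_mhe))
  n <- length(groups)
  seeds <- derive_seeds(seed, 2L * n)
  pheno_seeds <- seeds[seq_len(n)]
  bold_seeds <- seeds[n + seq_len(n)]

  recs <- vector("list", n)
  bolds <- vector("list", n)
  motions <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    ph <- config$phenotypes[[g]]
    rec <- with_seed(pheno_seeds[i], {
      data.frame(
        subject_id = sprintf("sub-%03d", i),
        group = g,
        age_y = max(18, rnorm(1, ph$age[1], ph$age[2])),
        sex = ifelse(runif(1) < ph$male_p, "M", "F"),
        education_y = max(0, rnorm(1, ph$education[1], ph$education[2])),
        nct_a_s = max(1, rnorm(1, ph$nct_a[1], ph$nct_a[2])),
        dst_score = max(0, rnorm(1, ph$dst[1], ph$dst[2])),
        ammonia_umol_l = if (is.null(ph$ammonia)) NA_real_
                         else max(0, rnorm(1, ph$ammonia[1], ph$ammonia[2])),
        stringsAsFactors = FALSE)
    })
    if (generate_bold) {
      sim <- simulate_subject_bold(config$spec, config$effects[[g]],
                                   seed = bold_seeds[i])
      motions[[i]] <- sim$motion
      bolds[[i]] <- sim$bold
    } else {
      # same motion stream the full simulation would produce
      effective_couplings(config$spec, config$effects[[g]])  # validate
      motions[[i]] <- simulate_motion_trace(
        config$spec, derive_seeds(bold_seeds[i], 2L)[2L])
    }
    tr <- motion_trace(motions[[i]])
    rec$max_trans_mm <- max(abs(tr$translations_mm))
    rec$max_rot_deg <- max(abs(tr$rotations_deg))
    rec$included <- !motion_excluded(motions[[i]])
    recs[[i]] <- rec
  }
  records <- do.call(rbind, recs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "motion"), showWarnings = FALSE)
    tsv <- records[, c("subject_id", "group", "age_y", "sex", "education_y",
                       "nct_a_s", "dst_score", "ammonia_umol_l")]
    names(tsv) <- c("subject_id", "group", "age", "sex", "education",
                    "nct_a", "dst", "ammonia")
    write.table(tsv, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (i in seq_len(n)) {
      write.table(motions[[i]],
                  file.path(out_dir, "motion",
                            paste0(records$subject_id[i], "_motion.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (generate_bold) {
        dir.create(file.path(out_dir, "bold"), showWarnings = FALSE)
        write_bold(bolds[[i]],
                   file.path(out_dir, "bold",
                             paste0(records$subject_id[i], "_bold.nii.gz")))
      }
    }
  }
  list(records = records, bold = bolds, motion = motions)
}

#' Classify minimal hepatic encephalopathy from psychometric scores
#'
#' A cirrhotic subject is classified as MHE when at least one score is
#' abnormal by more than two standard deviations from the control mean, in
#' the impaired direction of each test: NCT-A is a completion time (longer is
#' worse), DST a score (lower is worse). Inequalities are strict.
#'
#' @param nct_a NCT-A completion time, seconds.
#' @param dst DST score.
#' @param control_stats list with `nct_a = c(mean, sd)` and
#'   `dst = c(mean, sd)` from age-matched controls; defaults to the published
#'   control summaries.
#' @return logical.
#' @export
classify_mhe <- function(nct_a, dst,
                         control_stats = list(nct_a = c(44.06, 10.66),
                                              dst = c(46.83, 12.51))) {
  if (is.na(nct_a) || is.na(dst)) stopf("missing psychometric score")
  if (control_stats$nct_a[2] <= 0 || control_stats$dst[2] <= 0)
    stopf("control SDs must be positive")
  (nct_a > control_stats$nct_a[1] + 2 * control_stats$nct_a[2]) ||
    (dst < control_stats$dst[1] - 2 * control_stats$dst[2])
}
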