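#' Extract per-region mean FCD values
#'
#' For each subject and each labeled cluster, the mean of the subject's map
#' over the cluster's voxels.
#'
#' @param maps list of per-subject 3D arrays or `fcd_maps`.
#' @param label_map 3D integer array of region labels (0 = background),
#'   e.g. the `"label_map"` attribute of [extract_clusters()].
#' @param which map component when `fcd_maps` objects are supplied.
#' @return numeric matrix, subjects x regions; columns named `region_<id>`.
#' @export
extract_region_means <- function(maps, label_map, which = "total") {
  ids <- sort(unique(label_map[label_map > 0L]))
  if (length(ids) == 0L) stopf("label map contains no regions")
  vox <- lapply(ids, function(l) {
    v <- which(label_map == l)
    if (length(v) == 0L) stopf("region %d is empty", l)
    v
  })
  out <- vapply(maps, function(m) {
    a <- if (inherits(m, "fcd_maps")) m[[which]] else m
    vapply(vox, function(v) mean(a[v]), numeric(1))
  }, numeric(length(ids)))
  out <- if (length(ids) == 1L) matrix(out, ncol = 1L) else t(out)
  colnames(out) <- paste0("region_", ids)
  rownames(out) <- names(maps)
  out
}

#' Partial Spearman correlation
#'
#' Rank-based correlation between `x` and `y` with covariates removed:
#' both variables are converted to midranks, the covariates are regressed
#' out of each rank vector by ordinary least squares, and the Pearson
#' correlation of the residuals is returned. Without covariates this equals
#' the ordinary Spearman rho. The two-sided p-value uses the t
#' approximation with df = n - 2 - c (c = covariate columns); an exact
#' permutation p is available for small samples.
#'
#' @param x,y numeric vectors (non-constant).
#' @param covariates optional data frame / matrix of covariates (e.g. age,
#'   sex coded 0/1, education).
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed seed for the permutation p-value.
#' @return list with `rho`, `p`, `df`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL,
                             p_method = c("t", "permutation"),
                             n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  ok <- stats::complete.cases(x, y, if (is.null(covariates)) rep(TRUE, length(x))
                              else covariates)
  x <- x[ok]; y <- y[ok]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    # constant covariates (e.g. single-sex subsamples) are inestimable
    keep <- vapply(covariates, function(v) length(unique(v)) > 1L,
                   logical(1))
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates) == 0L) covariates <- NULL
  }
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0)
    stopf("x and y must be non-constant (ranks carry no information)")
  nc <- if (is.null(covariates)) 0L
        else ncol(stats::model.matrix(~ ., data = as.data.frame(covariates))) - 1L
  if (n < nc + 3L) stopf("need at least %d complete observations", nc + 3L)
  rho_of <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    if (!is.null(covariates)) {
      rx <- regress_covariates(rx, covariates)
      ry <- regress_covariates(ry, covariates)
    }
    cor(rx, ry)
  }
  rho <- rho_of(x, y)
  df <- n - 2L - nc
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tv <- rho * sqrt(df / (1 - rho^2))
      p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
    }
  } else {
    p <- with_seed(seed, {
      null_rho <- vapply(seq_len(n_perm),
                         function(i) rho_of(x, sample(y)), numeric(1))
      (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  list(rho = rho, p = p, df = df, n = n)
}

#' Bonferroni-corrected significance cutoff
#'
#' The per-test p-value cutoff `alpha / n_regions` used when the same
#' clinical variable is correlated across all regions showing group
#' differences (e.g. 0.05/13 for 13 regions).
#'
#' @param alpha family-wise level.
#' @param n_regions number of regions tested (>= 1).
#' @return numeric cutoff.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, n_regions) {
  if (n_regions < 1L) stopf("n_regions must be >= 1")
  alpha / n_regions
}

#' Classify a correlation under Bonferroni control
#'
#' Decision logic for reporting: a correlation is "uncorrected significant"
#' when p < alpha and "Bonferroni significant" only when p < alpha /
#' n_regions. A finding like rho = -0.40, p = 0.02 over 13 regions is thus
#' uncorrected-significant but not significant after correction.
#'
#' @param p uncorrected p-value.
#' @param n_regions number of regions in the family.
#' @param alpha family-wise level.
#' @return list with `cutoff`, `significant_uncorrected`,
#'   `significant_bonferroni`.
#' @export
classify_correlation <- function(p, n_regions, alpha = 0.05) {
  cutoff <- bonferroni_cutoff(alpha, n_regions)
  list(cutoff = cutoff,
       significant_uncorrected = p < alpha,
       significant_bonferroni = p < cutoff)
}

#' Region-wise clinical correlations
#'
#' Partial Spearman correlation of every region's mean FCD with every
#' clinical variable, covariate-adjusted, with the Bonferroni cutoff set by
#' the number of regions. Typically run separately within each patient
#' group.
#'
#' @param region_means subjects x regions matrix from
#'   [extract_region_means()].
#' @param clinical data frame with one row per subject, containing the
#'   columns named in `variables` and in `covariates`.
#' @param variables character vector of clinical column names to correlate.
#' @param covariates character vector of covariate column names (default
#'   age, sex, education).
#' @param alpha family-wise level.
#' @return data frame (region, variable, n, rho, p_uncorrected, cutoff,
#'   significant_uncorrected, significant_bonferroni).
#' @export
correlate_regions <- function(region_means, clinical, variables,
                              covariates = c("age_y", "sex01",
                                             "education_y"),
                              alpha = 0.05) {
  stopifnot(nrow(clinical) == nrow(region_means))
  n_regions <- ncol(region_means)
  cutoff <- bonferroni_cutoff(alpha, n_regions)
  out <- list()
  for (r in colnames(region_means)) for (v in variables) {
    cov_df <- if (length(covariates))
      clinical[, covariates, drop = FALSE] else NULL
    res <- partial_spearman(region_means[, r], clinical[[v]], cov_df)
    out[[length(out) + 1L]] <- data.frame(
      region = r, variable = v, n = res$n, rho = res$rho,
      p_uncorrected = res$p, cutoff = cutoff,
      significant_uncorrected = res$p < alpha,
      significant_bonferroni = res$p < cutoff)
  }
  do.call(rbind, out)
}
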