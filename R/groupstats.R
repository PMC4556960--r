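# stack per-subject 3D maps (or fcd_maps components) into subjects x voxels
maps_to_matrix <- function(maps, mask, which = "total") {
  rows <- lapply(maps, function(m) {
    a <- if (inherits(m, "fcd_maps")) m[[which]] else m
    a[mask]
  })
  do.call(rbind, rows)
}

stat_result <- function(stat_map, stat_kind, df, p_map, mask,
                        voxel_size_mm) {
  structure(list(stat_map = stat_map, stat_kind = stat_kind, df = df,
                 p_map = p_map, mask = mask, voxel_size_mm = voxel_size_mm),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  df <- paste(x$df, collapse = ", ")
  cat(sprintf("<stat_result> %s map (df = %s), %d in-mask voxels\n",
              x$stat_kind, df, sum(x$mask)))
  cat(sprintf("  max |%s| = %.3f, min p = %.3g\n", x$stat_kind,
              max(abs(x$stat_map[x$mask])), min(x$p_map[x$mask])))
  invisible(x)
}

#' Residualize subject values on nuisance covariates
#'
#' Ordinary least squares of per-subject values (scalars or voxel maps) on
#' an intercept plus the supplied covariates, across subjects. The returned
#' values are the residuals plus the grand intercept, so group contrasts are
#' computed on covariate-adjusted data. Residuals are exactly orthogonal to
#' every covariate.
#'
#' @param values numeric vector (one value per subject) or subjects x
#'   variables matrix.
#' @param covariates data frame or matrix of per-subject covariates (e.g.
#'   age, sex coded 0/1, education). Factors/characters are converted to
#'   0/1 dummies via `model.matrix`.
#' @return object of the same shape as `values`, with attribute
#'   `"n_covariates"` recording the degrees of freedom consumed.
#' @export
regress_covariates <- function(values, covariates) {
  v <- as.matrix(values)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != nrow(v))
    stopf("covariates have %d rows but values have %d", nrow(X), nrow(v))
  if (nrow(v) < ncol(X) + 2L)
    stopf("need at least %d subjects for %d covariates", ncol(X) + 2L,
          ncol(X) - 1L)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("collinear covariates: %s",
          paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]],
                collapse = ", "))
  fit <- X %*% qr.coef(qrX, v)
  res <- v - fit + rep(colMeans(v), each = nrow(v))
  out <- if (is.matrix(values)) res else drop(res)
  attr(out, "n_covariates") <- ncol(X) - 1L
  out
}

#' Voxel-wise one-sample t test
#'
#' Random-effects one-sample t test of per-subject maps against zero:
#' \eqn{t = \bar x / (s / \sqrt n)} per voxel, df = n - 1, two-sided p.
#' Voxels with zero between-subject variance get the degenerate limit
#' (p = 0 for nonzero mean, p = 1 otherwise) with a warning.
#'
#' @param maps list of per-subject 3D arrays or `fcd_maps`.
#' @param mask 3D logical analysis mask.
#' @param which map component when `fcd_maps` objects are supplied.
#' @return a `stat_result` with `stat_kind = "t"`.
#' @export
one_sample_t <- function(maps, mask, which = "total") {
  Y <- maps_to_matrix(maps, mask, which)
  n <- nrow(Y)
  if (n < 2L) stopf("need at least 2 subjects")
  m <- colMeans(Y)
  s <- sqrt(colSums(sweep(Y, 2, m)^2) / (n - 1))
  tval <- numeric(length(m))
  degen <- s == 0
  if (any(degen))
    warning("zero-variance voxel(s); p set to the degenerate limit")
  tval[!degen] <- m[!degen] / (s[!degen] / sqrt(n))
  tval[degen & m != 0] <- sign(m[degen & m != 0]) * Inf
  p <- 2 * pt(abs(tval), n - 1, lower.tail = FALSE)
  p[degen & m != 0] <- 0
  p[degen & m == 0] <- 1
  to_map <- function(v) { a <- array(0, dim(mask)); a[mask] <- v; a }
  pm <- array(1, dim(mask)); pm[mask] <- p
  stat_result(to_map(tval), "t", n - 1, pm, mask, NULL)
}

# covariate-adjusted subjects x voxels matrix + df penalty; zero-variance
# covariate columns (e.g. a constant sex indicator in a small subsample)
# are inestimable and silently dropped, with the df charge reduced to the
# columns actually used
adjust_for_covariates <- function(Y, covariates) {
  if (is.null(covariates)) return(list(Y = Y, c = 0L))
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(x) length(unique(x)) > 1L, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(list(Y = Y, c = 0L))
  Yr <- regress_covariates(Y, covariates)
  list(Y = Yr, c = attr(Yr, "n_covariates"))
}

#' Voxel-wise one-way ANOVA with covariate adjustment
#'
#' Covariates are residualized out first (see [regress_covariates()]); the
#' per-voxel between/within F statistic is then computed on the adjusted
#' values with degrees of freedom (k - 1, N - k - c), where c is the number
#' of covariate columns consumed by the residualization.
#'
#' @param maps list of per-subject 3D arrays or `fcd_maps`.
#' @param groups factor or character vector of group labels, one per
#'   subject; every group needs at least 2 subjects.
#' @param mask 3D logical analysis mask.
#' @param covariates optional per-subject covariates.
#' @param which map component when `fcd_maps` objects are supplied.
#' @return a `stat_result` with `stat_kind = "F"`.
#' @export
one_way_anova <- function(maps, groups, mask, covariates = NULL,
                          which = "total") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) stopf("every group needs at least 2 subjects")
  Y <- maps_to_matrix(maps, mask, which)
  adj <- adjust_for_covariates(Y, covariates)
  Y <- adj$Y
  N <- nrow(Y); k <- nlevels(groups)
  G <- stats::model.matrix(~ groups - 1)
  ng <- colSums(G)
  gm <- sweep(crossprod(G, Y), 1, ng, `/`)       # group means, k x voxels
  grand <- colMeans(Y)
  ssb <- colSums(ng * sweep(gm, 2, grand)^2)
  fit <- G %*% gm
  ssw <- colSums((Y - fit)^2)
  df1 <- k - 1L
  df2 <- N - k - adj$c
  Fv <- (ssb / df1) / (ssw / df2)
  Fv[ssw == 0] <- Inf
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  to_map <- function(v, fill = 0) { a <- array(fill, dim(mask)); a[mask] <- v; a }
  stat_result(to_map(Fv), "F", c(df1, df2), to_map(p, fill = 1), mask, NULL)
}

#' Voxel-wise post-hoc two-sample t test
#'
#' Pooled-variance two-sample t on covariate-adjusted values for one group
#' pair, evaluated only inside `restrict_mask` (typically the
#' ANOVA-significant voxels). The map is signed: positive means the first
#' group of `pair` exceeds the second. Covariates are residualized across
#' the subjects of the two groups; df = n1 + n2 - 2 - c.
#'
#' @param maps list of per-subject 3D arrays or `fcd_maps` (all subjects).
#' @param groups group labels, one per subject.
#' @param pair character vector of length 2: the groups to compare, in
#'   order.
#' @param restrict_mask 3D logical mask of voxels to test; must be a subset
#'   of `mask`.
#' @param mask 3D logical analysis mask.
#' @param covariates optional per-subject covariates (subset to the pair).
#' @param which map component when `fcd_maps` objects are supplied.
#' @return a `stat_result` with `stat_kind = "t"`; statistics are zero and
#'   p = 1 outside `restrict_mask`. An empty `restrict_mask` yields an
#'   all-zero result with a warning.
#' @export
posthoc_t <- function(maps, groups, pair, restrict_mask, mask,
                      covariates = NULL, which = "total") {
  stopifnot(length(pair) == 2L)
  if (any(restrict_mask & !mask))
    stopf("restrict_mask must be a subset of the analysis mask")
  sel <- groups %in% pair
  g <- factor(groups[sel], levels = pair)
  if (any(table(g) < 2L)) stopf("both groups need at least 2 subjects")
  to_map <- function(v, fill = 0) { a <- array(fill, dim(mask)); a[mask] <- v; a }
  if (!any(restrict_mask)) {
    warning("restrict_mask is empty; returning an empty result")
    return(stat_result(to_map(0), "t", sum(sel) - 2L, to_map(1, 1), mask,
                       NULL))
  }
  Y <- maps_to_matrix(maps[sel], mask, which)
  adj <- adjust_for_covariates(
    Y, if (is.null(covariates)) NULL else
      as.data.frame(covariates)[sel, , drop = FALSE])
  Y <- adj$Y
  n1 <- sum(g == pair[1]); n2 <- sum(g == pair[2])
  m1 <- colMeans(Y[g == pair[1], , drop = FALSE])
  m2 <- colMeans(Y[g == pair[2], , drop = FALSE])
  ss <- colSums(sweep(Y[g == pair[1], , drop = FALSE], 2, m1)^2) +
    colSums(sweep(Y[g == pair[2], , drop = FALSE], 2, m2)^2)
  df <- n1 + n2 - 2L - adj$c
  sp <- sqrt(ss / df)
  tv <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  tv[sp == 0 & m1 == m2] <- 0
  tv[sp == 0 & m1 != m2] <- sign((m1 - m2)[sp == 0 & m1 != m2]) * Inf
  p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
  keep <- restrict_mask[mask]
  tv[!keep] <- 0
  p[!keep] <- 1
  stat_result(to_map(tv), "t", df, to_map(p, fill = 1), mask, NULL)
}
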