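#' Chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square without continuity correction (df = 1), as used for
#' group sex-distribution comparisons. `a`/`b` are the counts of the two
#' categories in group 1, `c`/`d` in group 2.
#'
#' @param a,b,c,d nonnegative counts; all row and column margins must be
#'   positive.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stopf("counts must be nonnegative")
  m <- matrix(cnt, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopf("all margins must be positive")
  res <- chisq.test(m, correct = FALSE)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (Student) two-sample t test from group means, SDs and
#' sizes, df = n1 + n2 - 2, two-sided p. `welch = TRUE` switches to the
#' Welch-Satterthwaite version.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (sd > 0, n >= 2).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param welch use the unequal-variance test.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 welch = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stopf("SDs must be positive")
  if (n1 < 2 || n2 < 2) stopf("each group needs n >= 2")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tval <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tval, df = df, p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

#' Two-sample t test from raw values
#'
#' Computes the group summaries and delegates to [two_sample_t_summary()],
#' so the raw and summary routes agree exactly.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @param welch use the unequal-variance test.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t_raw <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stopf("each group needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0) stopf("zero pooled variance")
  two_sample_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                       welch = welch)
}

#' Format a p-value for tabulation
#'
#' Two decimals for p >= 0.001, otherwise the string `"<0.001"`.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.2f", p))
}

#' Demographic and clinical comparison table
#'
#' Builds the standard cohort-description table comparing healthy controls
#' with all cirrhotic patients (both patient groups combined): sex
#' distribution by chi-square, and age, education, NCT-A and DST by pooled
#' two-sample t test, with mean +/- SD per column and formatted p-values.
#'
#' @param records subject data frame as produced by [simulate_cohort()]
#'   (columns `group`, `sex`, `age_y`, `education_y`, `nct_a_s`,
#'   `dst_score`, `ammonia_umol_l`).
#' @param welch use Welch instead of pooled t tests.
#' @return data frame of class `table1` with one row per protocol item and
#'   columns `protocol`, `hc`, `patients`, `p_value`; the unformatted
#'   p-values are kept in the `p_raw` column.
#' @export
build_table1 <- function(records, welch = FALSE) {
  hc <- records[records$group == "control", ]
  pat <- records[records$group != "control", ]
  if (nrow(hc) == 0L || nrow(pat) == 0L)
    stopf("both cohorts must be nonempty")
  msd <- function(x) sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
                             sd(x, na.rm = TRUE))
  chi <- chi_square_2x2(sum(hc$sex == "M"), sum(hc$sex == "F"),
                        sum(pat$sex == "M"), sum(pat$sex == "F"))
  rows <- list(
    data.frame(protocol = "Gender (M/F)",
               hc = sprintf("%d/%d", sum(hc$sex == "M"), sum(hc$sex == "F")),
               patients = sprintf("%d/%d", sum(pat$sex == "M"),
                                  sum(pat$sex == "F")),
               p_raw = chi$p))
  num_row <- function(label, col) {
    tt <- two_sample_t_raw(hc[[col]], pat[[col]], welch = welch)
    data.frame(protocol = label, hc = msd(hc[[col]]),
               patients = msd(pat[[col]]), p_raw = tt$p)
  }
  rows <- c(rows, list(
    num_row("Age (y)", "age_y"),
    num_row("Education (y)", "education_y"),
    data.frame(protocol = "Venous blood ammonia (umol/L)", hc = "",
               patients = msd(pat$ammonia_umol_l), p_raw = NA_real_),
    num_row("NCT-A (s)", "nct_a_s"),
    num_row("DST (score)", "dst_score"),
    data.frame(protocol = "MHE patients (n)", hc = "",
               patients = as.character(sum(pat$group == "MHE")),
               p_raw = NA_real_),
    data.frame(protocol = "Non-HE patients (n)", hc = "",
               patients = as.character(sum(pat$group == "nonHE")),
               p_raw = NA_real_)))
  out <- do.call(rbind, rows)
  out$p_value <- ifelse(is.na(out$p_raw), "", format_p(out$p_raw))
  class(out) <- c("table1", "data.frame")
  out
}

#' @export
print.table1 <- function(x, ...) {
  df <- as.data.frame(x)[, c("protocol", "hc", "patients", "p_value")]
  names(df) <- c("Protocol", "HC", "Patients", "P value")
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
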