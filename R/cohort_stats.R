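#' Welch two-sample t-test from summary statistics
#'
#' Computes the Welch (unequal-variance) two-sided t-test directly from group
#' means, standard deviations and sizes, with Satterthwaite degrees of
#' freedom — useful for checking published characteristics tables where only
#' summaries are printed.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) .stop_data("group sizes must be >= 2")
  if (s1 < 0 || s2 < 0) .stop_data("standard deviations must be >= 0")
  if (s1 == 0 && s2 == 0) .stop_data("degenerate: both group variances are 0")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Standard upper-tail Pearson chi-square with `(r-1)(c-1)` degrees of
#' freedom; for 2x2 tables with `continuity = TRUE` the Yates continuity
#' correction is applied. A zero row or column margin makes the test
#' undefined and raises an error (the analogue of a "did not converge" NA in
#' published sign-count tables).
#'
#' @param table Matrix of nonnegative counts, at least 2x2.
#' @param continuity Apply the Yates correction for 2x2 tables.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi2_independence <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    .stop_data("contingency table must be at least 2x2")
  if (any(table < 0) || any(table != round(table)))
    .stop_data("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stop_data("chi-square test undefined: zero row or column margin")
  res <- suppressWarnings(chisq.test(table, correct = continuity))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

.CONTINUOUS_VARS <- c("maternal_age", "maternal_bmi", "gestational_age",
                      "birthweight", "paternal_age", "paternal_bmi")
.CATEGORICAL_VARS <- c("parity", "maternal_smoking", "maternal_education",
                       "conception_subtype")

#' Characteristics table with per-variable group tests
#'
#' Compares ART-conceived to naturally-conceived newborns within each sex
#' stratum, one row per variable: Welch two-sided t-test for continuous
#' variables, Pearson chi-square (Yates-corrected when 2x2) for categorical
#' ones. Missing values are counted and reported separately and excluded from
#' the tests.
#'
#' @param samples Sample table.
#' @param variables Variables to summarize; defaults to every known
#'   continuous/categorical covariate present in `samples`.
#' @param stratify Column defining strata (default `"sex"`).
#' @return data.frame with columns `stratum`, `variable`, `kind`,
#'   `n_reference`, `n_exposed`, `n_missing`, `stat`, `df`, `p`, `note`.
#'   `reference` = natural conception, `exposed` = ART.
#' @export
summarize_cohort <- function(samples, variables = NULL, stratify = "sex") {
  validate_sample_table(samples)
  if (is.null(variables))
    variables <- intersect(c(.CONTINUOUS_VARS, .CATEGORICAL_VARS),
                           names(samples))
  rows <- list()
  for (stratum in sort(unique(samples[[stratify]]))) {
    sub <- samples[samples[[stratify]] == stratum, , drop = FALSE]
    exposed <- is_art(sub)
    for (v in variables) {
      x <- sub[[v]]
      kind <- if (v %in% .CONTINUOUS_VARS || is.numeric(x)) "continuous"
              else "categorical"
      ok <- !is.na(x)
      n_ref <- sum(ok & !exposed)
      n_exp <- sum(ok & exposed)
      stat <- df <- p <- NA_real_
      note <- ""
      if (n_ref == 0L || n_exp == 0L) {
        note <- "all missing in one group"
      } else if (kind == "continuous") {
        res <- tryCatch(
          welch_t_from_summary(mean(x[ok & exposed]), sd(x[ok & exposed]), n_exp,
                               mean(x[ok & !exposed]), sd(x[ok & !exposed]), n_ref),
          error = function(e) NULL)
        if (is.null(res)) note <- "degenerate variances" else {
          stat <- res$t; df <- res$df; p <- res$p
        }
      } else {
        tab <- table(factor(exposed[ok], levels = c(FALSE, TRUE)), x[ok])
        res <- tryCatch(chi2_independence(tab), error = function(e) NULL)
        if (is.null(res)) note <- "chi-square undefined (zero margin)" else {
          stat <- res$chi2; df <- res$df; p <- res$p
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = stratum, variable = v, kind = kind,
                   n_reference = n_ref, n_exposed = n_exp,
                   n_missing = sum(!ok), stat = stat, df = df, p = p,
                   note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
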