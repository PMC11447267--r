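## Genome-wide difference-distribution comparison between sexes (KS) and
## candidate CpG set enrichment against the EWAS background.

#' Per-CpG mean methylation difference, exposed minus reference
#'
#' Within one sex stratum, computes for every probe the mean beta value in
#' the ART group minus the mean in the natural-conception group, over
#' unmasked values (the per-CpG median +/- `mad_k` * MAD mask is applied
#' within the stratum first).
#'
#' @param beta Beta matrix.
#' @param samples Sample table.
#' @param stratum `"F"` or `"M"`.
#' @param contrast Contrast name (default `ART_vs_natural`).
#' @param mad_k MAD multiplier; `NULL` disables masking.
#' @return Named numeric vector (probe -> difference), containing only probes
#'   observed in both groups.
#' @export
mean_difference_vector <- function(beta, samples, stratum,
                                   contrast = "ART_vs_natural", mad_k = 5) {
  groups <- contrast_groups(contrast)
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  sub <- samples[samples$sex == stratum &
                   samples$conception %in% c(groups$exposed, groups$reference), ,
                 drop = FALSE]
  exposed <- sub$conception %in% groups$exposed
  if (!any(exposed) || all(exposed))
    .stop_data("stratum ", stratum, " lacks one of the contrast groups")
  b <- beta[, sub$sample_id, drop = FALSE]
  if (!is.null(mad_k))
    b <- t(apply(b, 1L, function(v) mad_mask(v, k = mad_k)$values))
  m_exp <- rowMeans(b[, exposed, drop = FALSE], na.rm = TRUE)
  m_ref <- rowMeans(b[, !exposed, drop = FALSE], na.rm = TRUE)
  d <- m_exp - m_ref
  d[is.finite(d)]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Exact supremum difference of the two empirical CDFs, with the asymptotic
#' two-sample p-value.
#'
#' @param x,y Numeric samples (nonempty).
#' @return List of class `ks_result`: `D`, `p`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) .stop_data("empty input to KS test")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  structure(list(D = unname(res$statistic), p = unname(res$p.value),
                 n1 = length(x), n2 = length(y)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4g, p = %.3g (n1 = %d, n2 = %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}

#' QQ-plot coordinates for a p-value vector
#'
#' Expected versus observed `-log10(p)` under the global null (uniform order
#' statistics `(i - 0.5) / n`), the data behind QQ plots of EWAS results.
#'
#' @param p P-values (`NA` dropped).
#' @return data.frame: `expected`, `observed`, both `-log10` scale, sorted.
#' @export
qq_coordinates <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(pmax(p, .Machine$double.xmin)))
}

#' Candidate CpG set enrichment against the EWAS background
#'
#' Tests whether a candidate set of CpGs (e.g. probes in genes linked to a
#' health outcome) shows smaller EWAS p-values than the background universe:
#' a one-sided Wilcoxon rank-sum test of the candidates' `-log10(p)`
#' exceeding the non-candidates', plus a lambda ratio (median chi-square
#' quantile of the candidates over that of the whole universe) and QQ
#' coordinates for both sets.
#'
#' @param p_background Named vector of EWAS p-values over the universe
#'   (names = probe IDs).
#' @param candidate_ids Candidate probe IDs (must be a subset of the
#'   universe, at least 5).
#' @param name Label for the set.
#' @return List of class `enrichment_result`: `name`, `n_candidates`,
#'   `statistic` (rank-sum W), `p` (one-sided), `lambda`, `qq_candidates`,
#'   `qq_background`.
#' @export
set_enrichment <- function(p_background, candidate_ids, name = "candidates") {
  if (is.null(names(p_background)))
    .stop_data("p_background must be named by probe ID")
  outside <- setdiff(candidate_ids, names(p_background))
  if (length(outside))
    .stop_data("candidate probes outside the universe: ",
               paste(head(outside, 10L), collapse = ", "))
  if (length(candidate_ids) < 5L) .stop_data("need at least 5 candidates")
  p_cand <- p_background[candidate_ids]
  p_rest <- p_background[setdiff(names(p_background), candidate_ids)]
  p_cand <- p_cand[!is.na(p_cand)]; p_rest <- p_rest[!is.na(p_rest)]
  w <- suppressWarnings(wilcox.test(-log10(p_cand), -log10(p_rest),
                                    alternative = "greater", exact = FALSE))
  chi <- function(p) qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chi(p_cand)) / median(chi(p_background), na.rm = TRUE)
  structure(list(name = name, n_candidates = length(p_cand),
                 statistic = unname(w$statistic), p = unname(w$p.value),
                 lambda = lambda,
                 qq_candidates = qq_coordinates(p_cand),
                 qq_background = qq_coordinates(p_background)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Set '%s': %d candidates, rank-sum p = %.3g, lambda = %.3f\n",
              x$name, x$n_candidates, x$p, x$lambda))
  invisible(x)
}
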