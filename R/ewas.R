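## Per-CpG mixed-model EWAS, stratified by sex, with BH-FDR control.

.DEFAULT_COVARIATES <- c("maternal_age", "maternal_smoking", "maternal_bmi",
                         "parity")

#' Conception-mode contrasts
#'
#' Named list of supported exposure contrasts. Each entry gives the conception
#' modes counted as exposed and as reference; the estimate sign convention is
#' exposed minus reference ("+" = hypermethylated in the exposed group).
#'
#' @return Named list with `exposed` and `reference` character vectors.
#' @param contrast Contrast name, one of `ART_vs_natural`, `fresh_vs_natural`,
#'   `frozen_vs_natural`, `ICSI_vs_natural`, `IVF_vs_natural`, `ICSI_vs_IVF`,
#'   `fresh_vs_frozen`.
#' @export
contrast_groups <- function(contrast) {
  defs <- list(
    ART_vs_natural   = list(exposed = c("fresh_IVF", "fresh_ICSI", "frozen_IVF",
                                        "frozen_ICSI", "ART_unknown"),
                            reference = "natural"),
    fresh_vs_natural = list(exposed = c("fresh_IVF", "fresh_ICSI"),
                            reference = "natural"),
    frozen_vs_natural = list(exposed = c("frozen_IVF", "frozen_ICSI"),
                             reference = "natural"),
    ICSI_vs_natural  = list(exposed = c("fresh_ICSI", "frozen_ICSI"),
                            reference = "natural"),
    IVF_vs_natural   = list(exposed = c("fresh_IVF", "frozen_IVF"),
                            reference = "natural"),
    ICSI_vs_IVF      = list(exposed = c("fresh_ICSI", "frozen_ICSI"),
                            reference = c("fresh_IVF", "frozen_IVF")),
    fresh_vs_frozen  = list(exposed = c("fresh_IVF", "fresh_ICSI"),
                            reference = c("frozen_IVF", "frozen_ICSI")))
  if (!contrast %in% names(defs))
    .stop_config("unknown contrast '", contrast, "'; available: ",
                 paste(names(defs), collapse = ", "))
  defs[[contrast]]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic BH q-values: `q(i) = min_{j >= i} p(j) * m / j` over ascending p,
#' capped at 1, mapped back to the input order. `NA` entries stay `NA` and do
#' not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    .stop_data("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Fit one outcome vector against a 0/1 exposure with fixed covariates and a
# plate random intercept (REML); falls back to a single-variance OLS fit when
# only one plate level is present or the mixed fit fails.
.fit_one <- function(y, exposure, covars, plate, wald_ref = c("normal", "t"),
                     min_n = 10L) {
  wald_ref <- match.arg(wald_ref)
  skip <- function(reason)
    list(estimate = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
         n_used = 0L, method = NA_character_, skip_reason = reason)

  d <- data.frame(y = y, exposure = as.numeric(exposure), plate = plate,
                  covars, stringsAsFactors = FALSE)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < min_n) return(skip("insufficient_n"))
  if (length(unique(d$exposure)) < 2L) return(skip("single_exposure_group"))

  # drop factor covariates left with a single level after subsetting
  terms <- "exposure"
  for (cv in names(covars)) {
    x <- d[[cv]]
    if (is.character(x) || is.factor(x)) {
      d[[cv]] <- droplevels(factor(x))
      if (nlevels(d[[cv]]) < 2L) next
    }
    terms <- c(terms, cv)
  }
  form <- as.formula(paste("y ~", paste(terms, collapse = " + ")))

  method <- "lmm"
  fit <- NULL
  if (length(unique(d$plate)) >= 2L) {
    fit <- tryCatch(
      nlme::lme(fixed = form, random = ~ 1 | plate, data = d,
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    method <- "ols"
    fit <- tryCatch(lm(form, data = d), error = function(e) NULL)
    if (is.null(fit)) return(skip("fit_failed"))
  }
  est <- tryCatch(unname(nlme::fixef(fit)["exposure"]), error = function(e)
    unname(coef(fit)["exposure"]))
  se <- tryCatch(sqrt(diag(vcov(fit))[["exposure"]]), error = function(e) NA_real_)
  if (!is.finite(est) || !is.finite(se) || se <= 0)
    return(skip("degenerate_fit"))
  stat <- est / se
  p <- if (wald_ref == "normal") 2 * pnorm(-abs(stat))
       else 2 * pt(-abs(stat), df = nrow(d) - length(terms) - 1L)
  list(estimate = est, se = se, stat = stat, p = p, n_used = nrow(d),
       method = method, skip_reason = NA_character_)
}

#' Fit the per-CpG linear mixed model
#'
#' Models one CpG's (masked) beta values as a function of a binary exposure
#' plus fixed covariates, with a random intercept per plate, fitted by REML.
#' The Wald statistic `estimate / se` is referred to the standard normal
#' (two-sided) by default, togglable to a t reference with residual degrees
#' of freedom. When only one plate level is present (or the mixed fit is
#' singular) the model falls back to ordinary least squares, in which case
#' the estimate and SE equal the closed-form OLS solution on the same design.
#'
#' @param y Numeric outcome vector aligned with `samples` rows (beta values,
#'   already outlier-masked).
#' @param samples Sample table.
#' @param exposure Logical/0-1 exposure vector aligned with `samples` rows.
#' @param covariates Covariate column names (default: maternal age, smoking,
#'   BMI, parity). Complete-case restriction is applied per model.
#' @param wald_ref `"normal"` (default) or `"t"`.
#' @param min_n Minimum observations after complete-case restriction.
#' @return List: `estimate` (exposed minus reference), `se`, `stat`, `p`,
#'   `n_used`, `method` (`"lmm"` or `"ols"`), `skip_reason` (NA when fitted).
#' @export
fit_cpg_lmm <- function(y, samples, exposure,
                        covariates = .DEFAULT_COVARIATES,
                        wald_ref = "normal", min_n = 10L) {
  .fit_one(y, exposure, samples[, covariates, drop = FALSE],
           samples$plate_id, wald_ref = wald_ref, min_n = min_n)
}

#' Sex-stratified EWAS over all probes of a beta matrix
#'
#' For every probe and sex stratum: applies the per-CpG median +/- `mad_k` *
#' MAD outlier mask within the analysis subset, restricts to complete cases,
#' fits the plate-random-intercept mixed model for the requested conception
#' contrast, and computes BH q-values within each stratum over the probes
#' actually tested. Probes that cannot be fitted stay in the table with a
#' `skip_reason` and are excluded from the BH adjustment.
#'
#' @param beta Beta matrix (probes x samples).
#' @param samples Sample table covering the matrix columns.
#' @param annotation Optional probe annotation used to attach `chr`, `pos`,
#'   `gene`.
#' @param contrast Contrast name (see [contrast_groups()]).
#' @param strata Sex strata to analyze (default both; use `"pooled"` for a
#'   single unstratified analysis).
#' @param fdr FDR threshold recorded with the table (default 0.01).
#' @param mad_k MAD multiplier for outlier masking (default 5).
#' @param covariates Fixed covariates (see [fit_cpg_lmm()]).
#' @param transform `"beta"` models beta values directly (default);
#'   `"logit"` models logit(beta) (an M-value-style analysis; values at 0 or
#'   1 become missing).
#' @param wald_ref Wald reference distribution, `"normal"` or `"t"`.
#' @return data.frame with one row per probe per stratum: `probe_id`, `chr`,
#'   `pos`, `gene`, `stratum`, `contrast`, `n_used`, `estimate`, `se`, `stat`,
#'   `p`, `q`, `skip_reason`. Attribute `fdr` records the threshold.
#' @export
run_stratified_ewas <- function(beta, samples, annotation = NULL,
                                contrast = "ART_vs_natural",
                                strata = c("F", "M"), fdr = 0.01, mad_k = 5,
                                covariates = .DEFAULT_COVARIATES,
                                transform = c("beta", "logit"),
                                wald_ref = "normal") {
  transform <- match.arg(transform)
  groups <- contrast_groups(contrast)
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    .stop_data("beta matrix columns missing from sample table")

  out <- list()
  for (stratum in strata) {
    sub <- if (identical(stratum, "pooled")) samples
           else samples[samples$sex == stratum, , drop = FALSE]
    sub <- sub[sub$conception %in% c(groups$exposed, groups$reference), ,
               drop = FALSE]
    if (nrow(sub) == 0L) .stop_data("empty stratum: ", stratum)
    exposure <- sub$conception %in% groups$exposed
    covars <- sub[, covariates, drop = FALSE]
    bsub <- beta[, sub$sample_id, drop = FALSE]

    rows <- vector("list", nrow(bsub))
    for (j in seq_len(nrow(bsub))) {
      yv <- bsub[j, ]
      if (all(is.na(yv))) {
        rows[[j]] <- list(estimate = NA_real_, se = NA_real_, stat = NA_real_,
                          p = NA_real_, n_used = 0L, method = NA_character_,
                          skip_reason = "all_missing")
        next
      }
      yv <- mad_mask(yv, k = mad_k)$values
      if (transform == "logit") {
        yv[!is.na(yv) & (yv <= 0 | yv >= 1)] <- NA
        yv <- .logit(yv)
      }
      rows[[j]] <- .fit_one(yv, exposure, covars, sub$plate_id,
                            wald_ref = wald_ref)
    }
    tab <- data.frame(probe_id = rownames(bsub),
                      stratum = stratum, contrast = contrast,
                      n_used = vapply(rows, `[[`, integer(1), "n_used"),
                      estimate = vapply(rows, `[[`, numeric(1), "estimate"),
                      se = vapply(rows, `[[`, numeric(1), "se"),
                      stat = vapply(rows, `[[`, numeric(1), "stat"),
                      p = vapply(rows, `[[`, numeric(1), "p"),
                      skip_reason = vapply(rows, `[[`, character(1),
                                           "skip_reason"),
                      stringsAsFactors = FALSE)
    tab$q <- bh_fdr(tab$p)
    out[[stratum]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(annotation)) {
    m <- match(res$probe_id, annotation$probe_id)
    res$chr <- annotation$chr[m]
    res$pos <- annotation$pos[m]
    res$gene <- annotation$gene[m]
  } else {
    res$chr <- NA_integer_; res$pos <- NA_integer_; res$gene <- NA_character_
  }
  res <- res[, c("probe_id", "chr", "pos", "gene", "stratum", "contrast",
                 "n_used", "estimate", "se", "stat", "p", "q", "skip_reason")]
  attr(res, "fdr") <- fdr
  res
}

#' Probes significant in two EWAS tables
#'
#' Intersects the `q < fdr` sets of two EWAS tables (e.g. the girls' and
#' boys' strata) and flags per-probe direction concordance of the estimates.
#'
#' @param tableA,tableB EWAS tables from [run_stratified_ewas()].
#' @param fdr Significance threshold on q (default 0.01).
#' @return data.frame: `probe_id`, `estimate_A`, `estimate_B`, `concordant`.
#' @export
overlap_significant <- function(tableA, tableB, fdr = 0.01) {
  sigA <- tableA[!is.na(tableA$q) & tableA$q < fdr, , drop = FALSE]
  sigB <- tableB[!is.na(tableB$q) & tableB$q < fdr, , drop = FALSE]
  ids <- intersect(sigA$probe_id, sigB$probe_id)
  ea <- sigA$estimate[match(ids, sigA$probe_id)]
  eb <- sigB$estimate[match(ids, sigB$probe_id)]
  data.frame(probe_id = ids, estimate_A = ea, estimate_B = eb,
             concordant = sign(ea) == sign(eb), stringsAsFactors = FALSE)
}

#' Per-gene counts of significant CpGs
#'
#' Counts `q < fdr` CpGs per gene (probes without a gene are excluded; a
#' probe annotated to several genes counts once in each) and summarizes genes
#' by their number of significant CpGs.
#'
#' @param table EWAS table for one stratum/contrast.
#' @param annotation Probe annotation.
#' @param fdr Significance threshold on q.
#' @return List with `genes` (data.frame `gene`, `n_significant`) and
#'   `histogram` (data.frame `n_cpgs_per_gene`, `n_genes`, `genes`).
#' @export
gene_hit_summary <- function(table, annotation, fdr = 0.01) {
  gm <- annotation_gene_map(annotation)
  sig <- table$probe_id[!is.na(table$q) & table$q < fdr]
  hits <- gm[gm$probe_id %in% sig, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(list(genes = data.frame(gene = character(0),
                                   n_significant = integer(0)),
                histogram = data.frame(n_cpgs_per_gene = integer(0),
                                       n_genes = integer(0),
                                       genes = character(0))))
  cnt <- table(hits$gene)
  genes <- data.frame(gene = names(cnt), n_significant = as.integer(cnt),
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n_significant, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  hist_rows <- lapply(sort(unique(genes$n_significant)), function(k) {
    g <- genes$gene[genes$n_significant == k]
    data.frame(n_cpgs_per_gene = k, n_genes = length(g),
               genes = paste(g, collapse = ";"), stringsAsFactors = FALSE)
  })
  list(genes = genes, histogram = do.call(rbind, hist_rows))
}
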