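## ART x sex interaction: per-CpG interaction mixed models, per-gene
## sign-count chi-square, and the gene-level long-format block-wise
## permutation test.

#' Per-CpG ART-by-sex interaction model
#'
#' Pooled-sexes linear mixed model with ART, sex and ART x sex fixed effects
#' plus the standard covariates and a plate random intercept. The interaction
#' coefficient (effect in boys minus effect in girls, with girls as the sex
#' reference) is reported with its two-sided Wald p-value.
#'
#' @param y Masked beta vector aligned with `samples` rows.
#' @param samples Sample table (both sexes, both conception groups).
#' @param covariates Fixed covariate columns.
#' @param wald_ref Wald reference, `"normal"` (default) or `"t"`.
#' @return List: `estimate`, `se`, `stat`, `p`, `n_used`, `skip_reason`.
#' @export
fit_interaction_cpg <- function(y, samples, covariates = .DEFAULT_COVARIATES,
                                wald_ref = "normal") {
  skip <- function(reason)
    list(estimate = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
         n_used = 0L, skip_reason = reason)
  d <- data.frame(y = y, art = as.numeric(is_art(samples)),
                  sex = factor(samples$sex, levels = .SEX_LEVELS),
                  plate = samples$plate_id,
                  samples[, covariates, drop = FALSE],
                  stringsAsFactors = FALSE)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10L) return(skip("insufficient_n"))
  if (any(table(d$art, d$sex) == 0L)) return(skip("missing_cell"))

  terms <- character(0)
  for (cv in covariates) {
    x <- d[[cv]]
    if (is.character(x) || is.factor(x)) {
      d[[cv]] <- droplevels(factor(x))
      if (nlevels(d[[cv]]) < 2L) next
    }
    terms <- c(terms, cv)
  }
  form <- as.formula(paste(c("y ~ art * sex", terms), collapse = " + "))
  fit <- tryCatch(
    nlme::lme(fixed = form, random = ~ 1 | plate, data = d, method = "REML",
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) fit <- tryCatch(lm(form, data = d), error = function(e) NULL)
  if (is.null(fit)) return(skip("fit_failed"))
  cf <- tryCatch(nlme::fixef(fit), error = function(e) coef(fit))
  est <- unname(cf["art:sexM"])
  se <- tryCatch(sqrt(diag(vcov(fit))[["art:sexM"]]), error = function(e) NA_real_)
  if (!is.finite(est) || !is.finite(se) || se <= 0) return(skip("degenerate_fit"))
  stat <- est / se
  p <- if (wald_ref == "normal") 2 * pnorm(-abs(stat))
       else 2 * pt(-abs(stat), df = nrow(d) - length(cf))
  list(estimate = est, se = se, stat = stat, p = p, n_used = nrow(d),
       skip_reason = NA_character_)
}

#' Sign counts of per-CpG ART effects for one gene
#'
#' Crosses sex (rows: girls, boys) with the sign of the per-CpG ART-effect
#' estimate (columns: `+` hypermethylated, `-` hypomethylated) over the
#' gene's CpGs present with estimates in both stratified EWAS tables.
#' Estimates exactly 0 count as `+` (documented tie rule; probability-zero
#' with continuous data).
#'
#' @param girls,boys Stratified EWAS tables (see [run_stratified_ewas()]).
#' @param gene Gene symbol.
#' @param annotation Probe annotation.
#' @return 2x2 integer matrix, rows `girls`/`boys`, columns `+`/`-`.
#' @export
sign_count_table <- function(girls, boys, gene, annotation) {
  gm <- annotation_gene_map(annotation)
  probes <- gm$probe_id[gm$gene == gene]
  if (!length(probes)) .stop_data("gene not in annotation: ", gene)
  eg <- girls$estimate[match(probes, girls$probe_id)]
  eb <- boys$estimate[match(probes, boys$probe_id)]
  ok <- !is.na(eg) & !is.na(eb)
  if (!any(ok)) .stop_data("gene has no estimated CpGs in both tables: ", gene)
  m <- matrix(c(sum(eg[ok] >= 0), sum(eg[ok] < 0),
                sum(eb[ok] >= 0), sum(eb[ok] < 0)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("girls", "boys"), c("+", "-")))
  storage.mode(m) <- "integer"
  m
}

#' Long-format stack of one gene's CpGs
#'
#' One row per (individual, CpG) with the CpG's (outlier-masked) beta value
#' as outcome; the individual's ART status, sex and adjusting covariates are
#' replicated across that individual's rows, and the CpG identity is kept as
#' a column. Masked or missing (CpG, individual) cells are absent.
#'
#' @param beta Beta matrix.
#' @param annotation Probe annotation.
#' @param samples Sample table.
#' @param gene Gene symbol.
#' @param min_cpgs Minimum CpGs with data for eligibility (default 21, i.e.
#'   more than 20).
#' @param mad_k MAD multiplier for the per-CpG outlier mask (applied within
#'   the supplied samples); `NULL` disables masking.
#' @param covariates Covariate columns to carry along.
#' @return data.frame: `sample_id`, `cpg`, `beta`, `art`, `sex`, covariates.
#' @export
gene_stack_long <- function(beta, annotation, samples, gene, min_cpgs = 21L,
                            mad_k = 5, covariates = .DEFAULT_COVARIATES) {
  gm <- annotation_gene_map(annotation)
  probes <- intersect(gm$probe_id[gm$gene == gene], rownames(beta))
  probes <- probes[rowSums(!is.na(beta[probes, , drop = FALSE])) > 0L]
  if (length(probes) < min_cpgs)
    .stop_data("gene ", gene, " has ", length(probes),
               " CpGs with data; needs >= ", min_cpgs)
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  sub <- beta[probes, , drop = FALSE]
  if (!is.null(mad_k))
    sub <- t(apply(sub, 1L, function(v) mad_mask(v, k = mad_k)$values))
  long <- data.frame(
    sample_id = rep(colnames(sub), each = length(probes)),
    cpg = rep(probes, times = ncol(sub)),
    beta = as.vector(sub),
    stringsAsFactors = FALSE)
  m <- match(long$sample_id, samples$sample_id)
  long$art <- as.numeric(is_art(samples))[m]
  long$sex <- samples$sex[m]
  for (cv in covariates) long[[cv]] <- samples[[cv]][m]
  long <- long[!is.na(long$beta), , drop = FALSE]
  rownames(long) <- NULL
  long
}

# Design pieces for the stacked interaction model. Nuisance block: intercept,
# CpG fixed intercepts (unless stack_model = "plain"), covariates, ART main
# effect. Tested block: sex main effect and ART:sex.
.stack_design <- function(long, covariates, stack_model) {
  for (cv in covariates) {
    if (is.character(long[[cv]])) long[[cv]] <- factor(long[[cv]])
  }
  keep <- complete.cases(long[, c("beta", "art", "sex", covariates),
                         drop = FALSE])
  long <- long[keep, , drop = FALSE]
  cov_terms <- covariates[vapply(covariates, function(cv) {
    x <- long[[cv]]
    !is.factor(x) || nlevels(droplevels(x)) > 1L
  }, logical(1))]
  rhs <- c(if (stack_model == "cpg_intercepts" &&
               length(unique(long$cpg)) > 1L) "cpg",
           cov_terms, "art")
  Xn <- model.matrix(as.formula(paste("~", paste(rhs, collapse = " + "))),
                     data = long)
  sexm <- as.numeric(long$sex == "M")
  list(long = long, y = long$beta, Xn = Xn, sexm = sexm, art = long$art)
}

# t-statistic of the ART:sex coefficient given residualized tested columns.
.stack_t <- function(qr_n, y, Z) {
  ry <- qr.resid(qr_n, y)
  rZ <- qr.resid(qr_n, Z)
  XtX <- crossprod(rZ)
  b <- solve(XtX, crossprod(rZ, ry))
  res <- ry - rZ %*% b
  df <- length(y) - qr_n$rank - ncol(Z)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  list(estimate = b[ncol(Z)], t = b[ncol(Z)] / se[ncol(Z)], df = df)
}

#' Stacked ART-by-sex interaction statistic for one gene
#'
#' Ordinary least squares on the long-format stack: outcome = beta value,
#' fixed effects = CpG identity (CpG-specific intercepts, unless
#' `stack_model = "plain"`), covariates, ART, sex and ART x sex. Returns the
#' ART x sex coefficient and its naive t-statistic; inference is delegated
#' entirely to the block-wise permutation ([block_permutation_p()]), never to
#' the naive standard error, which ignores within-individual correlation.
#'
#' @param long Long table from [gene_stack_long()].
#' @param covariates Covariate columns present in `long`.
#' @param stack_model `"cpg_intercepts"` (default) or `"plain"`.
#' @return List: `estimate` (beta scale), `t`.
#' @export
stacked_interaction_stat <- function(long, covariates = .DEFAULT_COVARIATES,
                                     stack_model = c("cpg_intercepts",
                                                     "plain")) {
  stack_model <- match.arg(stack_model)
  ds <- .stack_design(long, covariates, stack_model)
  qr_n <- qr(ds$Xn)
  Z <- cbind(sex = ds$sexm, art_sex = ds$art * ds$sexm)
  if (qr(cbind(ds$Xn, Z))$rank < qr_n$rank + 2L)
    .stop_data("collinear stacked design")
  st <- .stack_t(qr_n, ds$y, Z)
  list(estimate = unname(st$estimate), t = unname(st$t))
}

.perm_pvalue <- function(t_obs, t_perm)
  (1 + sum(abs(t_perm) >= abs(t_obs))) / (length(t_perm) + 1)

#' Block-wise permutation p-value for the stacked interaction
#'
#' Generates the null distribution of the stacked ART x sex statistic by
#' permuting sex labels across individuals *within conception group*, each
#' individual's whole block of CpG rows carrying its permuted label, so
#' within-individual correlation is preserved and the ART margin is fixed.
#' The empirical p-value uses the add-one rule
#' `(1 + #\{b : |T_b| >= |T_obs|\}) / (B + 1)`, so its minimum is `1/(B+1)`.
#'
#' The `"freedman_lane"` scheme instead permutes individual-level residual
#' blocks of the reduced (no-interaction) model within conception group; it
#' requires every individual to have the same observed CpG set (no ragged
#' blocks) and errors otherwise, advising the label scheme.
#'
#' @param long Long table from [gene_stack_long()].
#' @param covariates Covariate columns.
#' @param B Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param scheme `"label"` (default) or `"freedman_lane"`.
#' @param stack_model `"cpg_intercepts"` or `"plain"`.
#' @return List: `p` (empirical p-value), `estimate`, `t_obs`, `t_perm`
#'   (length-B vector), `B`.
#' @export
block_permutation_p <- function(long, covariates = .DEFAULT_COVARIATES,
                                B = 999L, seed = 1L,
                                scheme = c("label", "freedman_lane"),
                                stack_model = c("cpg_intercepts", "plain")) {
  scheme <- match.arg(scheme)
  stack_model <- match.arg(stack_model)
  if (B < 99L) .stop_config("B must be >= 99")
  ds <- .stack_design(long, covariates, stack_model)
  ind <- unique(ds$long[, c("sample_id", "art", "sex")])
  if (length(unique(ind$sex)) < 2L || length(unique(ind$art)) < 2L)
    .stop_data("degenerate strata: need both sexes and both conception groups")
  row_ind <- match(ds$long$sample_id, ind$sample_id)

  # orthonormal basis of the nuisance column space, computed once; projecting
  # with Q is algebraically the same residualization the QR path performs
  qr_n <- qr(ds$Xn)
  Q <- qr.Q(qr_n)[, seq_len(qr_n$rank), drop = FALSE]
  proj_out <- function(v) v - Q %*% crossprod(Q, v)
  n_obs <- length(ds$y)
  df <- n_obs - qr_n$rank - 2L
  fast_fit <- function(ry, rZ) {
    XtX <- crossprod(rZ)
    b <- solve(XtX, crossprod(rZ, ry))
    res <- ry - rZ %*% b
    se <- sqrt(sum(res^2) / df * solve(XtX)[2L, 2L])
    c(estimate = b[2L], t = b[2L] / se)
  }

  Z_obs <- cbind(ds$sexm, ds$art * ds$sexm)
  ry <- proj_out(ds$y)
  obs <- fast_fit(ry, proj_out(Z_obs))
  set.seed(seed)
  t_perm <- numeric(B)

  if (scheme == "label") {
    art_groups <- split(seq_len(nrow(ind)), ind$art)
    for (b in seq_len(B)) {
      perm_sex <- ind$sex
      for (g in art_groups) perm_sex[g] <- ind$sex[g][sample(length(g))]
      sexm_b <- as.numeric(perm_sex == "M")[row_ind]
      Zb <- cbind(sexm_b, ds$art * sexm_b)
      t_perm[b] <- fast_fit(ry, proj_out(Zb))[["t"]]
    }
  } else {
    # Freedman-Lane: reduced model = nuisance + sex main effect; permute the
    # reduced-model residuals in individual blocks within conception group.
    cpg_sets <- vapply(split(ds$long$cpg, row_ind),
                       function(x) paste(sort(x), collapse = ","), "")
    if (length(unique(cpg_sets)) > 1L)
      .stop_data("freedman_lane scheme needs identical observed CpG sets per ",
                 "individual (ragged blocks found); use scheme = 'label'")
    qr_red <- qr(cbind(ds$Xn, sexm = ds$sexm))
    fit_red <- qr.fitted(qr_red, ds$y)
    res_red <- qr.resid(qr_red, ds$y)
    ord <- order(row_ind, ds$long$cpg)
    inv_ord <- order(ord)            # rows grouped by individual, cpg-sorted
    n_cpg <- length(unique(ds$long$cpg))
    res_blocks <- matrix(res_red[ord], nrow = n_cpg)  # one column per individual
    block_of <- unique(row_ind[ord])                  # individual per column
    art_groups <- split(seq_along(block_of), ind$art[block_of])
    rZ_obs <- proj_out(Z_obs)
    for (b in seq_len(B)) {
      cols <- seq_along(block_of)
      for (g in art_groups) cols[g] <- g[sample(length(g))]
      y_b <- fit_red + as.vector(res_blocks[, cols])[inv_ord]
      t_perm[b] <- fast_fit(proj_out(y_b), rZ_obs)[["t"]]
    }
  }
  list(p = .perm_pvalue(obs[["t"]], t_perm),
       estimate = unname(obs[["estimate"]]),
       t_obs = unname(obs[["t"]]), t_perm = t_perm, B = B)
}

#' Gene-level ART-by-sex interaction scan
#'
#' For every gene with more than `min_cpgs - 1` CpGs with data: tabulates the
#' per-CpG ART-effect signs by sex (from the stratified EWAS tables) with the
#' Yates-corrected chi-square test of independence, finds the lowest per-CpG
#' interaction p-value (pooled mixed model), and computes the stacked
#' interaction estimate with its block-wise permutation empirical p-value.
#' Empirical p-values are BH-adjusted across eligible genes.
#'
#' @param beta Beta matrix.
#' @param samples Sample table.
#' @param annotation Probe annotation.
#' @param girls,boys Stratified EWAS tables for the ART contrast.
#' @param B Permutations per gene (default 999).
#' @param min_cpgs Eligibility threshold: at least this many CpGs with data
#'   (default 21, i.e. more than 20).
#' @param fdr FDR threshold recorded with the table (default 0.05).
#' @param seed Base seed; gene `i` uses `seed + i`.
#' @param scheme,stack_model Passed to [block_permutation_p()].
#' @param cpg_level Compute the per-CpG interaction column (mixed model per
#'   CpG); set `FALSE` to skip it in large scans.
#' @param covariates Covariate columns.
#' @return data.frame, one row per eligible gene: `gene`, `chr`, `pos_start`,
#'   `pos_end`, `n_cpgs`, `girls_pos`, `girls_neg`, `boys_pos`, `boys_neg`,
#'   `chi2_p`, `lowest_cpg_p`, `interaction_estimate`, `empirical_p`, `q`.
#' @export
run_gene_interaction_scan <- function(beta, samples, annotation, girls, boys,
                                      B = 999L, min_cpgs = 21L, fdr = 0.05,
                                      seed = 1L, scheme = "label",
                                      stack_model = "cpg_intercepts",
                                      cpg_level = TRUE,
                                      covariates = .DEFAULT_COVARIATES) {
  gm <- annotation_gene_map(annotation)
  gm <- gm[gm$probe_id %in% rownames(beta), , drop = FALSE]
  counts <- table(gm$gene)
  eligible <- sort(names(counts)[counts >= min_cpgs])
  if (!length(eligible)) {
    warning("no genes with >= ", min_cpgs, " CpGs; empty interaction table")
    return(data.frame())
  }
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rows <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    g <- eligible[i]
    probes <- gm$probe_id[gm$gene == g]
    sc <- tryCatch(sign_count_table(girls, boys, g, annotation),
                   error = function(e) NULL)
    chi_p <- if (is.null(sc)) NA_real_ else
      tryCatch(chi2_independence(sc, continuity = TRUE)$p,
               error = function(e) NA_real_)
    low_p <- NA_real_
    if (cpg_level) {
      ps <- vapply(probes, function(pr) {
        yv <- mad_mask(beta[pr, ])$values
        fit_interaction_cpg(yv, samples, covariates = covariates)$p
      }, numeric(1))
      if (any(!is.na(ps))) low_p <- min(ps, na.rm = TRUE)
    }
    long <- tryCatch(gene_stack_long(beta, annotation, samples, g,
                                     min_cpgs = min_cpgs,
                                     covariates = covariates),
                     error = function(e) NULL)
    if (is.null(long)) next
    perm <- block_permutation_p(long, covariates = covariates, B = B,
                                seed = seed + i, scheme = scheme,
                                stack_model = stack_model)
    idx <- match(probes, annotation$probe_id)
    rows[[i]] <- data.frame(
      gene = g, chr = annotation$chr[idx[1]],
      pos_start = min(annotation$pos[idx]), pos_end = max(annotation$pos[idx]),
      n_cpgs = length(probes),
      girls_pos = if (is.null(sc)) NA_integer_ else sc["girls", "+"],
      girls_neg = if (is.null(sc)) NA_integer_ else sc["girls", "-"],
      boys_pos = if (is.null(sc)) NA_integer_ else sc["boys", "+"],
      boys_neg = if (is.null(sc)) NA_integer_ else sc["boys", "-"],
      chi2_p = chi_p, lowest_cpg_p = low_p,
      interaction_estimate = perm$estimate, empirical_p = perm$p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$empirical_p)
  attr(res, "fdr") <- fdr
  res
}

#' Per-gene T-statistic track for plotting
#'
#' Exports, for one gene, each CpG's position and the sex-specific ART
#' Wald statistics from the two stratified EWAS tables — the data behind
#' per-gene association track figures.
#'
#' @param girls,boys Stratified EWAS tables.
#' @param gene Gene symbol.
#' @param annotation Probe annotation.
#' @return data.frame: `probe_id`, `chr`, `pos`, `stat_girls`, `stat_boys`.
#' @export
gene_stat_track <- function(girls, boys, gene, annotation) {
  gm <- annotation_gene_map(annotation)
  probes <- gm$probe_id[gm$gene == gene]
  if (!length(probes)) .stop_data("gene not in annotation: ", gene)
  idx <- match(probes, annotation$probe_id)
  out <- data.frame(probe_id = probes,
                    chr = annotation$chr[idx], pos = annotation$pos[idx],
                    stat_girls = girls$stat[match(probes, girls$probe_id)],
                    stat_boys = boys$stat[match(probes, boys$probe_id)],
                    stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}
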