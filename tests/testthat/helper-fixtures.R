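# Shared fixtures: small synthetic datasets built in code.

tiny_config <- function(seed = 42, ...) {
  args <- list(n_samples_per_sex = 100L, art_fraction = 0.5, n_probes = 60L,
               n_genes = 2L, cpgs_per_gene = c(21L, 23L),
               frac_genes_eligible = 1, n_plates = 4L,
               covariate_missing_rate = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(effect_config, args)
}

tiny_dataset <- function(seed = 42, ...) {
  cfg <- tiny_config(seed = seed, ...)
  samples <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  gen <- generate_beta_matrix(samples, ann, cfg)
  list(cfg = cfg, samples = samples, ann = ann, beta = gen$beta,
       truth = gen$truth)
}

# closed-form OLS via the normal equations: the independent oracle for the
# single-plate mixed-model fallback
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  r <- y - X %*% b
  s2 <- sum(r^2) / (nrow(X) - ncol(X))
  list(coef = drop(b), se = sqrt(s2 * diag(solve(XtX))))
}

# brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# point and take the sup difference
ks_brute_force <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  f1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  f2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(f1 - f2))
}

# an EWAS-shaped table with chosen estimates/q values for bookkeeping tests
fake_ewas_table <- function(probe_ids, estimates, q = rep(1, length(probe_ids)),
                            stratum = "F") {
  data.frame(probe_id = probe_ids, chr = 1L, pos = seq_along(probe_ids),
             gene = "", stratum = stratum, contrast = "ART_vs_natural",
             n_used = 100L, estimate = estimates, se = 1,
             stat = estimates, p = q, q = q, skip_reason = NA_character_,
             stringsAsFactors = FALSE)
}
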