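test_that("BH step-up matches the by-hand example and tie/edge conventions", {
  # by hand, m = 4: 0.001*4/1, 0.01*4/2, 0.02*4/3, 0.8*4/4; min-cascade leaves
  # the sequence unchanged (already monotone)
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.08 / 3, 0.8))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("BH q-values dominate p elementwise and are monotone in ascending p", {
  set.seed(20)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("single-plate mixed fit equals closed-form OLS to 6 significant digits", {
  set.seed(22)
  n <- 80
  s <- data.frame(sample_id = as.character(1:n),
                  sex = "F",
                  conception = sample(c("natural", "fresh_IVF"), n, TRUE),
                  maternal_age = rnorm(n, 31, 4),
                  maternal_smoking = sample(c("never", "former"), n, TRUE),
                  maternal_bmi = rnorm(n, 24, 3),
                  parity = sample(c("nulliparous", "multiparous"), n, TRUE),
                  plate_id = "P1", stringsAsFactors = FALSE)
  y <- plogis(rnorm(n, 0, 0.4))
  exposure <- is_art(s)
  fit <- fit_cpg_lmm(y, s, exposure)
  expect_identical(fit$method, "ols")

  X <- model.matrix(~ exposure + maternal_age + maternal_smoking +
                      maternal_bmi + parity,
                    data = cbind(s, exposure = as.numeric(exposure)))
  oracle <- ols_oracle(X, y)
  expect_equal(fit$estimate, unname(oracle$coef["exposure"]), tolerance = 1e-6)
  expect_equal(fit$se, unname(oracle$se["exposure"]), tolerance = 1e-6)
})

test_that("flipping the exposure coding negates the estimate, keeps |Wald|", {
  d <- tiny_dataset(seed = 23)
  sF <- d$samples[d$samples$sex == "F", ]
  y <- d$beta[1, sF$sample_id]
  a <- fit_cpg_lmm(y, sF, is_art(sF))
  b <- fit_cpg_lmm(y, sF, !is_art(sF))
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-6)
  expect_equal(abs(a$stat), abs(b$stat), tolerance = 1e-6)
})

test_that("degenerate and underpowered probes are skipped with a reason", {
  d <- tiny_dataset(seed = 24)
  sF <- d$samples[d$samples$sex == "F", ]
  # outcome exactly equal to the exposure indicator: zero residual variance
  y <- as.numeric(is_art(sF))
  fit <- fit_cpg_lmm(y, sF, is_art(sF))
  expect_true(!is.na(fit$skip_reason) || !is.finite(fit$stat) ||
                abs(fit$stat) > 1e6)
  few <- fit_cpg_lmm(c(0.5, 0.4, rep(NA, nrow(sF) - 2)), sF, is_art(sF))
  expect_identical(few$skip_reason, "insufficient_n")
  one_group <- fit_cpg_lmm(d$beta[2, sF$sample_id], sF,
                           rep(TRUE, nrow(sF)))
  expect_identical(one_group$skip_reason, "single_exposure_group")
})

test_that("stratified EWAS is deterministic and keeps skipped probes out of BH", {
  d <- tiny_dataset(seed = 25)
  beta <- d$beta
  beta[3, d$samples$sample_id[d$samples$sex == "F"]] <- NA
  t1 <- run_stratified_ewas(beta, d$samples, d$ann)
  t2 <- run_stratified_ewas(beta, d$samples, d$ann)
  expect_identical(t1, t2)
  rowF <- t1[t1$stratum == "F" & t1$probe_id == rownames(beta)[3], ]
  expect_identical(rowF$skip_reason, "all_missing")
  expect_true(is.na(rowF$q))
  tested <- t1[t1$stratum == "F" & is.na(t1$skip_reason), ]
  expect_equal(tested$q, bh_fdr(tested$p))
  expect_true(all(t1$probe_id %in% rownames(beta)))
  expect_identical(nrow(t1), 2L * nrow(beta))
})

test_that("EWAS recovers strong injected effects with FDR held", {
  cfg <- effect_config(n_samples_per_sex = 300L, art_fraction = 0.5,
                       n_probes = 110L, n_genes = 1L, cpgs_per_gene = c(5L, 5L),
                       frac_art_affected_girls = 10 / 110, delta_girls = 1.5,
                       covariate_missing_rate = 0, seed = 26)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  gen <- generate_beta_matrix(s, ann, cfg)
  tab <- run_stratified_ewas(gen$beta, s, ann, strata = "F")
  truth_pos <- gen$truth$probe_id[gen$truth$delta_girls != 0]
  found <- tab$probe_id[!is.na(tab$q) & tab$q < 0.01]
  expect_gte(sum(truth_pos %in% found), 0.8 * length(truth_pos))
  expect_lte(sum(!(found %in% truth_pos)), 1L)
})

test_that("overlap of significant sets intersects and flags concordance", {
  a <- fake_ewas_table(paste0("cg", 1:6), estimates = c(1, 1, -1, 1, 1, 1),
                       q = c(0.001, 0.001, 0.001, 0.5, 0.5, 0.001))
  b <- fake_ewas_table(paste0("cg", 1:6), estimates = c(1, -1, -1, 1, 1, 1),
                       q = c(0.001, 0.001, 0.001, 0.001, 0.5, 0.5),
                       stratum = "M")
  ov <- overlap_significant(a, b, fdr = 0.01)
  expect_setequal(ov$probe_id, c("cg1", "cg2", "cg3"))
  expect_identical(ov$concordant[match(c("cg1", "cg2", "cg3"), ov$probe_id)],
                   c(TRUE, FALSE, TRUE))
  none <- overlap_significant(a, fake_ewas_table("cg9", 1, q = 0.001), 0.01)
  expect_identical(nrow(none), 0L)
  self <- overlap_significant(a, a, fdr = 0.01)
  expect_setequal(self$probe_id, c("cg1", "cg2", "cg3", "cg6"))
})

test_that("gene hit summary counts multi-gene probes once per gene", {
  ann <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4"),
                    chr = 1L, pos = 1:4,
                    gene = c("A", "A;B", "B", ""))
  tab <- fake_ewas_table(ann$probe_id, estimates = 1,
                         q = c(0.001, 0.001, 0.5, 0.001))
  gh <- gene_hit_summary(tab, ann, fdr = 0.01)
  expect_identical(gh$genes$n_significant[gh$genes$gene == "A"], 2L)
  expect_identical(gh$genes$n_significant[gh$genes$gene == "B"], 1L)
  expect_identical(sum(gh$histogram$n_genes), 2L)
  empty <- gene_hit_summary(fake_ewas_table("cg1", 1, q = 0.9), ann, 0.01)
  expect_identical(nrow(empty$genes), 0L)
})
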