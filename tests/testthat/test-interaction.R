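test_that("sign counts cross sex with estimate sign, rows transpose when sexes swap", {
  # 86-CpG gene with signs fixed to the published RXRA-style pattern:
  # girls 33+/53-, boys 57+/29-
  probes <- sprintf("cg%03d", 1:86)
  ann <- data.frame(probe_id = probes, chr = 9L, pos = seq_along(probes),
                    gene = "RXRA_like")
  girls <- fake_ewas_table(probes, estimates = c(rep(1, 33), rep(-1, 53)))
  boys <- fake_ewas_table(probes, estimates = c(rep(1, 57), rep(-1, 29)),
                          stratum = "M")
  sc <- sign_count_table(girls, boys, "RXRA_like", ann)
  expect_identical(sc, matrix(c(33L, 53L, 57L, 29L), 2, byrow = TRUE,
                              dimnames = list(c("girls", "boys"), c("+", "-"))))
  swapped <- sign_count_table(boys, girls, "RXRA_like", ann)
  expect_identical(unname(swapped), unname(sc[2:1, , drop = FALSE]))
  expect_error(sign_count_table(girls, boys, "absent", ann), "absent")
})

test_that("all-positive estimates in both sexes give a degenerate chi-square margin", {
  probes <- sprintf("cg%03d", 1:30)
  ann <- data.frame(probe_id = probes, chr = 1L, pos = seq_along(probes),
                    gene = "G")
  girls <- fake_ewas_table(probes, estimates = rep(1, 30))
  boys <- fake_ewas_table(probes, estimates = rep(1, 30), stratum = "M")
  sc <- sign_count_table(girls, boys, "G", ann)
  expect_identical(unname(sc[, "-"]), c(0L, 0L))
  expect_error(chi2_independence(sc), "zero row or column")
})

test_that("zero estimates count as hypermethylated (documented tie rule)", {
  probes <- c("cg1", "cg2")
  ann <- data.frame(probe_id = probes, chr = 1L, pos = 1:2, gene = "G")
  girls <- fake_ewas_table(probes, estimates = c(0, -1))
  boys <- fake_ewas_table(probes, estimates = c(-1, 0), stratum = "M")
  sc <- sign_count_table(girls, boys, "G", ann)
  expect_identical(unname(sc["girls", ]), c(1L, 1L))
  expect_identical(unname(sc["boys", ]), c(1L, 1L))
})

test_that("long-format stack has one row per observed (individual, CpG) cell", {
  cfg <- tiny_config(seed = 27, n_samples_per_sex = 50L, n_probes = 25L,
                     n_genes = 1L, cpgs_per_gene = c(25L, 25L),
                     frac_probes_no_gene = 0)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  beta <- generate_beta_matrix(s, ann, cfg)$beta
  gene <- unique(ann$gene[ann$gene != ""])
  long <- gene_stack_long(beta, ann, s, gene, mad_k = NULL)
  expect_identical(nrow(long), 100L * 25L)
  # wide reconstruction from long equals the original matrix (pivot oracle)
  wide <- matrix(NA_real_, 25L, 100L,
                 dimnames = list(sort(rownames(beta)), colnames(beta)))
  wide[cbind(long$cpg, long$sample_id)] <- long$beta
  expect_equal(wide[rownames(beta), ], beta)

  # masked cells are absent from the long table
  beta2 <- beta
  beta2[1, 1] <- NA
  long2 <- gene_stack_long(beta2, ann, s, gene, mad_k = NULL)
  expect_identical(nrow(long2), 100L * 25L - 1L)
  expect_error(gene_stack_long(beta[1:10, ], ann, s, gene, mad_k = NULL),
               "needs >= 21")
})

test_that("stacked statistic equals the full OLS interaction fit", {
  cfg <- tiny_config(seed = 28, n_samples_per_sex = 60L)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  beta <- generate_beta_matrix(s, ann, cfg)$beta
  gene <- names(which.max(table(ann$gene[ann$gene != ""])))
  long <- gene_stack_long(beta, ann, s, gene)
  st <- stacked_interaction_stat(long)
  ref <- lm(beta ~ cpg + maternal_age + maternal_smoking + maternal_bmi +
              parity + art + sex + art:sex,
            data = transform(long, sex = factor(sex, levels = c("F", "M"))))
  cf <- summary(ref)$coefficients["art:sexM", ]
  expect_equal(st$estimate, unname(cf["Estimate"]), tolerance = 1e-8)
  expect_equal(st$t, unname(cf["t value"]), tolerance = 1e-8)
})

test_that("one-CpG stack reduces to the plain interaction regression", {
  cfg <- tiny_config(seed = 29, n_samples_per_sex = 80L)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  beta <- generate_beta_matrix(s, ann, cfg)$beta
  gene <- unique(ann$gene[ann$gene != ""])[1]
  pr <- ann$probe_id[ann$gene == gene][1]
  long <- gene_stack_long(beta, ann[ann$probe_id == pr, ], s, gene,
                          min_cpgs = 1L, mad_k = NULL)
  st <- stacked_interaction_stat(long)
  ref <- lm(y ~ art * sex + maternal_age + maternal_smoking + maternal_bmi +
              parity,
            data = data.frame(y = beta[pr, s$sample_id],
                              art = as.numeric(is_art(s)),
                              sex = factor(s$sex, levels = c("F", "M")),
                              s[, c("maternal_age", "maternal_smoking",
                                    "maternal_bmi", "parity")]))
  expect_equal(st$estimate, unname(coef(ref)["art:sexM"]), tolerance = 1e-8)
})

test_that("stacked estimate is invariant to CpG-level shifts and row duplication", {
  cfg <- tiny_config(seed = 30, n_samples_per_sex = 50L)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  beta <- generate_beta_matrix(s, ann, cfg)$beta
  gene <- names(which.max(table(ann$gene[ann$gene != ""])))
  long <- gene_stack_long(beta, ann, s, gene, mad_k = NULL)
  st <- stacked_interaction_stat(long)

  shifted <- long
  one_cpg <- shifted$cpg == shifted$cpg[1]
  shifted$beta[one_cpg] <- shifted$beta[one_cpg] + 0.17
  expect_equal(stacked_interaction_stat(shifted)$estimate, st$estimate,
               tolerance = 1e-8)

  doubled <- rbind(long, long)
  expect_equal(stacked_interaction_stat(doubled)$estimate, st$estimate,
               tolerance = 1e-8)
})

test_that("relabelling the sexes flips the interaction estimate's sign", {
  d <- tiny_dataset(seed = 32, n_samples_per_sex = 150L)
  y <- mad_mask(d$beta[5, ])$values
  a <- fit_interaction_cpg(y, d$samples)
  swapped <- d$samples
  swapped$sex <- ifelse(d$samples$sex == "F", "M", "F")
  b <- fit_interaction_cpg(y, swapped)
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
  # a missing design cell is skipped with a reason
  no_art_f <- d$samples[!(d$samples$sex == "F" & is_art(d$samples)), ]
  res <- fit_interaction_cpg(d$beta[5, no_art_f$sample_id], no_art_f)
  expect_identical(res$skip_reason, "missing_cell")
})

test_that("empirical p-values honour the add-one rule", {
  perm_p <- artewas:::.perm_pvalue
  expect_equal(perm_p(0, rnorm(199)), 1)           # |T_b| >= 0 always
  expect_equal(perm_p(10, rnorm(199)), 1 / 200)    # nothing beats T_obs
  expect_gte(perm_p(1.5, rnorm(199)), 1 / 200)
})

test_that("block permutation is deterministic per seed and both schemes run", {
  cfg <- tiny_config(seed = 33, n_samples_per_sex = 50L)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  beta <- generate_beta_matrix(s, ann, cfg)$beta
  gene <- names(which.max(table(ann$gene[ann$gene != ""])))
  long <- gene_stack_long(beta, ann, s, gene, mad_k = NULL)

  a <- block_permutation_p(long, B = 99, seed = 5)
  b <- block_permutation_p(long, B = 99, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 100)
  expect_lte(a$p, 1)

  fl <- block_permutation_p(long, B = 99, seed = 5, scheme = "freedman_lane")
  expect_gte(fl$p, 1 / 100)
  expect_lte(fl$p, 1)
  expect_equal(fl$t_obs, a$t_obs)  # observed statistic identical across schemes

  ragged <- long[-1, ]
  expect_error(block_permutation_p(ragged, B = 99, scheme = "freedman_lane"),
               "ragged")
  expect_error(block_permutation_p(long, B = 10), ">= 99")
})

test_that("gene scan fills every summary column and conserves sign counts", {
  d <- tiny_dataset(seed = 34)
  ew <- run_stratified_ewas(d$beta, d$samples, d$ann)
  girls <- ew[ew$stratum == "F", ]
  boys <- ew[ew$stratum == "M", ]
  scan <- run_gene_interaction_scan(d$beta, d$samples, d$ann, girls, boys,
                                    B = 99, seed = 2)
  expect_setequal(scan$gene, unique(d$ann$gene[d$ann$gene != ""]))
  for (i in seq_len(nrow(scan))) {
    expect_identical(scan$girls_pos[i] + scan$girls_neg[i], scan$n_cpgs[i])
    expect_identical(scan$boys_pos[i] + scan$boys_neg[i], scan$n_cpgs[i])
  }
  expect_true(all(scan$empirical_p >= 1 / 100 & scan$empirical_p <= 1))
  expect_equal(scan$q, bh_fdr(scan$empirical_p))
  expect_true(all(!is.na(scan$lowest_cpg_p)))
  # no eligible genes -> empty with warning
  expect_warning(
    empty <- run_gene_interaction_scan(d$beta, d$samples, d$ann, girls, boys,
                                       B = 99, min_cpgs = 1000L),
    "no genes")
  expect_identical(nrow(empty), 0L)
})

test_that("per-gene statistic track orders CpGs by position with both sexes", {
  d <- tiny_dataset(seed = 35)
  ew <- run_stratified_ewas(d$beta, d$samples, d$ann)
  gene <- unique(d$ann$gene[d$ann$gene != ""])[1]
  tr <- gene_stat_track(ew[ew$stratum == "F", ], ew[ew$stratum == "M", ],
                        gene, d$ann)
  expect_true(all(diff(tr$pos) > 0))
  expect_identical(nrow(tr), sum(d$ann$gene == gene))
  expect_true(all(is.finite(tr$stat_girls)))
  expect_true(all(is.finite(tr$stat_boys)))
})
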