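test_that("generator is deterministic: same seed and config give identical output", {
  a <- tiny_dataset(seed = 7)
  b <- tiny_dataset(seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ann, b$ann)
  expect_identical(a$beta, b$beta)
  c <- tiny_dataset(seed = 8)
  expect_false(identical(a$beta, c$beta))
})

test_that("generated beta values lie strictly in (0, 1)", {
  d <- tiny_dataset(seed = 3)
  expect_true(all(d$beta > 0 & d$beta < 1))
})

test_that("confounding = 0 makes ART independent of maternal covariates", {
  cfg <- effect_config(n_samples_per_sex = 1000L, art_fraction = 0.5,
                       confounding = 0, seed = 11)
  s <- generate_cohort(cfg)
  art <- as.numeric(is_art(s))
  expect_lt(abs(cor(art, s$maternal_age)), 0.1)
  expect_lt(abs(cor(art, as.numeric(s$parity == "nulliparous"))), 0.1)
})

test_that("confounding = 1 reproduces older, more nulliparous ART mothers", {
  cfg <- effect_config(n_samples_per_sex = 1000L, seed = 12)
  s <- generate_cohort(cfg)
  art <- is_art(s)
  expect_gt(mean(s$maternal_age[art]) - mean(s$maternal_age[!art]), 2)
  expect_gt(mean(s$parity[art] == "nulliparous"),
            mean(s$parity[!art] == "nulliparous"))
})

test_that("ART counts stay within binomial 99% bounds per sex", {
  cfg <- effect_config(n_samples_per_sex = 1000L, art_fraction = 0.5, seed = 5)
  s <- generate_cohort(cfg)
  bounds <- qbinom(c(0.005, 0.995), 1000L, 0.5)
  for (sx in c("F", "M")) {
    n_art <- sum(is_art(s) & s$sex == sx)
    expect_gte(n_art, bounds[1])
    expect_lte(n_art, bounds[2])
  }
  expect_false(anyDuplicated(s$sample_id) > 0)
  expect_true(all(table(s$sex) == 1000L))
  expect_true(all(s$plate_id %in% sprintf("P%02d", 1:20)))
  # ART newborns carry a subtype, natural ones do not
  expect_true(all(s$conception[is_art(s)] != "natural"))
})

test_that("annotation honours an exact genes-by-CpGs layout on autosomes", {
  cfg <- effect_config(n_probes = 125L, n_genes = 5L,
                       cpgs_per_gene = c(25L, 25L), frac_probes_no_gene = 0,
                       seed = 9)
  ann <- generate_probe_annotation(cfg)
  counts <- table(ann$gene[ann$gene != ""])
  expect_length(counts, 5L)
  expect_true(all(counts == 25L))
  expect_true(all(ann$chr %in% 1:22))
  for (c_ in unique(ann$chr)) {
    pos <- ann$pos[ann$chr == c_]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("annotation leaves the configured fraction of probes intergenic", {
  cfg <- effect_config(n_probes = 500L, n_genes = 10L,
                       cpgs_per_gene = c(5L, 10L), seed = 2)
  ann <- generate_probe_annotation(cfg)
  expect_identical(nrow(ann), 500L)
  expect_gt(sum(ann$gene == ""), 0L)
})

test_that("with all deltas zero the per-probe two-group t rejection rate is nominal", {
  cfg <- effect_config(n_samples_per_sex = 200L, art_fraction = 0.5,
                       n_probes = 1000L, n_genes = 1L,
                       cpgs_per_gene = c(5L, 5L), plate_sd = 0,
                       confounding = 0, covariate_missing_rate = 0, seed = 21)
  s <- generate_cohort(cfg)
  ann <- generate_probe_annotation(cfg)
  beta <- generate_beta_matrix(s, ann, cfg)$beta
  art <- is_art(s)
  p <- apply(beta, 1L, function(v)
    t.test(v[art], v[!art])$p.value)
  rate <- mean(p < 0.05)
  tol <- 2 * sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(rate - 0.05), tol)
})

test_that("truth table flags interactions exactly where the sex deltas differ", {
  d <- tiny_dataset(seed = 13, frac_art_affected_girls = 0.3, delta_girls = 0.4,
                    frac_interaction = 0.2, delta_interaction = 0.8)
  tr <- d$truth
  expect_identical(tr$is_interaction, tr$delta_girls != tr$delta_boys)
  expect_gt(sum(tr$is_interaction), 0L)
  # whole-gene interaction injection marks every CpG of the chosen gene
  d2 <- tiny_dataset(seed = 13, n_interaction_genes = 1L,
                     delta_interaction = 0.8)
  genes_hit <- unique(d2$truth$gene[d2$truth$is_interaction])
  expect_length(genes_hit, 1L)
  expect_true(all(d2$truth$is_interaction[d2$truth$gene == genes_hit]))
})

test_that("invalid configurations are rejected by name", {
  expect_error(effect_config(art_fraction = 1.2), "art_fraction")
  expect_error(effect_config(n_samples_per_sex = 0), "n_samples_per_sex")
  expect_error(effect_config(plate_sd = -1), "plate_sd")
  expect_error(effect_config(baseline_mix = c(0, 0.8, 0.5)), "baseline_mix")
  expect_error(effect_config(cpgs_per_gene = c(10, 5)), "cpgs_per_gene")
  expect_error(generate_probe_annotation(
    effect_config(n_probes = 10L, n_genes = 5L, cpgs_per_gene = c(25L, 25L))),
    "too small")
})
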