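#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic data generator: cohort size and
#' composition, probe/gene layout, injected ART effects on the logit(beta)
#' scale, variance components, and the ART-covariate confounding strength.
#' Defaults emulate the structure of a two-sex, two-conception-group newborn
#' cohort of roughly 1,000 children per sex with a plate random effect and a
#' bimodal baseline beta-value distribution, as seen on Illumina-style
#' methylation arrays.
#'
#' @param n_samples_per_sex Number of newborns per sex.
#' @param art_fraction Probability that a newborn is ART-conceived.
#' @param n_probes Total number of CpG probes (gene-annotated plus intergenic).
#' @param n_genes Number of genes to lay out.
#' @param cpgs_per_gene Length-2 vector `c(min, max)`: range of CpG counts per
#'   gene (uniform draw).
#' @param frac_genes_eligible Fraction of genes forced to have more than 20
#'   CpGs so the gene-level interaction scan has eligible genes. Ignored when
#'   the `cpgs_per_gene` range already lies entirely above (or below) 20.
#' @param frac_probes_no_gene Fraction of probes left without a gene label
#'   (intergenic). Probes left over after the gene layout also stay unlabelled.
#' @param frac_art_affected_girls,frac_art_affected_boys Fraction of probes
#'   with a true ART effect in girls / boys.
#' @param delta_girls,delta_boys Injected ART effect sizes on the logit(beta)
#'   scale for affected probes.
#' @param frac_interaction Fraction of probes (chosen independently) given a
#'   sex-differential ART effect: at those probes the boys' effect is set to
#'   the girls' effect plus `delta_interaction`.
#' @param delta_interaction Difference (boys minus girls) in the injected ART
#'   effect at interaction probes, logit scale.
#' @param n_interaction_genes Number of genes whose entire CpG set is given the
#'   interaction effect (for gene-level power studies); genes with > 20 CpGs
#'   are used first.
#' @param plate_sd Standard deviation of the plate random intercept
#'   (logit scale).
#' @param residual_sd Residual standard deviation (logit scale).
#' @param n_plates Number of processing plates; samples are split evenly.
#' @param baseline_mix Named vector `c(mode1, mode2, weight)`: the two modes of
#'   the bimodal baseline beta distribution, strictly inside (0, 1), and the
#'   mixing weight of the low mode.
#' @param baseline_jitter_sd SD of the logit-scale jitter around each mode.
#' @param confounding Strength in `[0, 1]` of the ART association with
#'   maternal age and nulliparity (1 reproduces cohort-typical gaps of about
#'   +3.2 years of maternal age and +23 percentage points nulliparity among
#'   ART mothers; 0 makes ART independent of all covariates).
#' @param covariate_effects Named vector of logit-scale methylation effects:
#'   `maternal_age` (per year, centred), `maternal_bmi` (per kg/m^2, centred),
#'   `smoking` (per ordinal smoking level), `parity` (multiparous vs
#'   nulliparous). Small nonzero defaults so confounding adjustment is
#'   exercised.
#' @param subtype_probs Named probabilities over ART subtypes
#'   (`fresh_IVF`, `fresh_ICSI`, `frozen_IVF`, `frozen_ICSI`, `ART_unknown`).
#' @param covariate_missing_rate Probability that maternal BMI or gestational
#'   age is missing for a sample.
#' @param seed Integer seed; each generator derives its own sub-stream
#'   deterministically from it.
#'
#' @return A validated list of class `effect_config`.
#' @export
effect_config <- function(n_samples_per_sex = 1000L,
                          art_fraction = 0.49,
                          n_probes = 1000L,
                          n_genes = 20L,
                          cpgs_per_gene = c(min = 5L, max = 30L),
                          frac_genes_eligible = 0.25,
                          frac_probes_no_gene = 0.10,
                          frac_art_affected_girls = 0,
                          frac_art_affected_boys = 0,
                          delta_girls = 0,
                          delta_boys = 0,
                          frac_interaction = 0,
                          delta_interaction = 0,
                          n_interaction_genes = 0L,
                          plate_sd = 0.1,
                          residual_sd = 0.4,
                          n_plates = 20L,
                          baseline_mix = c(mode1 = 0.15, mode2 = 0.85, weight = 0.4),
                          baseline_jitter_sd = 0.5,
                          confounding = 1,
                          covariate_effects = c(maternal_age = 0.005,
                                                maternal_bmi = 0.003,
                                                smoking = 0.02,
                                                parity = 0.03),
                          subtype_probs = c(fresh_IVF = 0.455, fresh_ICSI = 0.34,
                                            frozen_IVF = 0.09, frozen_ICSI = 0.04,
                                            ART_unknown = 0.075),
                          covariate_missing_rate = 0.01,
                          seed = 1L) {
  cfg <- list(n_samples_per_sex = as.integer(n_samples_per_sex),
              art_fraction = art_fraction,
              n_probes = as.integer(n_probes),
              n_genes = as.integer(n_genes),
              cpgs_per_gene = as.integer(cpgs_per_gene),
              frac_genes_eligible = frac_genes_eligible,
              frac_probes_no_gene = frac_probes_no_gene,
              frac_art_affected_girls = frac_art_affected_girls,
              frac_art_affected_boys = frac_art_affected_boys,
              delta_girls = delta_girls,
              delta_boys = delta_boys,
              frac_interaction = frac_interaction,
              delta_interaction = delta_interaction,
              n_interaction_genes = as.integer(n_interaction_genes),
              plate_sd = plate_sd,
              residual_sd = residual_sd,
              n_plates = as.integer(n_plates),
              baseline_mix = baseline_mix,
              baseline_jitter_sd = baseline_jitter_sd,
              confounding = confounding,
              covariate_effects = covariate_effects,
              subtype_probs = subtype_probs,
              covariate_missing_rate = covariate_missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "effect_config"
  validate_effect_config(cfg)
  cfg
}

#' Validate an `effect_config`
#'
#' @param cfg An `effect_config` list.
#' @return `cfg`, invisibly, after checks.
#' @export
validate_effect_config <- function(cfg) {
  props <- c("art_fraction", "frac_genes_eligible", "frac_probes_no_gene",
             "frac_art_affected_girls", "frac_art_affected_boys",
             "frac_interaction", "confounding", "covariate_missing_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      .stop_config(p, " must be a proportion in [0, 1]")
  }
  for (p in c("n_samples_per_sex", "n_probes", "n_genes", "n_plates")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      .stop_config(p, " must be a positive count")
  }
  if (cfg$n_interaction_genes < 0) .stop_config("n_interaction_genes must be >= 0")
  if (cfg$plate_sd < 0 || cfg$residual_sd < 0)
    .stop_config("plate_sd and residual_sd must be >= 0")
  if (length(cfg$cpgs_per_gene) != 2L || any(cfg$cpgs_per_gene < 1) ||
      cfg$cpgs_per_gene[1] > cfg$cpgs_per_gene[2])
    .stop_config("cpgs_per_gene must be c(min, max) with 1 <= min <= max")
  bm <- cfg$baseline_mix
  if (length(bm) != 3L || any(bm[1:2] <= 0) || any(bm[1:2] >= 1))
    .stop_config("baseline_mix modes must lie strictly inside (0, 1)")
  if (bm[3] < 0 || bm[3] > 1)
    .stop_config("baseline_mix weight must lie in [0, 1]")
  if (abs(sum(cfg$subtype_probs) - 1) > 1e-8 || any(cfg$subtype_probs < 0))
    .stop_config("subtype_probs must be nonnegative and sum to 1")
  invisible(cfg)
}

#' Generate a synthetic newborn cohort sample sheet
#'
#' Draws a two-sex cohort with per-newborn covariates: conception mode
#' (natural or one of four ART subtypes plus "unknown procedure"), maternal
#' age, smoking, BMI, parity, plate assignment, and optional covariates
#' (gestational age, birthweight, parental age/education). With
#' `confounding > 0`, ART mothers are older and more often nulliparous,
#' mirroring the covariate imbalance typical of ART cohorts.
#'
#' @param config An [effect_config()].
#' @return A `data.frame` sample table (see [read_sample_table()] for the
#'   column contract), one row per newborn, with unique `sample_id`.
#' @export
generate_cohort <- function(config) {
  validate_effect_config(config)
  set.seed(config$seed)
  n_per <- config$n_samples_per_sex
  n <- 2L * n_per
  conf <- config$confounding

  sex <- rep(c("F", "M"), each = n_per)
  art <- rbinom(n, 1L, config$art_fraction)

  conception <- ifelse(art == 1L,
                       sample(names(config$subtype_probs), n, replace = TRUE,
                              prob = config$subtype_probs),
                       "natural")

  # ART mothers: +3.2 years mean age, tighter SD; 70% vs 47% nulliparous
  maternal_age <- rnorm(n, mean = 30 + 3.2 * conf * art,
                        sd = 4.6 - 1.0 * conf * art)
  p_nulli <- 0.47 + 0.23 * conf * art
  parity <- ifelse(runif(n) < p_nulli, "nulliparous", "multiparous")
  maternal_bmi <- rnorm(n, 24.1, 4.0)
  maternal_smoking <- sample(c("never", "former", "quit_before_18w",
                               "continued_after_18w"),
                             n, replace = TRUE, prob = c(0.50, 0.31, 0.10, 0.09))

  plate_id <- sprintf("P%02d", rep_len(sample(config$n_plates), n)[sample(n)])

  gestational_age <- rnorm(n, 39.5, 1.6)
  bw_base <- ifelse(sex == "M", 3730, 3570)
  birthweight <- rnorm(n, bw_base - 120 * conf * art, 520)
  paternal_age <- maternal_age + 2.7 + rnorm(n, 0, 3)
  maternal_education <- sample(c("less_than_high_school", "high_school",
                                 "college_le4", "college_gt4"),
                               n, replace = TRUE, prob = c(0.06, 0.28, 0.41, 0.25))

  miss <- function(x) {
    x[runif(n) < config$covariate_missing_rate] <- NA
    x
  }

  out <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                    sex = sex,
                    conception = conception,
                    maternal_age = maternal_age,
                    maternal_smoking = maternal_smoking,
                    maternal_bmi = miss(maternal_bmi),
                    parity = parity,
                    plate_id = plate_id,
                    gestational_age = miss(gestational_age),
                    birthweight = birthweight,
                    maternal_education = maternal_education,
                    paternal_age = paternal_age,
                    stringsAsFactors = FALSE)
  validate_sample_table(out)
  out
}

#' Generate a synthetic probe annotation
#'
#' Lays out `n_genes` genes, each a contiguous run of CpGs on one autosome,
#' plus intergenic probes without a gene label. Positions are strictly
#' increasing within each chromosome (1-based, manifest style). The fraction
#' of genes with more than 20 CpGs is configurable so the gene-level
#' interaction scan has eligible genes.
#'
#' @param config An [effect_config()].
#' @return A `data.frame` with columns `probe_id`, `chr` (integer 1-22),
#'   `pos`, `gene` (`""` for intergenic probes).
#' @export
generate_probe_annotation <- function(config) {
  validate_effect_config(config)
  set.seed(config$seed + 1L)
  lo <- config$cpgs_per_gene[1]; hi <- config$cpgs_per_gene[2]
  ng <- config$n_genes
  # sample() treats a length-1 x as 1:x; draw by index instead
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

  if (lo > 20L || hi <= 20L) {
    sizes <- resample(seq(lo, hi), ng)
  } else {
    n_elig <- round(config$frac_genes_eligible * ng)
    sizes <- c(resample(seq(21L, hi), n_elig),
               resample(seq(lo, 20L), ng - n_elig))
    sizes <- sizes[sample(ng)]
  }
  if (sum(sizes) > config$n_probes)
    .stop_config("n_probes (", config$n_probes,
                 ") too small for the gene layout (needs >= ", sum(sizes), ")")
  n_nogene <- config$n_probes - sum(sizes)

  gene_names <- sprintf("GENE%03d", seq_len(ng))
  gene_chr <- sample(1:22, ng, replace = TRUE)
  chr <- c(rep(gene_chr, sizes), sample(1:22, n_nogene, replace = TRUE))
  gene <- c(rep(gene_names, sizes), rep("", n_nogene))

  ann <- data.frame(probe_id = sprintf("cg%08d", seq_len(config$n_probes)),
                    chr = chr, pos = NA_integer_, gene = gene,
                    stringsAsFactors = FALSE)
  # strictly increasing positions per chromosome; gene runs stay contiguous
  for (c_ in sort(unique(ann$chr))) {
    idx <- which(ann$chr == c_)
    ann$pos[idx] <- cumsum(sample(500:5000, length(idx), replace = TRUE))
  }
  ann <- ann[order(ann$chr, ann$pos), , drop = FALSE]
  rownames(ann) <- NULL
  validate_probe_annotation(ann)
  ann
}

#' Generate a synthetic beta-value matrix with known ground truth
#'
#' For probe j and sample i the generative model on the logit scale is
#' `logit(beta_ij) = logit(baseline_j) + delta_sex(j) * ART_i +
#' covariate effects + plate intercept + residual`, mapped through the
#' inverse logit so every value lies strictly in (0, 1). Baselines come from
#' a two-component (bimodal) mixture. The returned truth table records the
#' injected logit-scale ART effects per probe and sex.
#'
#' @param samples Sample table from [generate_cohort()].
#' @param annotation Probe annotation from [generate_probe_annotation()].
#' @param config The same [effect_config()].
#' @return A list with `beta` (numeric matrix, probes x samples, dimnames set)
#'   and `truth` (`data.frame`: `probe_id`, `delta_girls`, `delta_boys`,
#'   `is_interaction`, `gene`).
#' @export
generate_beta_matrix <- function(samples, annotation, config) {
  validate_effect_config(config)
  if (nrow(samples) == 0L || nrow(annotation) == 0L)
    .stop_data("samples and annotation must be nonempty")
  set.seed(config$seed + 2L)
  n_p <- nrow(annotation)
  n_s <- nrow(samples)

  bm <- config$baseline_mix
  low <- runif(n_p) < bm[3]
  baseline_logit <- .logit(ifelse(low, bm[1], bm[2])) +
    rnorm(n_p, 0, config$baseline_jitter_sd)

  dg <- rep(0, n_p)
  db <- rep(0, n_p)
  if (config$frac_art_affected_girls > 0)
    dg[sample(n_p, round(config$frac_art_affected_girls * n_p))] <- config$delta_girls
  if (config$frac_art_affected_boys > 0)
    db[sample(n_p, round(config$frac_art_affected_boys * n_p))] <- config$delta_boys
  if (config$frac_interaction > 0) {
    idx <- sample(n_p, round(config$frac_interaction * n_p))
    db[idx] <- dg[idx] + config$delta_interaction
  }
  if (config$n_interaction_genes > 0L) {
    counts <- table(annotation$gene[annotation$gene != ""])
    elig <- names(counts)[order(-counts)]
    if (length(elig) < config$n_interaction_genes)
      .stop_config("fewer genes than n_interaction_genes")
    for (g in elig[seq_len(config$n_interaction_genes)]) {
      idx <- which(annotation$gene == g)
      db[idx] <- dg[idx] + config$delta_interaction
    }
  }

  art <- as.numeric(samples$conception != "natural")
  is_f <- samples$sex == "F"
  # per-sample fixed covariate contribution (missing covariates contribute 0)
  ce <- config$covariate_effects
  smoke_lvl <- match(samples$maternal_smoking,
                     c("never", "former", "quit_before_18w",
                       "continued_after_18w")) - 1L
  covar <- ce[["maternal_age"]] * (samples$maternal_age - mean(samples$maternal_age)) +
    ce[["maternal_bmi"]] * ifelse(is.na(samples$maternal_bmi), 0,
                                  samples$maternal_bmi - mean(samples$maternal_bmi,
                                                              na.rm = TRUE)) +
    ce[["smoking"]] * ifelse(is.na(smoke_lvl), 0, smoke_lvl) +
    ce[["parity"]] * (samples$parity == "multiparous")

  plates <- unique(samples$plate_id)
  u <- setNames(rnorm(length(plates), 0, config$plate_sd), plates)

  eta <- matrix(baseline_logit, n_p, n_s) +
    dg %o% (art * is_f) + db %o% (art * !is_f) +
    matrix(covar + u[samples$plate_id], n_p, n_s, byrow = TRUE) +
    matrix(rnorm(n_p * n_s, 0, config$residual_sd), n_p, n_s)

  beta <- .invlogit(eta)
  dimnames(beta) <- list(annotation$probe_id, samples$sample_id)

  truth <- data.frame(probe_id = annotation$probe_id,
                      delta_girls = dg, delta_boys = db,
                      is_interaction = dg != db,
                      gene = annotation$gene,
                      stringsAsFactors = FALSE)
  list(beta = beta, truth = truth)
}
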