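## Orchestration: config handling, one-command synthetic dataset simulation,
## the full analysis pipeline, and a results digest.

.RUN_DEFAULTS <- list(
  sample_sheet = NULL, beta_matrix = NULL, annotation = NULL,
  exclusion_lists = character(0), candidate_sets = list(),
  output_dir = "artewas_out",
  contrasts = "ART_vs_natural", fdr_cpg = 0.01, fdr_gene = 0.05,
  mad_k = 5, min_cpgs = 21L, permutations = 999L, seed = 1L,
  perm_scheme = "label", stack_model = "cpg_intercepts",
  extra_covariates = character(0), min_subtype_n = 30L,
  transform = "beta", wald_ref = "normal", run_interaction = TRUE)

#' Build a pipeline run configuration
#'
#' Merges a YAML config file (optional) and in-call overrides over the
#' package defaults. Unknown keys are rejected by name. Thresholds
#' (`fdr_cpg`, `fdr_gene`) must lie in (0, 1).
#'
#' @param path Optional YAML file.
#' @param ... Named overrides of config keys.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- .RUN_DEFAULTS
  apply_keys <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(.RUN_DEFAULTS))
    if (length(unknown))
      .stop_config("unknown config key(s) in ", origin, ": ",
                   paste(unknown, collapse = ", "))
    cfg[names(vals)] <- vals
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) .stop_config("config file not found: ", path)
    cfg <- apply_keys(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_keys(cfg, list(...), "call")
  for (k in c("fdr_cpg", "fdr_gene")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1)
      .stop_config(k, " must lie in (0, 1)")
  }
  if (cfg$permutations < 99L) .stop_config("permutations must be >= 99")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a full synthetic dataset to files
#'
#' Writes the four pipeline inputs produced by the synthetic generator:
#' `samples.tsv`, `beta_matrix.tsv`, `annotation.csv` and `truth.tsv`
#' (the injected ground-truth effects). Byte-identical for identical seeds.
#'
#' @param config An [effect_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
simulate_dataset <- function(config = effect_config(), dir = "artewas_sim") {
  validate_effect_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) .stop_data("cannot create output directory: ", dir)
  samples <- generate_cohort(config)
  ann <- generate_probe_annotation(config)
  gen <- generate_beta_matrix(samples, ann, config)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             beta = file.path(dir, "beta_matrix.tsv"),
             annotation = file.path(dir, "annotation.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_sample_table(samples, paths["samples"])
  write_beta_matrix(gen$beta, paths["beta"])
  write_probe_annotation(ann, paths["annotation"])
  write.table(gen$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("simulated dataset (seed ", config$seed, ") written to ", dir)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Stage order: input validation and probe filtering, cohort characteristics
#' tests, sex-stratified per-CpG mixed-model EWAS for every configured
#' contrast with BH-FDR, the gene-level ART x sex interaction scan (sign
#' counts, chi-square, stacked estimate, block-wise permutation), and the
#' between-sex KS comparison of methylation difference distributions plus
#' any candidate-set enrichments. Every table is written as TSV with a
#' provenance header into `output_dir`. No stage mutates its inputs.
#'
#' @param config A [run_config()] with input paths set.
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (k in c("sample_sheet", "beta_matrix", "annotation")) {
    if (is.null(config[[k]])) .stop_config("config key '", k, "' not set")
    if (!file.exists(config[[k]]))
      .stop_data("input file for '", k, "' not found: ", config[[k]],
                 " (pre-flight check)")
  }
  for (f in unlist(config$exclusion_lists))
    if (!file.exists(f)) .stop_data("exclusion list not found: ", f)
  for (f in unlist(config$candidate_sets))
    if (!file.exists(f)) .stop_data("candidate set not found: ", f)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  covariates <- c(.DEFAULT_COVARIATES, config$extra_covariates)

  samples <- read_sample_table(config$sample_sheet)
  beta <- read_beta_matrix(config$beta_matrix)
  ann <- read_probe_annotation(config$annotation)
  excl <- lapply(config$exclusion_lists, read_probe_list)
  if (is.null(names(excl)) && length(excl))
    names(excl) <- basename(unlist(config$exclusion_lists))
  filt <- apply_probe_filters(beta, exclusion_sets = excl, annotation = ann)
  beta <- filt$matrix
  if (nrow(beta) == 0L) .stop_data("no probes remain after filtering")
  if (nrow(filt$report)) write_result_table(filt$report, out("probe_filters.tsv"),
                                            seed = config$seed)

  results <- list(filter_report = filt$report)
  results$cohort <- summarize_cohort(samples)
  write_result_table(results$cohort, out("cohort_characteristics.tsv"),
                     seed = config$seed)

  ewas_tables <- list()
  for (ct in config$contrasts) {
    groups <- contrast_groups(ct)
    sizes <- table(factor(samples$conception %in% groups$exposed,
                          levels = c(FALSE, TRUE)),
                   samples$conception %in% c(groups$exposed, groups$reference))
    n_exp <- sum(samples$conception %in% groups$exposed)
    n_ref <- sum(samples$conception %in% groups$reference)
    if (min(n_exp, n_ref) < config$min_subtype_n) {
      message("skipping contrast ", ct, ": group below min_subtype_n (",
              config$min_subtype_n, ")")
      next
    }
    tab <- run_stratified_ewas(beta, samples, ann, contrast = ct,
                               fdr = config$fdr_cpg, mad_k = config$mad_k,
                               covariates = covariates,
                               transform = config$transform,
                               wald_ref = config$wald_ref)
    write_result_table(tab, out(paste0("ewas_", ct, ".tsv")),
                       seed = config$seed)
    for (s in unique(tab$stratum)) {
      qq <- qq_coordinates(tab$p[tab$stratum == s])
      write_result_table(qq, out(paste0("qq_", ct, "_", s, ".tsv")),
                         seed = config$seed)
    }
    ewas_tables[[ct]] <- tab
  }
  results$ewas <- ewas_tables

  main <- ewas_tables[["ART_vs_natural"]]
  if (!is.null(main)) {
    girls <- main[main$stratum == "F", , drop = FALSE]
    boys <- main[main$stratum == "M", , drop = FALSE]
    results$overlap <- overlap_significant(girls, boys, fdr = config$fdr_cpg)
    write_result_table(results$overlap, out("overlap_significant.tsv"),
                       seed = config$seed)
    results$gene_hits <- list(F = gene_hit_summary(girls, ann, config$fdr_cpg),
                              M = gene_hit_summary(boys, ann, config$fdr_cpg))
    for (s in names(results$gene_hits)) {
      h <- results$gene_hits[[s]]$histogram
      if (nrow(h)) write_result_table(h, out(paste0("gene_hits_", s, ".tsv")),
                                      seed = config$seed)
    }
    if (isTRUE(config$run_interaction)) {
      results$interaction <- run_gene_interaction_scan(
        beta, samples, ann, girls, boys, B = config$permutations,
        min_cpgs = config$min_cpgs, fdr = config$fdr_gene,
        seed = config$seed, scheme = config$perm_scheme,
        stack_model = config$stack_model, covariates = covariates)
      if (length(results$interaction))
        write_result_table(results$interaction, out("gene_interaction.tsv"),
                           seed = config$seed)
    }

    diff_f <- mean_difference_vector(beta, samples, "F", mad_k = config$mad_k)
    diff_m <- mean_difference_vector(beta, samples, "M", mad_k = config$mad_k)
    results$ks <- ks_two_sample(diff_f, diff_m)
    write_result_table(data.frame(D = results$ks$D, p = results$ks$p,
                                  n_girls = results$ks$n1,
                                  n_boys = results$ks$n2),
                       out("ks_sex_difference.tsv"), seed = config$seed)
    write_result_table(data.frame(probe_id = names(diff_f), diff_girls = diff_f,
                                  diff_boys = diff_m[names(diff_f)]),
                       out("mean_differences.tsv"), seed = config$seed)

    if (length(config$candidate_sets)) {
      enr <- list()
      for (nm in names(config$candidate_sets)) {
        ids <- read_probe_list(config$candidate_sets[[nm]])
        for (s in c("F", "M")) {
          tab <- if (s == "F") girls else boys
          pv <- setNames(tab$p, tab$probe_id)
          ids_in <- intersect(ids, names(pv))
          e <- set_enrichment(pv, ids_in, name = paste0(nm, "_", s))
          enr[[e$name]] <- e
        }
      }
      results$enrichment <- enr
      write_result_table(
        data.frame(set = names(enr),
                   n_candidates = vapply(enr, `[[`, numeric(1), "n_candidates"),
                   p = vapply(enr, `[[`, numeric(1), "p"),
                   lambda = vapply(enr, `[[`, numeric(1), "lambda")),
        out("enrichment.tsv"), seed = config$seed)
    }
  }
  invisible(results)
}

#' Digest of a completed pipeline run
#'
#' Recounts the written result tables into a short results summary:
#' significant CpGs per stratum and contrast, the between-sex overlap,
#' eligible genes and top genes by empirical interaction p, and the KS
#' statistic. Errors listing missing tables when the run is incomplete.
#'
#' @param output_dir Directory written by [run_pipeline()].
#' @param fdr_cpg,fdr_gene Thresholds used for counting.
#' @return Character vector of digest lines (also printed).
#' @export
pipeline_report <- function(output_dir, fdr_cpg = 0.01, fdr_gene = 0.05) {
  ewas_files <- list.files(output_dir, pattern = "^ewas_.*\\.tsv$",
                           full.names = TRUE)
  need <- c("cohort_characteristics.tsv")
  missing_tabs <- need[!file.exists(file.path(output_dir, need))]
  if (length(missing_tabs) || !length(ewas_files))
    stop("incomplete run; missing table(s): ",
         paste(c(missing_tabs, if (!length(ewas_files)) "ewas_*.tsv"),
               collapse = ", "), call. = FALSE)
  lines <- character(0)
  say <- function(...) lines <<- c(lines, sprintf(...))
  for (f in ewas_files) {
    tab <- read.delim(f, comment.char = "#")
    ct <- sub("^ewas_(.*)\\.tsv$", "\\1", basename(f))
    for (s in unique(tab$stratum)) {
      n_sig <- sum(tab$q[tab$stratum == s] < fdr_cpg, na.rm = TRUE)
      say("%s [%s]: %d significant CpGs at q < %g (of %d tested)",
          ct, s, n_sig, fdr_cpg, sum(!is.na(tab$p[tab$stratum == s])))
    }
  }
  ov <- file.path(output_dir, "overlap_significant.tsv")
  if (file.exists(ov)) {
    o <- read.delim(ov, comment.char = "#")
    say("overlap between sexes: %d CpGs (%d direction-concordant)",
        nrow(o), sum(o$concordant))
  }
  gi <- file.path(output_dir, "gene_interaction.tsv")
  if (file.exists(gi)) {
    g <- read.delim(gi, comment.char = "#")
    say("gene interaction scan: %d eligible genes, %d at q < %g",
        nrow(g), sum(g$q < fdr_gene, na.rm = TRUE), fdr_gene)
    top <- g[order(g$empirical_p), , drop = FALSE][seq_len(min(5L, nrow(g))), ]
    say("top genes by empirical p: %s",
        paste(sprintf("%s (p=%.4g)", top$gene, top$empirical_p),
              collapse = ", "))
  }
  ks <- file.path(output_dir, "ks_sex_difference.tsv")
  if (file.exists(ks)) {
    k <- read.delim(ks, comment.char = "#")
    say("KS girls-vs-boys difference distributions: D = %.4g (p = %.3g)",
        k$D, k$p)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
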