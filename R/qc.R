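#' Observation-level outlier mask by the median +/- k * MAD rule
#'
#' For one CpG's beta values, computes the median and the *unscaled* median
#' absolute deviation (the median of absolute differences from the overall
#' median, with no 1.4826 consistency constant) and masks every value outside
#' `[median - k * MAD, median + k * MAD]`. When MAD is exactly 0 (near-constant
#' probe) nothing is masked: the literal rule would discard every value
#' unequal to the median, which is not a defensible outlier definition.
#' Missing values stay missing and are not counted as masked.
#'
#' @param values Numeric vector of beta values (may contain `NA`).
#' @param k Multiplier; the conventional cutoff is 5.
#' @return List with `mask` (logical, `TRUE` = masked outlier), `values` (the
#'   input with masked entries set `NA`), and `report` (one-row data.frame:
#'   `median`, `mad`, `lower`, `upper`, `n_masked`).
#' @export
mad_mask <- function(values, k = 5) {
  if (all(is.na(values))) .stop_data("mad_mask: all values missing")
  med <- median(values, na.rm = TRUE)
  mad0 <- median(abs(values - med), na.rm = TRUE)
  if (mad0 == 0) {
    mask <- rep(FALSE, length(values))
    lo <- med; hi <- med
  } else {
    lo <- med - k * mad0
    hi <- med + k * mad0
    mask <- !is.na(values) & (values < lo | values > hi)
  }
  out <- values
  out[mask] <- NA
  list(mask = mask, values = out,
       report = data.frame(median = med, mad = mad0, lower = lo, upper = hi,
                           n_masked = sum(mask)))
}

#' Remove excluded probes from a beta matrix
#'
#' Restricts the matrix to probes present in the annotation (when given) and
#' in none of the exclusion sets (e.g. cross-hybridizing probes, SNP-affected
#' probes). A probe in several sets is removed once and attributed to the
#' first set listing it. Unknown IDs in exclusion sets are ignored.
#'
#' @param matrix Beta matrix (probes x samples).
#' @param exclusion_sets Named (or unnamed) list of character vectors of probe
#'   IDs to drop.
#' @param annotation Optional annotation; probes absent from it are dropped.
#' @return List with `matrix` (filtered) and `report` (data.frame: `set`,
#'   `n_removed`).
#' @export
apply_probe_filters <- function(matrix, exclusion_sets = list(),
                                annotation = NULL) {
  probes <- rownames(matrix)
  removed_by <- rep(NA_character_, length(probes))
  if (!is.null(annotation)) {
    out <- !(probes %in% annotation$probe_id)
    removed_by[out] <- "not_in_annotation"
  }
  if (length(exclusion_sets)) {
    set_names <- names(exclusion_sets) %||% paste0("set", seq_along(exclusion_sets))
    if (is.null(names(exclusion_sets))) names(exclusion_sets) <- set_names
    for (i in seq_along(exclusion_sets)) {
      hit <- is.na(removed_by) & probes %in% exclusion_sets[[i]]
      removed_by[hit] <- set_names[i]
    }
  }
  keep <- is.na(removed_by)
  tab <- table(removed_by[!keep])
  report <- data.frame(set = names(tab), n_removed = as.integer(tab),
                       stringsAsFactors = FALSE)
  if (!any(keep)) warning("no probes remain after filtering")
  list(matrix = matrix[keep, , drop = FALSE], report = report)
}

#' Reconcile recorded sex with externally inferred sex
#'
#' Where an inferred sex (e.g. from sex-chromosome signal, supplied as a map)
#' disagrees with the recorded sex, the record is replaced by the inferred
#' value and the change logged. Samples absent from the map are untouched.
#'
#' @param samples Sample table.
#' @param inferred_sex Named character vector (`sample_id` -> `"F"`/`"M"`),
#'   possibly partial.
#' @return List with `samples` (updated) and `report` (data.frame:
#'   `sample_id`, `recorded`, `inferred`).
#' @export
reconcile_sex <- function(samples, inferred_sex) {
  if (length(inferred_sex)) {
    .check_levels(unname(inferred_sex), .SEX_LEVELS, "inferred sex")
    idx <- match(names(inferred_sex), samples$sample_id)
    known <- !is.na(idx)
    changed <- known & samples$sex[idx] != unname(inferred_sex)
  } else {
    idx <- integer(0)
    changed <- logical(0)
  }
  report <- data.frame(sample_id = names(inferred_sex)[changed],
                       recorded = samples$sex[idx[changed]],
                       inferred = unname(inferred_sex)[changed],
                       stringsAsFactors = FALSE)
  samples$sex[idx[changed]] <- unname(inferred_sex)[changed]
  list(samples = samples, report = report)
}
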