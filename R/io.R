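## Readers/writers for every table the pipeline touches. All readers validate
## strictly and reject malformed input; all writers emit files their paired
## reader accepts. Missing token is "NA"; coordinates 1-based (manifest style).

.SEX_LEVELS <- c("F", "M")
.CONCEPTION_LEVELS <- c("natural", "fresh_IVF", "fresh_ICSI",
                        "frozen_IVF", "frozen_ICSI", "ART_unknown")
.SMOKING_LEVELS <- c("never", "former", "quit_before_18w",
                     "continued_after_18w")
.PARITY_LEVELS <- c("nulliparous", "multiparous")
.MANDATORY_COLS <- c("sample_id", "sex", "conception", "maternal_age",
                     "maternal_smoking", "maternal_bmi", "parity", "plate_id")

.check_levels <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    .stop_data("unknown ", what, " value(s) in row(s) ",
               paste(head(which(bad), 10L), collapse = ", "), ": ",
               paste(unique(x[bad]), collapse = ", "))
}

#' Validate a sample table
#'
#' Checks the column contract (see [read_sample_table()]), uniqueness of
#' `sample_id`, and category labels for sex, conception mode, smoking and
#' parity.
#'
#' @param samples A data.frame.
#' @return `samples`, invisibly.
#' @export
validate_sample_table <- function(samples) {
  missing_cols <- setdiff(.MANDATORY_COLS, names(samples))
  if (length(missing_cols))
    .stop_data("sample table lacks mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    .stop_data("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  .check_levels(samples$sex, .SEX_LEVELS, "sex")
  .check_levels(samples$conception, .CONCEPTION_LEVELS, "conception")
  .check_levels(samples$maternal_smoking, .SMOKING_LEVELS, "maternal_smoking")
  .check_levels(samples$parity, .PARITY_LEVELS, "parity")
  for (col in c("maternal_age", "maternal_bmi")) {
    if (!is.numeric(samples[[col]]))
      .stop_data("column ", col, " must be numeric")
  }
  invisible(samples)
}

#' ART indicator for a sample table
#'
#' A newborn counts as ART-conceived iff its conception mode is anything other
#' than `natural` (all four fresh/frozen x IVF/ICSI subtypes and
#' `ART_unknown`).
#'
#' @param samples A validated sample table.
#' @return Logical vector, one element per row.
#' @export
is_art <- function(samples) samples$conception != "natural"

#' Read / write a sample sheet
#'
#' The sample sheet is delimited text with a header and one row per newborn.
#' Mandatory columns: `sample_id` (unique), `sex` (`F`/`M`), `conception`
#' (`natural`, `fresh_IVF`, `fresh_ICSI`, `frozen_IVF`, `frozen_ICSI`,
#' `ART_unknown`), `maternal_age` (years), `maternal_smoking` (`never`,
#' `former`, `quit_before_18w`, `continued_after_18w`), `maternal_bmi`
#' (kg/m^2), `parity` (`nulliparous`/`multiparous`), `plate_id`. Optional
#' columns (e.g. `gestational_age`, `birthweight`, `maternal_education`,
#' `paternal_age`, `paternal_bmi`) pass through typed. Missing values are
#' written/read as `NA`.
#'
#' @param path File path.
#' @param dialect `"tab"` or `"comma"`.
#' @return `read_sample_table`: a validated data.frame.
#' @export
read_sample_table <- function(path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stop_data("file not found: ", path)
  df <- if (dialect == "tab")
    read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
               na.strings = "NA")
  else
    read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
             na.strings = "NA")
  validate_sample_table(df)
  df
}

#' @rdname read_sample_table
#' @param samples A validated sample table.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a beta-value matrix
#'
#' Tab-separated: first column `probe_id`, remaining columns one per sample
#' with sample IDs in the header. Values must lie in `[0, 1]` or be the
#' missing token `NA`; anything else is rejected with the offending
#' probe/sample coordinates. `.gz` paths are handled transparently.
#'
#' @param path File path (optionally gzip-compressed).
#' @return `read_beta_matrix`: numeric matrix, probes x samples, with
#'   dimnames.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) .stop_data("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#", na.strings = "NA")
  if (nrow(df) == 0L || ncol(df) < 2L)
    .stop_data("no probes in beta matrix file: ", path)
  probe_ids <- as.character(df[[1]])
  if (anyDuplicated(probe_ids))
    .stop_data("duplicated probe_id in beta matrix: ",
               probe_ids[duplicated(probe_ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) .stop_data("non-numeric cell(s) in beta matrix")
  if (anyDuplicated(colnames(m)))
    .stop_data("duplicated sample IDs in beta matrix header")
  rownames(m) <- probe_ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    .stop_data("beta value outside [0, 1] at probe ",
               probe_ids[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]],
               " (", m[bad[1, , drop = FALSE]], ")")
  m
}

#' @rdname read_beta_matrix
#' @param matrix Numeric matrix, probes x samples, dimnames set, values in
#'   `[0, 1]` or `NA`.
#' @export
write_beta_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  if (any(!is.na(matrix) & (matrix < 0 | matrix > 1)))
    .stop_data("beta values outside [0, 1]")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(matrix)), collapse = "\t"), con)
  body <- cbind(rownames(matrix),
                format(matrix, digits = 10, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Validate a probe annotation
#'
#' @param ann A data.frame with columns `probe_id`, `chr`, `pos`, `gene`.
#' @return `ann`, invisibly.
#' @export
validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "chr", "pos", "gene")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    .stop_data("annotation lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ann$probe_id))
    .stop_data("duplicated probe_id in annotation")
  chr <- suppressWarnings(as.integer(ann$chr))
  bad <- is.na(chr) | chr < 1L | chr > 22L
  if (any(bad))
    .stop_data("non-autosomal or unparseable chromosome in annotation (",
               paste(unique(ann$chr[bad]), collapse = ", "),
               "); only autosomes 1-22 are modelled")
  if (any(ann$pos < 1L)) .stop_data("annotation positions must be >= 1")
  invisible(ann)
}

#' Read / write probe annotation
#'
#' CSV with header `probe_id,chr,pos,gene`. Chromosomes must be autosomes
#' 1-22 (this pipeline models autosomal CpGs only); positions are 1-based
#' (hg19-style manifest convention). A probe annotated to several genes lists
#' them separated by `";"` (e.g. `NECAB3;ACTL10`); use
#' [annotation_gene_map()] to expand to one row per (probe, gene).
#'
#' @param path File path.
#' @return `read_probe_annotation`: data.frame `probe_id`, `chr` (integer),
#'   `pos` (integer), `gene` (character, possibly `";"`-separated, `""` for
#'   none).
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) .stop_data("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 colClasses = c(probe_id = "character", gene = "character"))
  validate_probe_annotation(df)
  df$chr <- as.integer(df$chr)
  df$pos <- as.integer(df$pos)
  df$gene[is.na(df$gene)] <- ""
  df
}

#' @rdname read_probe_annotation
#' @param ann A validated annotation data.frame.
#' @export
write_probe_annotation <- function(ann, path) {
  validate_probe_annotation(ann)
  write.table(ann[, c("probe_id", "chr", "pos", "gene")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand an annotation to one row per (probe, gene)
#'
#' Splits `";"`-separated gene labels; a probe annotated to several genes
#' contributes one row per gene (and is flagged), so it is counted once in
#' each gene in gene-level analyses. Probes without a gene are dropped.
#'
#' @param ann Annotation data.frame.
#' @return data.frame with columns `probe_id`, `chr`, `pos`, `gene`,
#'   `multi_gene` (logical).
#' @export
annotation_gene_map <- function(ann) {
  keep <- !is.na(ann$gene) & ann$gene != ""
  ann <- ann[keep, , drop = FALSE]
  genes <- strsplit(ann$gene, ";", fixed = TRUE)
  nrep <- lengths(genes)
  out <- data.frame(probe_id = rep(ann$probe_id, nrep),
                    chr = rep(ann$chr, nrep),
                    pos = rep(ann$pos, nrep),
                    gene = trimws(unlist(genes)),
                    multi_gene = rep(nrep > 1L, nrep),
                    stringsAsFactors = FALSE)
  out[out$gene != "", , drop = FALSE]
}

#' Read a probe list
#'
#' Plain text, one probe ID per line; blank lines and `#` comments ignored;
#' duplicates collapse to a single membership.
#'
#' @param path File path.
#' @return Character vector of unique probe IDs.
#' @export
read_probe_list <- function(path) {
  if (!file.exists(path)) .stop_data("file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[x != "" & !startsWith(x, "#")]
  unique(x)
}

#' Write a results table as TSV with a provenance header
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param seed Seed recorded in the header (optional).
#' @export
write_result_table <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# artewas %s%s", as.character(packageVersion("artewas")),
                 if (is.null(seed)) "" else sprintf("; seed=%d", as.integer(seed)))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
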