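#' Construct an expression cohort
#'
#' Couples a log2-scale gene-by-sample expression matrix (as produced by
#' upstream RMA / quantile normalization; missing entries allowed) with
#' per-sample metadata. Every sample must belong to a study stratum
#' (`study_id`); downstream z-standardization is performed within study.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param metadata data.frame with one row per sample; must contain
#'   `sample_id` matching the matrix columns and `study_id`. Optional
#'   columns: `group`, `age`, `age_decade`, `stage`, `tissue`, and any
#'   others, carried through scoring.
#' @return An object of class `"expression_cohort"` with elements `values`
#'   and `metadata` (reordered to the matrix column order).
#' @export
expression_cohort <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!is.data.frame(metadata) || !all(c("sample_id", "study_id") %in%
                                       names(metadata)))
    stop("metadata must be a data.frame with columns sample_id and study_id")
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  if (!setequal(metadata$sample_id, colnames(values)))
    stop("metadata sample_id and matrix colnames do not match 1:1")
  if (any(is.na(metadata$study_id)) || any(!nzchar(metadata$study_id)))
    stop("every sample needs a nonmissing study_id")
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata,
                 zscaled = FALSE),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> %d genes x %d samples, %d studies%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$metadata$study_id)),
              if (isTRUE(x$zscaled)) " (z-scale)" else ""))
  if ("group" %in% names(x$metadata)) {
    tb <- table(x$metadata$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Dialect: header row of sample ids, first column gene ids, tab separated;
#' lines starting with `#` are treated as comments. `NA` marks missing
#' values.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop(.input_error(paste0("no such file: ", path)))
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read per-sample metadata from TSV
#'
#' Requires columns `sample_id` and `study_id`; all other columns are
#' passed through.
#'
#' @param path Path to the TSV file.
#' @return data.frame of metadata.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop(.input_error(paste0("no such file: ", path)))
  md <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "study_id") %in% names(md)))
    stop(.input_error(
      "metadata TSV must contain columns 'sample_id' and 'study_id'"))
  md
}

#' Write a cohort as the expression + metadata TSV pair
#'
#' @param cohort An `"expression_cohort"`.
#' @param expression_path,metadata_path Output paths.
#' @param header Optional character vector of `#`-prefixed provenance lines
#'   written atop each file.
#' @return Invisibly, the two paths.
#' @export
write_cohort_tsv <- function(cohort, expression_path, metadata_path,
                             header = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  df <- data.frame(gene_id = rownames(cohort$values),
                   cohort$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, expression_path, header)
  .write_tsv(cohort$metadata, metadata_path, header)
  invisible(c(expression_path, metadata_path))
}

.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
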