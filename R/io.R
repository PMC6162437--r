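# Plain-text readers and writers for the tabular formats the package consumes:
# expression matrices, sample label tables, and taxon count tables are all
# tab-separated UTF-8 text so that cohorts round-trip through version control.

#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected layout is the one written by [write_expression_tsv()]: a
#' header row of sample ids, a first column of gene ids, and numeric values
#' (interpreted as `log2(FPKM + 1)` throughout the package). Missing values
#' are rejected outright rather than imputed, because downstream scoring is
#' rank-based and silent imputation would corrupt within-sample ranks.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' write_expression_tsv(m, f)
#' read_expression_tsv(f)
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >= 1 sample column",
                          call. = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(m) <- genes
  check_expression_matrix(m, "expression TSV")
  m
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param gene_column Name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path, gene_column = "gene") {
  check_expression_matrix(matrix)
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label table
#'
#' @param path TSV with a header and two columns: sample id, label.
#' @return A data frame with columns `sample` and `label`.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label TSV needs two columns: sample, label", call. = FALSE)
  out <- data.frame(sample = as.character(df[[1L]]), label = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample)) stop("duplicated sample ids in ", path, call. = FALSE)
  out
}

#' Write a two-column sample label table
#'
#' @param labels Data frame whose first two columns are sample id and label.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels[, 1:2], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
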