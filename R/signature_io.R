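# Gene-set signatures: GMT parsing, validation against a matrix, round-trip.

#' Construct a signature collection
#'
#' A signature collection is a named list of gene sets -- the CRC, stromal,
#' EMT and developmental signatures the subtyping workflow scores -- with an
#' optional category tag per set. Gene identifiers are matched elsewhere by
#' exact string equality after uppercasing; no alias resolution is attempted.
#'
#' @param sets Named list; each element a character vector of gene ids.
#' @param descriptions Optional named character vector of set descriptions.
#' @param categories Optional named character vector of category tags
#'   (e.g. "canonical CRC", "stromal", "immune").
#' @return An object of class `signature_collection`.
#' @export
signature_collection <- function(sets, descriptions = NULL, categories = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list of gene id vectors", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- toupper(as.character(g))
    g <- g[!duplicated(g)]
    if (any(g == "")) stop("empty gene identifier in a set", call. = FALSE)
    g
  })
  bad <- names(sets)[vapply(sets, length, 1L) < 2L]
  if (length(bad))
    stop("sets with < 2 genes after deduplication: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(sets = sets,
                 descriptions = descriptions %||% setNames(rep("", length(sets)), names(sets)),
                 categories = categories),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("signature_collection: %d sets, %d genes total\n",
              length(x$sets), sum(vapply(x$sets, length, 1L))))
  invisible(x)
}

#' @export
length.signature_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Parses the Broad GMT dialect: one set per line,
#' `NAME <TAB> DESCRIPTION <TAB> gene1 <TAB> gene2 ...`. Genes are uppercased
#' and deduplicated preserving first occurrence; a repeated gene inside one
#' line triggers a warning naming the set. Lines with fewer than three fields,
#' duplicate set names, and empty files are errors.
#'
#' @param path Path to a GMT file.
#' @return A [signature_collection()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("WNT_TARGETS\tdesc\tMYC\tAXIN2", f)
#' read_gmt(f)
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    nm <- f[[1L]]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", nm, i), call. = FALSE)
    genes <- toupper(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning(sprintf("set '%s': %d duplicate gene(s) removed", nm,
                      sum(duplicated(genes))), call. = FALSE)
    sets[[nm]] <- genes[!duplicated(genes)]
    desc[nm] <- f[[2L]]
  }
  signature_collection(sets, descriptions = desc)
}

#' Write a signature collection to a GMT file
#'
#' @param collection A [signature_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "signature_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Report signature coverage in an expression matrix
#'
#' For each set, counts how many member genes are present among the matrix
#' rownames (exact match after uppercasing). Sets with fewer than two present
#' genes are flagged unusable: an enrichment running sum over a single hit is
#' degenerate.
#'
#' @param collection A [signature_collection()].
#' @param matrix Expression matrix (genes x samples).
#' @return Data frame with one row per set: `set`, `n_genes`, `n_present`,
#'   `coverage`, `usable`.
#' @export
validate_against_matrix <- function(collection, matrix) {
  stopifnot(inherits(collection, "signature_collection"))
  check_expression_matrix(matrix)
  universe <- toupper(rownames(matrix))
  n_present <- vapply(collection$sets, function(g) sum(g %in% universe), 1L)
  n_genes <- vapply(collection$sets, length, 1L)
  data.frame(set = names(collection$sets),
             n_genes = n_genes,
             n_present = n_present,
             coverage = n_present / n_genes,
             usable = n_present >= 2L,
             row.names = NULL, stringsAsFactors = FALSE)
}
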