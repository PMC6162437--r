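# Microbial read-count profiling: taxonomy aggregation, relative abundance,
# per-taxon enrichment against the cohort baseline, and community diversity.
#
# The input contract is a taxon x sample table of reads already mapped to a
# microbial database (host-depleted shotgun data); read mapping itself is out
# of scope. Diversity is computed at the level the counts are given
# (typically species).

#' Construct a taxon count table
#'
#' @param counts Non-negative integer matrix, taxa x samples, with taxon
#'   rownames and sample colnames.
#' @param lineage Data frame with columns `taxon`, `phylum`, `family`,
#'   `species`, one row per count row (matched by `taxon`).
#' @param database Optional tag of the mapping database (e.g. "HMP", "ABG").
#' @return An object of class `taxon_count_table`.
#' @export
taxon_count_table <- function(counts, lineage, database = "other") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (taxa x samples)", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs taxon rownames and sample colnames", call. = FALSE)
  need <- c("taxon", "phylum", "family", "species")
  if (!all(need %in% names(lineage)))
    stop("`lineage` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!setequal(lineage$taxon, rownames(counts)) ||
      anyDuplicated(lineage$taxon))
    stop("`lineage$taxon` must match the count rownames exactly", call. = FALSE)
  lineage <- lineage[match(rownames(counts), lineage$taxon), , drop = FALSE]
  rownames(lineage) <- NULL
  structure(list(counts = counts, lineage = lineage, database = database),
            class = "taxon_count_table")
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat(sprintf("taxon_count_table: %d taxa x %d samples (db: %s)\n",
              nrow(x$counts), ncol(x$counts), x$database))
  invisible(x)
}

#' Read a taxon count table from TSV
#'
#' Expected columns: `taxon`, `phylum`, `family`, `species`, then one numeric
#' column per sample -- the format written by [write_taxon_tsv()].
#'
#' @param path Path to the TSV.
#' @param database Database tag to attach.
#' @return A [taxon_count_table()].
#' @export
read_taxon_tsv <- function(path, database = "other") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon", "phylum", "family", "species")
  if (!all(need %in% names(df)))
    stop("taxon TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  cnt <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(cnt) <- df$taxon
  taxon_count_table(cnt, df[, need], database = database)
}

#' Write a taxon count table to TSV
#'
#' @param table A [taxon_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_tsv <- function(table, path) {
  stopifnot(inherits(table, "taxon_count_table"))
  df <- cbind(table$lineage, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate a taxon count table to a taxonomy level
#'
#' Sums counts within each distinct value of the requested lineage level.
#' Per-sample totals are conserved exactly.
#'
#' @param table A [taxon_count_table()].
#' @param level One of "phylum", "family", "species".
#' @return A [taxon_count_table()] whose rows are the distinct lineage values
#'   at `level` (lineage columns below that level carry the aggregate name).
#' @export
aggregate_taxonomy <- function(table, level = c("species", "family", "phylum")) {
  stopifnot(inherits(table, "taxon_count_table"))
  level <- match.arg(level)
  key <- table$lineage[[level]]
  if (any(is.na(key) | key == ""))
    stop("lineage not populated at level '", level, "'", call. = FALSE)
  agg <- rowsum(table$counts, group = key)
  keys <- rownames(agg)
  first <- match(keys, key)
  lin <- data.frame(taxon = keys,
                    phylum = table$lineage$phylum[first],
                    family = if (level == "phylum") keys else table$lineage$family[first],
                    species = if (level == "species") table$lineage$species[first] else keys,
                    stringsAsFactors = FALSE)
  if (level == "phylum") lin$family <- lin$taxon
  if (level != "species") lin$species <- lin$taxon
  taxon_count_table(agg, lin, database = table$database)
}

#' Per-sample relative abundances
#'
#' @param table A [taxon_count_table()].
#' @return List: `proportions` (taxa x samples; columns of empty samples are
#'   `NA`), `empty_samples` (character vector of samples with zero total).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  N <- colSums(table$counts)
  empty <- colnames(table$counts)[N == 0]
  if (length(empty))
    warning("sample(s) with zero total reads: ", paste(empty, collapse = ", "),
            call. = FALSE)
  p <- sweep(table$counts, 2L, ifelse(N > 0, N, NA_real_), "/")
  list(proportions = p, empty_samples = empty)
}

#' Per-taxon enrichment against the cohort baseline
#'
#' Scales each sample to reads-per-million and reports, per (taxon, sample),
#' `log2((rpm + pseudocount) / (cohort median rpm of that taxon + pseudocount))`
#' -- the red/green enrichment scale of a cohort heatmap. The cohort median
#' is the default baseline; pass `baseline = "mean"` to compare against the
#' cohort mean instead.
#'
#' @param table A [taxon_count_table()] with >= 2 samples.
#' @param pseudocount Added to both numerator and denominator.
#' @param baseline "median" (default) or "mean".
#' @return Numeric matrix, taxa x samples, of log2 fold-changes.
#' @export
enrichment_log2fc <- function(table, pseudocount = 0.5,
                              baseline = c("median", "mean")) {
  stopifnot(inherits(table, "taxon_count_table"))
  baseline <- match.arg(baseline)
  if (ncol(table$counts) < 2L)
    stop("cohort enrichment needs >= 2 samples", call. = FALSE)
  check_scalar_number(pseudocount, "pseudocount", min = 0)
  N <- colSums(table$counts)
  rpm <- sweep(table$counts, 2L, ifelse(N > 0, N, NA_real_), "/") * 1e6
  ref <- apply(rpm, 1L, if (baseline == "median") median else mean, na.rm = TRUE)
  log2((rpm + pseudocount) / (ref + pseudocount))
}

#' Simpson's diversity of one sample
#'
#' The unbiased pairwise-draw form
#' `D = 1 - sum(n_i * (n_i - 1)) / (N * (N - 1))`: the probability that two
#' reads drawn without replacement map to different species. A monoculture
#' gives 0; `(1, 1)` gives 1. Note this is not the plug-in `1 - sum(p_i^2)`.
#'
#' @param counts Non-negative integer vector of per-taxon read counts with
#'   total `N >= 2`.
#' @return Simpson's D in `[0, 1]`.
#' @export
#' @examples
#' simpson_diversity(c(5, 5))  # 1 - 40/90
simpson_diversity <- function(counts) {
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  N <- sum(counts)
  if (N < 2) stop("Simpson's diversity needs N >= 2 reads", call. = FALSE)
  1 - sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Shannon-Wiener diversity of one sample
#'
#' `D = -sum(p_i * ln(p_i))` with `p_i = n_i / N`, natural log; zero-count
#' taxa contribute 0 (the `0 * ln 0 -> 0` convention).
#'
#' @param counts Non-negative integer vector of per-taxon read counts with
#'   total `N >= 1`.
#' @return Shannon's D in `[0, ln(observed taxa)]`.
#' @export
#' @examples
#' shannon_diversity(c(5, 5))  # ln 2
shannon_diversity <- function(counts) {
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  N <- sum(counts)
  if (N < 1) stop("Shannon diversity needs N >= 1 reads", call. = FALSE)
  p <- counts[counts > 0] / N
  -sum(p * log(p))
}

#' Per-sample diversity table
#'
#' @param table A [taxon_count_table()].
#' @return Data frame: `sample`, `simpson`, `shannon`, `N`, `taxa_observed`.
#'   Samples with too few reads for an index get `NA` there.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  out <- data.frame(sample = colnames(table$counts),
                    simpson = NA_real_, shannon = NA_real_,
                    N = colSums(table$counts),
                    taxa_observed = colSums(table$counts > 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_len(nrow(out))) {
    x <- table$counts[, j]
    if (out$N[j] >= 2) out$simpson[j] <- simpson_diversity(x)
    if (out$N[j] >= 1) out$shannon[j] <- shannon_diversity(x)
  }
  out
}

#' Compare diversity between sample groups
#'
#' Per-group median and IQR of each diversity index, plus a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) p-value for every group pair.
#'
#' @param diversity A data frame from [diversity_table()].
#' @param groups Data frame with columns `sample` and `label`.
#' @return List: `summary` (group x index medians/IQRs), `tests` (data frame
#'   `index`, `group1`, `group2`, `p_value`).
#' @export
compare_groups <- function(diversity, groups) {
  g <- setNames(groups$label, groups$sample)[diversity$sample]
  if (anyNA(g)) stop("samples missing a group label: ",
                     paste(diversity$sample[is.na(g)], collapse = ", "),
                     call. = FALSE)
  lv <- unique(g)
  if (length(lv) < 2L) stop(">= 2 groups required", call. = FALSE)
  idx <- c("simpson", "shannon")
  summ <- do.call(rbind, lapply(lv, function(l) {
    d <- diversity[g == l, ]
    data.frame(group = l, n = nrow(d),
               simpson_median = median(d$simpson, na.rm = TRUE),
               simpson_iqr = stats::IQR(d$simpson, na.rm = TRUE),
               shannon_median = median(d$shannon, na.rm = TRUE),
               shannon_iqr = stats::IQR(d$shannon, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(idx, function(ix)
    do.call(rbind, lapply(pairs, function(pr) {
      x <- diversity[[ix]][g == pr[[1L]]]
      y <- diversity[[ix]][g == pr[[2L]]]
      p <- if (all(is.na(x)) || all(is.na(y))) NA_real_
      else suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
      # fully tied comparisons have zero rank variance: no evidence at all
      if (length(p) == 1L && is.nan(p)) p <- 1
      data.frame(index = ix, group1 = pr[[1L]], group2 = pr[[2L]],
                 p_value = p, stringsAsFactors = FALSE)
    }))))
  rownames(summ) <- rownames(tests) <- NULL
  list(summary = summ, tests = tests)
}
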