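# Nearest-archetype classification of tumors into invasion subtypes from
# their signature-enrichment profiles, and cross-tabulation against external
# subtype labels (e.g. CMS) with hypergeometric overlap enrichment.
#
# The classifier is deliberately transparent: each subtype is an archetype of
# expected signature activation (+1), irrelevance (0) or suppression (-1);
# samples are assigned to the archetype whose pattern their z-scaled ssGSEA
# profile matches best, or left unclassified when the match is weak or
# ambiguous.

#' The default invasion-subtype archetype matrix
#'
#' Four rows (proliferative, collective, crypt_like, EMT) by nine signature
#' columns, entries in \{-1, 0, +1\}. The pattern encodes the qualitative
#' behaviour of the four subtypes: proliferative tumors are the most extreme
#' in all CRC signatures except the epithelial one; collective invasion
#' suppresses the stromal block (mesenchymal, EMT activation, CAF, stromal,
#' invasive front) while staying epithelial; crypt-like and EMT invasion both
#' activate the stromal block and differ in proliferation and central-tumor
#' activation (crypt-like up, EMT down). Shipped as an editable TSV in
#' `inst/extdata/invasion_archetypes.tsv`; supply your own via
#' [read_archetypes()] to change signatures or patterns.
#'
#' @return Numeric matrix, subtypes x signatures, entries in \{-1, 0, 1\}.
#' @export
default_archetypes <- function() {
  read_archetypes(system.file("extdata", "invasion_archetypes.tsv",
                              package = "crcInvasion", mustWork = TRUE))
}

#' Read an archetype matrix from TSV
#'
#' Expected layout: first column subtype name, remaining columns one signed
#' integer (-1/0/+1) per signature.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, subtypes x signatures.
#' @export
read_archetypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  check_archetypes(m)
  m
}

check_archetypes <- function(archetypes) {
  if (!is.matrix(archetypes) || !is.numeric(archetypes))
    stop("`archetypes` must be a numeric matrix (subtypes x signatures)", call. = FALSE)
  if (is.null(rownames(archetypes)) || is.null(colnames(archetypes)))
    stop("`archetypes` needs subtype rownames and signature colnames", call. = FALSE)
  if (!all(archetypes %in% c(-1, 0, 1)))
    stop("archetype entries must be -1, 0 or +1", call. = FALSE)
  if (any(rowSums(archetypes != 0) == 0))
    stop("archetype row(s) with no nonzero entry", call. = FALSE)
  invisible(archetypes)
}

#' Z-scale an enrichment score matrix across samples
#'
#' Centers and scales each signature row to zero mean and unit standard
#' deviation across samples. The population SD convention (divide by n) is
#' used so that small hand-checked examples are exact. Constant rows cannot
#' be scaled; they are set to all-zero with a warning.
#'
#' @param esm Enrichment score matrix, signatures x samples (>= 2 samples).
#' @return Matrix of the same shape, row-wise z-scores.
#' @export
#' @examples
#' zscale_scores(rbind(sig = c(a = 1, b = 2, c = 3)))
zscale_scores <- function(esm) {
  if (!is.matrix(esm) || !is.numeric(esm))
    stop("`esm` must be a numeric matrix (signatures x samples)", call. = FALSE)
  if (ncol(esm) < 2L)
    stop("z-scaling is cohort-relative and needs >= 2 samples", call. = FALSE)
  out <- esm
  for (i in seq_len(nrow(esm))) {
    s <- sd_pop(esm[i, ])
    if (s == 0) {
      warning("constant score row set to zero: ", rownames(esm)[i] %||% i,
              call. = FALSE)
      out[i, ] <- 0
    } else out[i, ] <- (esm[i, ] - mean(esm[i, ])) / s
  }
  out
}

# cosine (uncentered correlation) between a sample's z-scores and one
# archetype row, over that row's nonzero support; degenerate norms give 0.
# Centered (Pearson) correlation is NOT used here: an archetype whose support
# is all +1 (e.g. crypt-like) is constant over its support, and centering
# would make its similarity undefined for every sample.
archetype_similarity <- function(z, arch_row) {
  sup <- arch_row != 0
  zs <- z[sup]; as_ <- arch_row[sup]
  den <- sqrt(sum(zs^2) * sum(as_^2))
  if (!is.finite(den) || den == 0) return(0)
  sum(zs * as_) / den
}

#' Classify samples into invasion subtypes by nearest archetype
#'
#' For each sample, the similarity to every archetype is the cosine between
#' the sample's z-scaled signature vector and the archetype's +/-1 entries
#' over that archetype's nonzero support. The sample gets the best-matching
#' subtype label if its confidence (best similarity) reaches `tau` and its
#' margin (best minus second-best similarity) reaches `delta`; otherwise it
#' is `unclassified`. Exact similarity ties are broken by archetype row
#' order (and reported via a message).
#'
#' The defaults `tau = 0.3`, `delta = 0.09` are calibrated on the reference
#' synthetic score cohort (archetype effect 1 SD, noise 1 SD,
#' [generate_archetype_scores()]) so that the unclassified fraction matches
#' the roughly one-fifth of tumors that resist classification in practice.
#'
#' @param scaled_scores Z-scaled score matrix from [zscale_scores()],
#'   signatures x samples.
#' @param archetypes Archetype matrix (subtypes x signatures), e.g.
#'   [default_archetypes()].
#' @param tau Minimum confidence (best-archetype similarity).
#' @param delta Minimum margin (best minus second-best similarity).
#' @return Data frame of class `subtype_assignment`: `sample`, `label`,
#'   `confidence`, `margin`, plus one `sim_<subtype>` column per archetype.
#'   The thresholds are stored in attributes `tau` and `delta`.
#' @export
classify_samples <- function(scaled_scores, archetypes = default_archetypes(),
                             tau = 0.3, delta = 0.09) {
  check_archetypes(archetypes)
  check_scalar_number(tau, "tau", min = -1, max = 1)
  check_scalar_number(delta, "delta", min = 0, max = 2)
  needed <- colnames(archetypes)[colSums(archetypes != 0) > 0]
  missing <- setdiff(needed, rownames(scaled_scores))
  if (length(missing))
    stop("archetype signature(s) missing from the score matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  z <- scaled_scores[colnames(archetypes), , drop = FALSE]
  n <- ncol(z)
  sims <- matrix(NA_real_, n, nrow(archetypes),
                 dimnames = list(colnames(z), rownames(archetypes)))
  for (j in seq_len(n))
    for (k in seq_len(nrow(archetypes)))
      sims[j, k] <- archetype_similarity(z[, j], archetypes[k, ])
  best_i <- apply(sims, 1L, which.max)
  conf <- sims[cbind(seq_len(n), best_i)]
  second <- apply(sims, 1L, function(s) sort(s, decreasing = TRUE)[2L])
  margin <- conf - second
  n_tied <- sum(margin == 0 & conf >= tau)
  if (n_tied)
    message(n_tied, " exact similarity tie(s) broken by archetype order")
  label <- rownames(archetypes)[best_i]
  label[conf < tau | margin < delta] <- "unclassified"
  out <- data.frame(sample = colnames(z), label = label, confidence = conf,
                    margin = margin, stringsAsFactors = FALSE, row.names = NULL)
  for (k in rownames(archetypes)) out[[paste0("sim_", k)]] <- sims[, k]
  attr(out, "tau") <- tau
  attr(out, "delta") <- delta
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

#' Summarize subtype assignments
#'
#' @param assignments A `subtype_assignment` data frame (or any data frame
#'   with a `label` column).
#' @return List: `counts` (named, all labels incl. unclassified),
#'   `n_samples`, `n_classified`, `fraction_classified`.
#' @export
#' @examples
#' a <- data.frame(label = rep(c("proliferative", "unclassified"), c(3, 1)))
#' summarize_subtypes(a)
summarize_subtypes <- function(assignments) {
  lab <- assignments$label
  counts <- table(lab)
  n <- length(lab)
  n_classified <- sum(lab != "unclassified")
  list(counts = c(counts),
       n_samples = n,
       n_classified = n_classified,
       fraction_classified = if (n) n_classified / n else 0)
}

#' Cross-tabulate subtype assignments against external labels
#'
#' Builds the contingency table over samples carrying both labels, with
#' row/column fractions and a per-cell one-sided hypergeometric p-value for
#' over-representation (is this cell larger than expected if the two
#' labelings were independent?). Raw p-values are reported together with a
#' Bonferroni-adjusted column, since every cell is tested.
#'
#' @param assignments A `subtype_assignment` data frame (columns `sample`,
#'   `label`), or any data frame with those columns.
#' @param external_labels Data frame with columns `sample` and `label`
#'   (e.g. CMS calls), as read by [read_labels_tsv()].
#' @return List of class `crosstab_result`: `counts`, `row_fractions`,
#'   `col_fractions`, `p_values`, `p_bonferroni`, `n_samples`.
#' @export
crosstab_enrichment <- function(assignments, external_labels) {
  a <- assignments[, c("sample", "label")]
  b <- external_labels[, c("sample", "label")]
  common <- intersect(a$sample, b$sample)
  if (!length(common))
    stop("no samples carry both labelings", call. = FALSE)
  la <- setNames(a$label, a$sample)[common]
  lb <- setNames(b$label, b$sample)[common]
  counts <- table(ours = la, external = lb)
  N <- sum(counts)
  p <- counts
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    K <- sum(counts[i, ]); n_draw <- sum(counts[, j]); x <- counts[i, j]
    # P(X >= x) for X ~ Hypergeometric(N, K, n_draw)
    p[i, j] <- phyper(x - 1, K, N - K, n_draw, lower.tail = FALSE)
  }
  structure(list(counts = unclass(counts),
                 row_fractions = proportions(unclass(counts), 1L),
                 col_fractions = proportions(unclass(counts), 2L),
                 p_values = unclass(p),
                 p_bonferroni = pmin(unclass(p) * length(p), 1),
                 n_samples = N),
            class = "crosstab_result")
}

#' @export
print.crosstab_result <- function(x, ...) {
  cat(sprintf("crosstab over %d doubly-labeled samples\n", x$n_samples))
  print(x$counts)
  invisible(x)
}
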