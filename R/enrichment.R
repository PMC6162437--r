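# Single-sample GSEA scoring and two-group GSEA with a permutation null.
#
# ssGSEA here follows the rank-weighted running-sum definition: within each
# sample, genes are ranked (1 = lowest expression), walked in descending rank
# order, and the score is the sum over all positions of the difference between
# the cumulative weighted hit fraction and the cumulative uniform miss
# fraction. Being rank-based, the score is invariant to any strictly
# increasing per-sample transform of expression.

#' Per-sample rank transform of an expression matrix
#'
#' Replaces values within each sample by ranks (1 = lowest). Ties are broken
#' deterministically by gene id (lexicographic order of the rownames), not by
#' average ranks: average ranks would break the integer steps of the running
#' sum, and the lexicographic rule is reproducible across platforms.
#'
#' @param matrix Expression matrix (genes x samples).
#' @return Integer matrix of the same shape: within-sample ranks.
#' @export
rank_transform <- function(matrix) {
  check_expression_matrix(matrix)
  tie_order <- order(rownames(matrix))
  out <- matrix(0L, nrow(matrix), ncol(matrix), dimnames = dimnames(matrix))
  for (j in seq_len(ncol(matrix))) {
    # order by value, ties by gene id: ranks are a permutation of 1..n
    o <- tie_order[order(matrix[tie_order, j], method = "radix")]
    out[o, j] <- seq_len(nrow(matrix))
  }
  out
}

#' ssGSEA enrichment score for one sample
#'
#' Walks the genes of one sample in descending rank order. A gene in the set
#' (a hit) advances the hit fraction by its weighted rank
#' `rank^weight_exponent`, normalized over all in-set genes; a gene outside
#' the set advances the miss fraction by `1 / (number of out-of-set genes)`.
#' The score is the sum of (hit fraction - miss fraction) over all positions.
#'
#' @param sample_ranks Named numeric vector of within-sample ranks
#'   (a column of [rank_transform()]).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Non-negative rank weight; `0` weights all hits
#'   equally, the conventional ssGSEA choice is `0.25`.
#' @return A single enrichment score.
#' @export
#' @examples
#' r <- c(A = 4, B = 3, C = 2, D = 1)
#' ssgsea_score(r, c("A", "C"), weight_exponent = 0)  # 1.0
ssgsea_score <- function(sample_ranks, gene_set, weight_exponent = 0.25) {
  if (is.null(names(sample_ranks))) stop("`sample_ranks` must be named by gene",
                                         call. = FALSE)
  check_scalar_number(weight_exponent, "weight_exponent", min = 0)
  hit <- names(sample_ranks) %in% toupper(gene_set) |
         names(sample_ranks) %in% gene_set
  m <- sum(hit); n <- length(sample_ranks)
  if (m < 2L) stop("gene set has < 2 genes in the matrix", call. = FALSE)
  if (m == n) stop("gene set covers the whole gene universe; miss fraction undefined",
                   call. = FALSE)
  o <- order(sample_ranks, decreasing = TRUE)
  hit_o <- hit[o]
  w <- ifelse(hit_o, sample_ranks[o]^weight_exponent, 0)
  cum_hit <- cumsum(w) / sum(w)
  cum_miss <- cumsum(!hit_o) / (n - m)
  sum(cum_hit - cum_miss)
}

#' ssGSEA score matrix over a signature collection
#'
#' Scores every usable set (>= 2 in-matrix genes, not the whole universe) in
#' every sample. Unusable sets are dropped with a warning. With
#' `normalize = TRUE` all scores are divided by the global score range
#' (max - min across the whole matrix), the conventional ssGSEA
#' normalization; this rescaling preserves within-set sample ordering.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param collection A [signature_collection()].
#' @param weight_exponent Rank weight, see [ssgsea_score()].
#' @param normalize Divide all scores by the global score range?
#' @return Numeric matrix, signatures x samples, with attributes
#'   `weight_exponent` and `normalized`.
#' @export
ssgsea_matrix <- function(matrix, collection, weight_exponent = 0.25,
                          normalize = TRUE) {
  check_expression_matrix(matrix)
  stopifnot(inherits(collection, "signature_collection"))
  cov <- validate_against_matrix(collection, matrix)
  usable <- cov$set[cov$usable & cov$n_present < nrow(matrix)]
  if (!length(usable)) stop("no usable sets for this matrix", call. = FALSE)
  dropped <- setdiff(cov$set, usable)
  if (length(dropped))
    warning("dropping unusable set(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  ranks <- rank_transform(matrix)
  rn_upper <- toupper(rownames(ranks))
  es <- matrix(NA_real_, length(usable), ncol(matrix),
               dimnames = list(usable, colnames(matrix)))
  for (s in usable) {
    genes <- rownames(ranks)[rn_upper %in% collection$sets[[s]]]
    for (j in seq_len(ncol(ranks)))
      es[s, j] <- ssgsea_score(ranks[, j], genes, weight_exponent)
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  attr(es, "weight_exponent") <- weight_exponent
  attr(es, "normalized") <- normalize
  es
}

# signal-to-noise ranking metric with the standard GSEA variance floor:
# each group SD is floored at 0.2 * |group mean| + 1e-8
signal_to_noise <- function(matrix, in_group1) {
  x1 <- matrix[, in_group1, drop = FALSE]
  x2 <- matrix[, !in_group1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- if (n1 > 1) sqrt(pmax(rowSums(x1^2) - n1 * m1^2, 0) / (n1 - 1)) else rep(0, nrow(x1))
  s2 <- if (n2 > 1) sqrt(pmax(rowSums(x2^2) - n2 * m2^2, 0) / (n2 - 1)) else rep(0, nrow(x2))
  s1 <- pmax(s1, 0.2 * abs(m1) + 1e-8)
  s2 <- pmax(s2, 0.2 * abs(m2) + 1e-8)
  (m1 - m2) / (s1 + s2)
}

# weighted Kolmogorov-Smirnov running-sum enrichment statistic on a ranking
# metric: hits advance by |metric|^p normalized, misses retreat uniformly;
# the statistic is the deviation of maximum magnitude
gsea_es <- function(metric, hit, p = 1) {
  o <- order(metric, decreasing = TRUE)
  hit_o <- hit[o]
  w <- ifelse(hit_o, abs(metric[o])^p, 0)
  sw <- sum(w)
  if (sw == 0) w[hit_o] <- 1 / sum(hit_o) else w <- w / sw
  run <- cumsum(w - (!hit_o) / sum(!hit))
  run[which.max(abs(run))]
}

#' Two-group GSEA with a permutation null
#'
#' Genes are ranked by signal-to-noise between the two groups; the weighted
#' Kolmogorov-Smirnov running-sum statistic of the gene set on that ranking
#' is compared with its permutation null. The permutation scheme follows the
#' usual sample-size guard: phenotype (label) permutation when both groups
#' have at least `min_group_for_phenotype` samples, otherwise gene-set
#' (random set of equal size) permutation. The p-value uses the add-one
#' estimator `(1 + #{permuted |ES| >= observed |ES|}) / (n_perm + 1)`, so it
#' is never zero and has granularity `1/(n_perm + 1)`.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param labels Two-level factor/character/logical vector over samples; the
#'   first level (or `TRUE`) is group 1, enrichment is signed towards it.
#' @param gene_set Character vector of gene ids (>= 2 present in the matrix).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param weight_exponent Hit weight exponent `p` of the running sum.
#' @param min_group_for_phenotype Minimum per-group size for phenotype
#'   permutation.
#' @return A list of class `gsea_result`: `set_size`, `es`, `p_value`,
#'   `n_perm`, `permutation` ("phenotype" or "gene_set"), `metric`
#'   ("signal_to_noise"), `seed`.
#' @export
gsea_two_group <- function(matrix, labels, gene_set, n_perm = 1000, seed = 1,
                           weight_exponent = 1, min_group_for_phenotype = 7) {
  check_expression_matrix(matrix)
  check_count(n_perm, "n_perm")
  if (length(labels) != ncol(matrix))
    stop("`labels` must have one entry per sample", call. = FALSE)
  if (is.logical(labels)) in1 <- labels
  else {
    lv <- unique(as.character(labels))
    if (length(lv) != 2L) stop("`labels` must have exactly 2 levels", call. = FALSE)
    in1 <- as.character(labels) == lv[[1L]]
  }
  if (!any(in1) || all(in1)) stop("both groups must be non-empty", call. = FALSE)
  hit <- toupper(rownames(matrix)) %in% toupper(gene_set)
  if (sum(hit) < 2L) stop("gene set has < 2 genes in the matrix", call. = FALSE)
  if (all(hit)) stop("gene set covers the whole gene universe", call. = FALSE)

  metric <- signal_to_noise(matrix, in1)
  obs <- gsea_es(metric, hit, weight_exponent)

  scheme <- if (min(sum(in1), sum(!in1)) >= min_group_for_phenotype)
    "phenotype" else "gene_set"
  set.seed(seed)
  null_es <- numeric(n_perm)
  if (scheme == "phenotype") {
    for (b in seq_len(n_perm)) {
      perm <- sample(in1)
      null_es[b] <- gsea_es(signal_to_noise(matrix, perm), hit, weight_exponent)
    }
  } else {
    m <- sum(hit)
    for (b in seq_len(n_perm)) {
      fake <- rep(FALSE, nrow(matrix))
      fake[sample.int(nrow(matrix), m)] <- TRUE
      null_es[b] <- gsea_es(metric, fake, weight_exponent)
    }
  }
  p <- (1 + sum(abs(null_es) >= abs(obs))) / (n_perm + 1)
  structure(list(set_size = sum(hit), es = obs, p_value = p, n_perm = n_perm,
                 permutation = scheme, metric = "signal_to_noise", seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, p = %.4g (%d genes, %d %s permutations)\n",
              x$es, x$p_value, x$set_size, x$n_perm, x$permutation))
  invisible(x)
}
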