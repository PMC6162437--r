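# Independent oracles and small fixture builders used across tests.
# The oracles are deliberately literal (position-by-position loops), kept
# separate from the package's vectorized implementations.

# brute-force ssGSEA running sum: walk positions in descending rank order,
# accumulating weighted hit and uniform miss fractions step by step
brute_force_ssgsea <- function(ranks, set_genes, w) {
  genes <- names(ranks)
  ord <- genes[order(ranks, decreasing = TRUE)]
  in_set <- ord %in% set_genes
  m <- sum(in_set)
  n <- length(ord)
  denom_hit <- 0
  for (g in ord[in_set]) denom_hit <- denom_hit + ranks[[g]]^w
  cum_hit <- 0; cum_miss <- 0; es <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_hit <- cum_hit + ranks[[ord[i]]]^w / denom_hit
    else cum_miss <- cum_miss + 1 / (n - m)
    es <- es + (cum_hit - cum_miss)
  }
  es
}

# random expression matrix with unique gene/sample names
random_expr <- function(n_genes, n_samples, seed = 1, mean = 3, sd = 1) {
  set.seed(seed)
  matrix(pmax(rnorm(n_genes * n_samples, mean, sd), 0), n_genes, n_samples,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# adjusted Rand index between two labelings (closed-form from the
# contingency table; independent of any clustering code under test)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# cohort configuration mirroring the 26-sample canine-like design: four
# planted groups, each marked by one up-regulated 40-gene set (2 SD), on a
# 400-gene background
canine_like_config <- function(seed, effect = 2) {
  groups <- c(g1 = 7L, g2 = 7L, g3 = 6L, g4 = 6L)
  d <- diag(4)
  dimnames(d) <- list(names(groups), names(groups))
  spec <- lapply(setNames(names(groups), paste0("set_", names(groups))),
                 function(g) list(n_genes = 40, effect = effect,
                                  directions = d[g, ]))
  cohort_config(n_samples_per_subtype = groups, n_background_genes = 400,
                signature_spec = spec, noise_sd = 1, baseline_mean = 3,
                seed = seed)
}
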