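test_that("expressed-gene filter matches a direct counting oracle", {
  set.seed(5)
  m <- random_expr(200, 8)
  m[sample(length(m), 800)] <- 0  # zero-inflate
  zero_gene <- rownames(m)[rowSums(m > 0) == 0]
  f1 <- filter_expressed(m, 1)
  expect_identical(nrow(f1), sum(rowSums(m > 0) >= 1))
  expect_false(any(zero_gene %in% rownames(f1)))
  # boundary: expressed in exactly one sample is retained at threshold 1
  one <- rownames(m)[rowSums(m > 0) == 1]
  expect_true(all(one %in% rownames(f1)))
  expect_error(filter_expressed(matrix(0, 3, 2,
    dimnames = list(letters[1:3], c("x", "y"))), 1), "no genes")
})

test_that("NMF reconstructs exact low-rank input and keeps its objective monotone", {
  m <- matrix(1, 10, 8, dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  fit <- nmf_factorize(m, 1, n_restarts = 3, seed = 1)
  expect_lt(fit$recon_error, 1e-6)
  expect_true(all(diff(fit$error_trace) <= 1e-8))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_error(nmf_factorize(m, 8, n_restarts = 2), "smaller than")
})

test_that("NMF recovers planted block structure and is permutation-equivariant", {
  set.seed(2)
  blocks <- rep(1:4, each = 6)
  m <- matrix(0.1, 80, 24) + abs(matrix(rnorm(80 * 24, 0, 0.05), 80, 24))
  for (k in 1:4) m[((k - 1) * 20 + 1):(k * 20), blocks == k] <- 10
  dimnames(m) <- list(paste0("g", 1:80), paste0("s", 1:24))
  fit <- nmf_factorize(m, 4, n_restarts = 10, seed = 3)
  expect_equal(adjusted_rand_index(fit$assignments, blocks), 1.0)
  # permuting sample columns permutes assignments identically
  perm <- sample(24)
  fit_p <- nmf_factorize(m[, perm], 4, n_restarts = 10, seed = 3)
  expect_equal(unname(adjusted_rand_index(fit_p$assignments, blocks[perm])), 1.0)
})

test_that("rank selection finds the planted rank and degrades gracefully", {
  co <- generate_expression_cohort(canine_like_config(seed = 1))
  sel <- select_rank(co$expression, 2:6, n_restarts = 10, seed = 1)
  expect_identical(sel$rank, 4L)
  expect_identical(sel$profile$rank, 2:6)
  expect_true(all(sel$profile$cophenetic <= 1 + 1e-12))
  # an exactly rank-1 matrix is maximally stable at rank 1
  m1 <- outer(runif(12, 1, 2), runif(9, 1, 2))
  dimnames(m1) <- list(paste0("g", 1:12), paste0("s", 1:9))
  sel1 <- select_rank(m1, 1:3, n_restarts = 5, seed = 2)
  expect_equal(sel1$profile$cophenetic[1], 1.0)
  expect_identical(sel1$rank, 1L)
})

test_that("top-variable hclust separates duplicated sample groups", {
  set.seed(7)
  base_a <- rnorm(300, 5); base_b <- rnorm(300, 5)
  m <- cbind(sapply(1:5, function(i) base_a + rnorm(300, 0, 0.05)),
             sapply(1:5, function(i) base_b + rnorm(300, 0, 0.05)))
  dimnames(m) <- list(paste0("g", 1:300), paste0("s", 1:10))
  hc <- top_variable_hclust(m, n_top_genes = 300, k_clusters = 2)
  expect_identical(unname(hc$labels[1:5]), rep(hc$labels[[1]], 5))
  expect_identical(unname(hc$labels[6:10]), rep(hc$labels[[6]], 5))
  expect_false(hc$labels[[1]] == hc$labels[[6]])
  # n_top = all genes is just no filtering
  expect_identical(hc$genes_used, rownames(m)[order(apply(m, 1, var),
                                                    decreasing = TRUE)])
  # constant sample profiles have undefined correlation
  m[, 1] <- 1
  expect_error(top_variable_hclust(m, 300, 2), "s1")
})

test_that("planted two-group structure is recovered by hclust and PCA", {
  aris <- vapply(1:5, function(s) {
    cfg <- cohort_config(
      n_samples_per_subtype = c(p = 10L, q = 10L),
      n_background_genes = 600,
      signature_spec = list(mark = list(n_genes = 60, effect = 2,
                                        directions = c(p = 1, q = -1))),
      seed = s)
    co <- generate_expression_cohort(cfg)
    hc <- top_variable_hclust(co$expression, 500, 2)
    adjusted_rand_index(hc$labels[co$labels$sample], co$labels$label)
  }, 1)
  expect_gte(mean(aris >= 0.9), 0.8)

  cfg <- cohort_config(
    n_samples_per_subtype = c(p = 12L, q = 12L),
    n_background_genes = 400,
    signature_spec = list(mark = list(n_genes = 50, effect = 2,
                                      directions = c(p = 1, q = -1))),
    seed = 31)
  co <- generate_expression_cohort(cfg)
  emb <- pca_embed(co$expression, 3)
  expect_true(all(diff(emb$variance_explained) <= 1e-12))
  expect_lte(sum(emb$variance_explained), 1)
  grp <- as.integer(co$labels$label == "p")
  expect_gte(abs(cor(emb$coordinates[co$labels$sample, 1], grp)), 0.8)
})

test_that("hclust trees export as readable Newick", {
  m <- random_expr(50, 6, seed = 2)
  hc <- top_variable_hclust(m, 50, 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(hc$tree, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, colnames(m))
})
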