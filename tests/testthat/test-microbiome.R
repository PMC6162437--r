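test_that("taxonomy aggregation conserves per-sample read totals", {
  g <- generate_taxon_counts(n_taxa = 60, n_samples = 8, depth = 3000, seed = 4)
  tab <- g$table
  for (lv in c("species", "family", "phylum")) {
    agg <- aggregate_taxonomy(tab, lv)
    expect_equal(colSums(agg$counts), colSums(tab$counts))
  }
  # two species of one family sum in the family table
  fam <- aggregate_taxonomy(tab, "family")
  f1 <- tab$lineage$family[[1]]
  expect_equal(unname(fam$counts[f1, ]),
               unname(colSums(tab$counts[tab$lineage$family == f1, , drop = FALSE])))
  # species-level aggregation of a species-level table is the identity on counts
  sp <- aggregate_taxonomy(tab, "species")
  expect_equal(unname(rowSums(sp$counts)[order(rownames(sp$counts))]),
               unname(rowSums(tab$counts)[order(tab$lineage$species)]))
})

test_that("relative abundances sum to one and flag empty samples", {
  cnt <- matrix(c(5L, 5L, 0L, 0L), 2, 2,
                dimnames = list(c("t1", "t2"), c("ok", "empty")))
  lin <- data.frame(taxon = c("t1", "t2"), phylum = "P", family = "F",
                    species = c("t1", "t2"))
  tab <- taxon_count_table(cnt, lin)
  expect_warning(ra <- relative_abundance(tab), "zero total")
  expect_equal(unname(ra$proportions[, "ok"]), c(0.5, 0.5))
  expect_true(all(is.na(ra$proportions[, "empty"])))
  expect_identical(ra$empty_samples, "empty")
})

test_that("cohort enrichment matches hand arithmetic and zeroes flat taxa", {
  cnt <- rbind(flat = c(100L, 100L, 100L),
               up   = c(100L, 100L, 800L),
               rest = c(800L, 800L, 100L))
  colnames(cnt) <- c("s1", "s2", "s3")
  lin <- data.frame(taxon = rownames(cnt), phylum = "P", family = "F",
                    species = rownames(cnt))
  tab <- taxon_count_table(cnt, lin)
  fc <- enrichment_log2fc(tab, pseudocount = 0.5)
  expect_equal(unname(fc["flat", ]), rep(0, 3))
  # depth-normalized rpm for 'up': (1e5, 1e5, 8e5), cohort median 1e5
  expect_equal(unname(fc["up", "s3"]), log2(8e5 + 0.5) - log2(1e5 + 0.5))
  expect_error(enrichment_log2fc(taxon_count_table(
    cnt[, 1, drop = FALSE], lin)), ">= 2 samples")
})

test_that("diversity indices match their closed forms", {
  expect_equal(simpson_diversity(c(10L)), 0)
  expect_equal(simpson_diversity(c(5L, 5L)), 1 - 40 / 90)
  expect_equal(round(simpson_diversity(c(5L, 5L)), 4), 0.5556)
  expect_equal(simpson_diversity(c(1L, 1L)), 1)
  expect_error(simpson_diversity(c(1L)), "N >= 2")
  expect_equal(shannon_diversity(c(7L)), 0)
  expect_equal(shannon_diversity(c(5L, 5L)), log(2))
  expect_equal(shannon_diversity(c(1L, 2L, 3L)), 1.011404, tolerance = 1e-6)
  expect_error(shannon_diversity(integer()), "N >= 1")
  # uniform composition maximizes both; Shannon hits ln k exactly
  for (k in c(2, 5, 10)) {
    u <- rep(10L, k)
    expect_equal(shannon_diversity(u), log(k))
    set.seed(k)
    skewed <- c(50L, rep(2L, k - 1))
    expect_lt(shannon_diversity(skewed), log(k))
    expect_lte(simpson_diversity(skewed), simpson_diversity(u))
  }
  # invariance to taxon relabeling/permutation
  x <- c(3L, 9L, 1L, 7L)
  expect_equal(shannon_diversity(sample(x)), shannon_diversity(x))
  expect_equal(simpson_diversity(rev(x)), simpson_diversity(x))
})

test_that("Shannon agrees with an independent implementation and subsampling converges", {
  skip_if_not_installed("vegan")
  set.seed(13)
  x <- as.integer(rmultinom(1, 5000, prob = runif(30))[, 1])
  expect_equal(shannon_diversity(x), unname(vegan::diversity(x, "shannon")))
  # multinomial subsample at growing depth approaches the full-depth value
  p <- x / sum(x)
  sh_small <- shannon_diversity(as.integer(rmultinom(1, 1e3, p)[, 1]))
  sh_big <- shannon_diversity(as.integer(rmultinom(1, 1e6, p)[, 1]))
  full <- shannon_diversity(x)
  expect_lt(abs(sh_big - full), abs(sh_small - full) + 0.01)
  expect_lt(abs(sh_big - full), 0.01)
})

test_that("group comparison reports medians and rank-test p-values", {
  g <- generate_taxon_counts(n_taxa = 100, n_samples = 12,
                             depleted_samples = 7:12, depth = 2000, seed = 6)
  d <- diversity_table(g$table)
  cg <- compare_groups(d, g$labels)
  expect_setequal(cg$summary$group, c("normal", "depleted"))
  expect_identical(nrow(cg$tests), 2L)  # one pair x two indices
  expect_true(all(cg$tests$p_value > 0 & cg$tests$p_value <= 1))
  # identical groups give p = 1 under the tie convention
  dd <- data.frame(sample = paste0("s", 1:6),
                   simpson = rep(0.5, 6), shannon = rep(1, 6), N = 100,
                   taxa_observed = 10)
  gl <- data.frame(sample = paste0("s", 1:6), label = rep(c("u", "v"), 3))
  cg2 <- compare_groups(dd, gl)
  expect_true(all(cg2$tests$p_value == 1))
  # medians invariant to sample order
  cg3 <- compare_groups(d[rev(seq_len(nrow(d))), ], g$labels)
  expect_equal(cg3$summary[order(cg3$summary$group), -1],
               cg$summary[order(cg$summary$group), -1], ignore_attr = TRUE)
})
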