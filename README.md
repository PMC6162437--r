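# crcInvasion

Molecular subtyping of colorectal tumors by **invasion mode**. Colorectal
carcinomas spread in recognizably different ways: as cohesive epithelial
groups (*collective* invasion), as monolayer, MYC-positive crypt-like
structures embedded in dense fibroblast stroma (*crypt-like* invasion), or
after epithelial–mesenchymal transition (*EMT*), while a fourth class is
dominated by WNT/β-catenin-driven epithelial proliferation rather than
invasion. These modes matter clinically: the mesenchymal consensus subtype
(CMS4) of colorectal cancer mixes two of them (crypt-like and EMT) that
differ in TGF-β activation and in how much mucosal microbiota the tumor
retains.

`crcInvasion` implements the computational chain needed to call these four
classes from bulk expression data and to characterize them, for
computational biologists working with tumor transcriptomes (human or
canine):

* **ssGSEA scoring.** For sample *j* with within-sample ranks *r* and gene
  set *S* (|S| = m of n genes), genes are walked in descending rank order
  and

  ES(S, j) = Σᵢ [ P_hit(i) − P_miss(i) ],
  P_hit(i) = Σ_{g ∈ S, pos ≤ i} r_g^α / Σ_{g ∈ S} r_g^α,
  P_miss(i) = #{g ∉ S, pos ≤ i} / (n − m),

  with weight α = 0.25 by default. Two-group GSEA uses the weighted
  Kolmogorov–Smirnov running-sum statistic on a signal-to-noise ranking with
  a phenotype-permutation null and the add-one p-value estimator.
* **NMF metagene consensus clustering.** Multiplicative-update NMF (squared
  Frobenius objective, best of 30 restarts), sample assignment by argmax
  metagene coefficient, consensus matrices over restarts, and rank selection
  at the peak of the consensus-cophenetic profile. Plus hierarchical
  clustering of top-variable genes (1 − Pearson, average linkage) and PCA.
* **Nearest-archetype subtype classification.** Signature × sample ssGSEA
  scores are z-scaled per signature (population SD); each sample's
  similarity to a subtype is the cosine between its z-profile and the
  subtype's ±1 archetype pattern over that pattern's nonzero support.
  Samples below a confidence (τ = 0.3) or margin (δ = 0.09) threshold stay
  `unclassified`. Cross-tabulation against external labels (e.g. CMS) uses
  per-cell one-sided hypergeometric enrichment.
* **Microbiome profiling** from taxon × sample read-count tables:
  taxonomy-level aggregation, log2 fold-change enrichment vs the cohort
  median (reads-per-million, pseudocount 0.5), Simpson's diversity in the
  unbiased pairwise form D = 1 − Σ nᵢ(nᵢ−1)/[N(N−1)], and Shannon–Wiener
  diversity D = −Σ pᵢ ln pᵢ.
* **Cross-species mutation annotation**: global protein alignment
  (BLOSUM62, affine gaps) with a residue correspondence map for relating
  mutation positions between orthologs; β-catenin phosphodegron flagging
  (D32, S33, G34, S37, T41, S45); premature-stop detection in
  intron-retaining transcripts.
* **Synthetic cohorts** with planted structure — expression cohorts with
  subtype-specific signature shifts, archetype-derived score cohorts,
  long-tailed taxon count tables with planted enrichment or depth
  depletion, toy ortholog pairs with known residue maps — so the whole
  pipeline is testable without any external download.

## Worked example

```r
library(crcInvasion)

# a 200-sample cohort drawn from the four invasion archetypes
arch <- default_archetypes()
g <- generate_archetype_scores(arch, n_per_subtype = 50,
                               effect = 1, noise_sd = 1, seed = 42)
calls <- classify_samples(zscale_scores(g$scores), arch)
summarize_subtypes(calls)[c("n_classified", "fraction_classified")]
#> $n_classified
#> [1] 155
#> $fraction_classified
#> [1] 0.775

head(calls[calls$label != "unclassified", 1:4], 3)
#>               sample         label confidence    margin
#> 2 S002_proliferative proliferative  0.5824307 0.5812217
#> 4 S004_proliferative proliferative  0.5173593 0.5636225
#> 5 S005_proliferative proliferative  0.4975845 0.1944996
```

Each classified sample carries its similarity to every archetype; the
`confidence` column is the best similarity and `margin` the gap to the
runner-up — samples that match no pattern, or two patterns almost equally,
stay unclassified (here 22.5%, close to the roughly one-fifth of real
tumors that resist classification). Diversity of a microbial count table:

```r
tc <- generate_taxon_counts(n_taxa = 150, n_samples = 16,
                            depleted_samples = 9:16, depth = 2000, seed = 1)
d <- diversity_table(tc$table)
compare_groups(d, tc$labels)$summary[, c("group", "shannon_median")]
#>      group shannon_median
#> 1   normal       4.247246
#> 2 depleted       3.917165
```

The depth-depleted (EMT-like) samples lose rare species and sit visibly
below the mucosa-like group in Shannon diversity.

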