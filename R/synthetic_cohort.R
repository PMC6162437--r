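# Synthetic-cohort generation: expression cohorts with planted subtype
# structure, signature-score cohorts drawn from the invasion archetypes,
# taxon count tables with planted enrichment/depletion, and toy ortholog
# protein pairs. All generators are deterministic given (config, seed).

#' Build a cohort configuration
#'
#' Describes a synthetic expression cohort: how many samples per subtype, how
#' many direction-free background genes, and a list of signature gene sets,
#' each with a per-subtype direction (+1 up, 0 neutral, -1 down) and an
#' effect size in units of the noise SD. Expression is Gaussian on the
#' log2 scale: background methods downstream are rank- or variance-based, so
#' the marginal family is not critical and a Gaussian keeps effect sizes
#' interpretable in SD units.
#'
#' @param n_samples_per_subtype Named positive integer vector: samples per
#'   subtype label.
#' @param n_background_genes Number of direction-free background genes.
#' @param signature_spec Named list; each element a list with `n_genes`
#'   (positive integer), `effect` (>= 0, in SD units) and `directions`
#'   (named vector over the subtype labels with entries -1/0/+1).
#' @param noise_sd Residual SD of log2 expression (> 0).
#' @param baseline_mean Baseline mean log2 expression.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples_per_subtype, n_background_genes,
                          signature_spec, noise_sd = 1, baseline_mean = 3,
                          seed = 1) {
  if (is.null(names(n_samples_per_subtype)) || any(names(n_samples_per_subtype) == ""))
    stop("`n_samples_per_subtype` must be named by subtype", call. = FALSE)
  if (any(n_samples_per_subtype < 1) ||
      any(n_samples_per_subtype != floor(n_samples_per_subtype)))
    stop("every subtype needs a positive integer sample count", call. = FALSE)
  check_count(n_background_genes, "n_background_genes", min = 0L)
  check_scalar_number(noise_sd, "noise_sd", min = 1e-12)
  check_scalar_number(baseline_mean, "baseline_mean")
  if (!is.list(signature_spec) || is.null(names(signature_spec)))
    stop("`signature_spec` must be a named list", call. = FALSE)
  subtypes <- names(n_samples_per_subtype)
  for (nm in names(signature_spec)) {
    s <- signature_spec[[nm]]
    if (is.null(s$n_genes) || s$n_genes < 1)
      stop("signature '", nm, "': positive `n_genes` required", call. = FALSE)
    if (is.null(s$effect) || s$effect < 0)
      stop("signature '", nm, "': `effect` must be >= 0", call. = FALSE)
    if (is.null(s$directions) || !all(subtypes %in% names(s$directions)))
      stop("signature '", nm, "': `directions` must cover every subtype",
           call. = FALSE)
    if (!all(s$directions %in% c(-1, 0, 1)))
      stop("signature '", nm, "': directions must be -1, 0 or +1", call. = FALSE)
  }
  structure(list(n_samples_per_subtype = n_samples_per_subtype,
                 n_background_genes = as.integer(n_background_genes),
                 signature_spec = signature_spec,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Translate an archetype matrix into a signature spec
#'
#' Convenience builder: one synthetic gene set per archetype signature
#' column, with that column's per-subtype directions.
#'
#' @param archetypes Archetype matrix (subtypes x signatures), e.g.
#'   [default_archetypes()].
#' @param n_genes Genes per signature set.
#' @param effect Effect size in SD units, shared by all sets.
#' @return A named list usable as `signature_spec` in [cohort_config()].
#' @export
archetype_signature_spec <- function(archetypes, n_genes = 20, effect = 1) {
  check_archetypes(archetypes)
  out <- lapply(colnames(archetypes), function(sig)
    list(n_genes = n_genes, effect = effect,
         directions = setNames(archetypes[, sig], rownames(archetypes))))
  names(out) <- colnames(archetypes)
  out
}

#' Generate a synthetic expression cohort with planted subtype structure
#'
#' Samples are drawn subtype by subtype. Genes of a signature set with
#' direction `d` and effect `e` in subtype `s` have mean
#' `baseline_mean + d * e * noise_sd` in `s`-samples; background genes keep
#' the baseline mean everywhere. All values are Gaussian with SD `noise_sd`
#' and clipped at 0 (the log2(FPKM+1) scale is non-negative).
#'
#' @param config A [cohort_config()].
#' @return List: `expression` (genes x samples matrix), `labels` (data frame
#'   `sample`, `label`), `config`.
#' @export
generate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  subtypes <- names(config$n_samples_per_subtype)
  n_per <- config$n_samples_per_subtype
  samples <- unlist(lapply(subtypes, function(s)
    sprintf("%s_%02d", s, seq_len(n_per[[s]]))), use.names = FALSE)
  labels <- rep(subtypes, n_per)

  sig_names <- names(config$signature_spec)
  sig_genes <- lapply(sig_names, function(nm)
    sprintf("%s_G%03d", toupper(nm), seq_len(config$signature_spec[[nm]]$n_genes)))
  names(sig_genes) <- sig_names
  bg_genes <- sprintf("BG_%05d", seq_len(config$n_background_genes))
  genes <- c(unlist(sig_genes, use.names = FALSE), bg_genes)
  if (anyDuplicated(genes)) stop("non-unique gene names", call. = FALSE)

  mu <- matrix(config$baseline_mean, length(genes), length(samples),
               dimnames = list(genes, samples))
  for (nm in sig_names) {
    s <- config$signature_spec[[nm]]
    for (st in subtypes) {
      d <- s$directions[[st]]
      if (d != 0)
        mu[sig_genes[[nm]], labels == st] <-
          config$baseline_mean + d * s$effect * config$noise_sd
    }
  }
  expr <- mu + matrix(rnorm(length(mu), 0, config$noise_sd),
                      nrow(mu), ncol(mu))
  expr[expr < 0] <- 0
  list(expression = expr,
       labels = data.frame(sample = samples, label = labels,
                           stringsAsFactors = FALSE),
       config = config)
}

#' Generate a synthetic signature-score cohort from archetypes
#'
#' Emulates a classified tumor cohort at the level the classifier consumes:
#' for a sample of subtype `s`, each signature score is
#' `effect * archetypes[s, signature] + N(0, noise_sd)`. This is the
#' reference cohort used for classifier parameter-recovery checks and for
#' calibrating the classification thresholds.
#'
#' @param archetypes Archetype matrix (subtypes x signatures).
#' @param n_per_subtype Samples per subtype (single number or named vector
#'   over the archetype rownames).
#' @param effect Archetype effect size (SD units).
#' @param noise_sd Score noise SD.
#' @param seed Integer seed.
#' @return List: `scores` (signatures x samples), `labels` (data frame
#'   `sample`, `label`).
#' @export
generate_archetype_scores <- function(archetypes = default_archetypes(),
                                      n_per_subtype = 50, effect = 1,
                                      noise_sd = 1, seed = 1) {
  check_archetypes(archetypes)
  check_scalar_number(effect, "effect", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 1e-12)
  subtypes <- rownames(archetypes)
  if (length(n_per_subtype) == 1L)
    n_per_subtype <- setNames(rep(n_per_subtype, length(subtypes)), subtypes)
  if (!all(subtypes %in% names(n_per_subtype)))
    stop("`n_per_subtype` must cover every archetype subtype", call. = FALSE)
  set.seed(seed)
  labels <- rep(subtypes, n_per_subtype[subtypes])
  samples <- sprintf("S%03d_%s", seq_along(labels), labels)
  scores <- sapply(labels, function(s)
    effect * archetypes[s, ] + rnorm(ncol(archetypes), 0, noise_sd))
  dimnames(scores) <- list(colnames(archetypes), samples)
  list(scores = scores,
       labels = data.frame(sample = samples, label = labels,
                           stringsAsFactors = FALSE))
}

# deterministic toy taxonomy: species are spread over a small set of phyla
# and families reminiscent of gut communities
.taxonomy_pool <- list(
  Bacteroidetes = c("Bacteroidaceae", "Rikenellaceae", "Prevotellaceae"),
  Proteobacteria = c("Enterobacteriaceae", "Helicobacteraceae"),
  Firmicutes = c("Lachnospiraceae", "Ruminococcaceae", "Clostridiaceae"),
  Fusobacteria = c("Fusobacteriaceae"),
  Actinobacteria = c("Bifidobacteriaceae"))

#' Generate a taxon count table with planted enrichment and depletion
#'
#' Draws a long-tailed community (Dirichlet base propensities shared by all
#' samples, with multiplicative lognormal per-sample variation -- the
#' standard model of between-sample abundance fluctuation, whose relative
#' variance is bounded across the whole abundance range) and per-sample
#' multinomial read counts at the configured depth, so column totals equal
#' the depth exactly. Planted `(taxon, sample, fold)` effects multiply that
#' taxon's propensity in that sample by `fold` before renormalization.
#' Depleted samples (the EMT-like contrast: tumors that have lost their
#' mucosa microbiota) are drawn at one tenth of the depth.
#'
#' @param n_taxa Number of species.
#' @param n_samples Number of samples.
#' @param planted List of `list(taxon =, sample =, fold =)` planted effects
#'   (taxon/sample by name or index).
#' @param depleted_samples Character or integer vector of samples to deplete.
#' @param depth Reads per (non-depleted) sample.
#' @param seed Integer seed.
#' @param base_shape Gamma shape of the community base propensities; small
#'   values give the long-tailed species abundance typical of shotgun data.
#' @param sample_sigma SD (log scale) of the per-sample lognormal abundance
#'   perturbation; larger means samples resemble each other less.
#' @param base_floor Constant added to every taxon's (unnormalized gamma)
#'   base propensity so that no species is entirely below the detection
#'   limit of the configured depth.
#' @return List: `table` (a [taxon_count_table()]), `labels` (data frame
#'   `sample`, `label` with labels `depleted`/`normal`).
#' @export
generate_taxon_counts <- function(n_taxa, n_samples, planted = list(),
                                  depleted_samples = character(),
                                  depth = 2000, seed = 1,
                                  base_shape = 0.3, sample_sigma = 0.5,
                                  base_floor = 0.05) {
  check_count(n_taxa, "n_taxa", min = 2L)
  check_count(n_samples, "n_samples")
  check_count(depth, "depth")
  taxa <- sprintf("sp%03d", seq_len(n_taxa))
  samples <- sprintf("S%02d", seq_len(n_samples))
  resolve <- function(x, pool, what) {
    if (is.numeric(x)) x <- pool[x]
    if (anyNA(x) || !all(x %in% pool))
      stop("unknown ", what, " in `planted`/`depleted_samples`", call. = FALSE)
    x
  }
  depleted <- resolve(depleted_samples, samples, "sample")
  for (p in planted) {
    if (is.null(p$taxon) || is.null(p$sample) || is.null(p$fold) || p$fold <= 0)
      stop("each planted effect needs taxon, sample and fold > 0", call. = FALSE)
    p$taxon <- resolve(p$taxon, taxa, "taxon")
    p$sample <- resolve(p$sample, samples, "sample")
  }

  set.seed(seed)
  phyla <- rep(names(.taxonomy_pool), length.out = n_taxa)
  fams <- vapply(phyla, function(ph) {
    fs <- .taxonomy_pool[[ph]]; fs[sample.int(length(fs), 1L)]
  }, "")
  lineage <- data.frame(taxon = taxa, phylum = phyla, family = fams,
                        species = paste0("Species_", taxa),
                        stringsAsFactors = FALSE)
  base <- rgamma(n_taxa, shape = base_shape) + base_floor
  base <- base / sum(base)
  counts <- matrix(0L, n_taxa, n_samples, dimnames = list(taxa, samples))
  for (j in seq_len(n_samples)) {
    w <- base * exp(rnorm(n_taxa, 0, sample_sigma))
    for (p in planted) {
      ps <- resolve(p$sample, samples, "sample")
      if (samples[j] %in% ps) {
        pt <- resolve(p$taxon, taxa, "taxon")
        w[match(pt, taxa)] <- w[match(pt, taxa)] * p$fold
      }
    }
    w <- w / sum(w)
    d <- if (samples[j] %in% depleted) depth %/% 10L else depth
    counts[, j] <- rmultinom(1L, d, w)[, 1L]
  }
  list(table = taxon_count_table(counts, lineage),
       labels = data.frame(sample = samples,
                           label = ifelse(samples %in% depleted,
                                          "depleted", "normal"),
                           stringsAsFactors = FALSE))
}

#' Generate a toy ortholog protein pair with known residue correspondence
#'
#' Builds a random protein `A`, then derives `B` by applying the stated
#' insertions (each inserts `len` random residues immediately before the
#' given `A` position; position `1` is an N-terminal insertion) and random
#' substitutions. The returned truth map gives, for every `A` position, its
#' `B` position -- the ground truth an alignment-based residue mapper must
#' recover (e.g. an N-terminal 13-residue insertion shifts every position by
#' +13, the offset relating canine TP53 residue 162 to human residue 175).
#'
#' @param length Length of protein A.
#' @param insertions List of `c(position, length)` pairs; positions must be
#'   distinct (overlapping insertions are ambiguous and rejected).
#' @param n_substitutions Number of random substitutions applied to B.
#' @param seed Integer seed.
#' @return List: `a`, `b` (character strings), `map` (integer vector,
#'   `map[p]` = B position of A position `p`).
#' @export
generate_toy_protein_pair <- function(length, insertions = list(),
                                      n_substitutions = 0, seed = 1) {
  check_count(length, "length", min = 2L)
  check_count(n_substitutions, "n_substitutions", min = 0L)
  if (n_substitutions >= length)
    stop("`n_substitutions` must be smaller than `length`", call. = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ins_pos <- vapply(insertions, function(x) as.integer(x[[1L]]), 1L)
  ins_len <- vapply(insertions, function(x) as.integer(x[[2L]]), 1L)
  if (length(ins_pos)) {
    if (any(ins_pos < 1L) || any(ins_pos > length + 1L))
      stop("insertion position out of bounds", call. = FALSE)
    if (any(ins_len < 1L)) stop("insertion length must be >= 1", call. = FALSE)
    if (anyDuplicated(ins_pos))
      stop("overlapping insertions (duplicate positions)", call. = FALSE)
  }
  set.seed(seed)
  a <- sample(aa, length, replace = TRUE)
  # B position of A position p: p plus all insertions at or before p
  offset <- vapply(seq_len(length), function(p) sum(ins_len[ins_pos <= p]), 1L)
  map <- seq_len(length) + offset
  b <- character(length + sum(ins_len))
  b[map] <- a
  b[-map] <- sample(aa, sum(ins_len), replace = TRUE)
  if (n_substitutions > 0) {
    subs <- sample.int(length, n_substitutions)
    for (p in subs) b[map[p]] <- sample(setdiff(aa, b[map[p]]), 1L)
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""), map = map)
}
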