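# Unsupervised structure discovery: expressed-gene filtering, NMF metagene
# factorization with consensus clustering and cophenetic rank selection,
# hierarchical clustering of top-variable genes, and PCA embedding.
#
# The NMF variant is the reference one for metagene extraction: multiplicative
# updates minimizing squared Frobenius reconstruction error. The objective is
# provably non-increasing under these updates, which the implementation
# asserts on every run.

#' Filter to expressed genes
#'
#' Keeps genes whose value exceeds `floor` in at least
#' `min_expressed_samples` samples. On the `log2(FPKM + 1)` scale the default
#' floor of 0 means "any evidence of expression".
#'
#' @param matrix Expression matrix (genes x samples).
#' @param min_expressed_samples Minimum number of samples above the floor.
#' @param floor Expression floor; strictly greater values count as expressed.
#' @return The filtered matrix, row order preserved.
#' @export
filter_expressed <- function(matrix, min_expressed_samples = 1, floor = 0) {
  check_expression_matrix(matrix)
  check_count(min_expressed_samples, "min_expressed_samples")
  keep <- rowSums(matrix > floor) >= min_expressed_samples
  if (!any(keep)) stop("no genes pass the expression filter", call. = FALSE)
  matrix[keep, , drop = FALSE]
}

# one run of multiplicative-update NMF; V (genes x samples) non-negative
nmf_run <- function(V, rank, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  err_prev <- Inf
  errors <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      errors <- c(errors, err)
      if (err > err_prev + 1e-8)
        stop("NMF objective increased; multiplicative update invariant violated",
             call. = FALSE)
      if (is.finite(err_prev) && (err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(W = W, H = H, error = errors[length(errors)], errors = errors)
}

#' NMF metagene factorization with consensus clustering
#'
#' Factorizes a non-negative expression matrix `V ~ W H` at a given rank by
#' multiplicative updates (squared Frobenius objective), keeping the best of
#' `n_restarts` random restarts by reconstruction error. Sample cluster
#' assignments are the argmax over the columns of `H` (ties go to the lowest
#' component index). A consensus matrix -- the fraction of restarts in which
#' each sample pair lands in the same cluster -- summarizes the stability of
#' the clustering.
#'
#' Input values are expected on the `log2(FPKM + 1)` scale, which is already
#' non-negative; residual negative entries are clipped at 0 with a message
#' reporting the count.
#'
#' @param matrix Expression matrix (genes x samples), non-negative after
#'   clipping.
#' @param rank Number of metagenes; must be `< min(genes, samples)`.
#' @param n_restarts Random restarts.
#' @param max_iter Maximum multiplicative updates per restart.
#' @param tol Relative reconstruction-error change declaring convergence
#'   (checked every 10 iterations).
#' @param seed Integer seed.
#' @return A list of class `nmf_result`: `W` (genes x rank), `H`
#'   (rank x samples), `assignments` (named integer vector), `consensus`
#'   (samples x samples), `recon_error`, `n_restarts`, `rank`, `seed`.
#' @export
nmf_factorize <- function(matrix, rank, n_restarts = 30, max_iter = 2000,
                          tol = 1e-6, seed = 1) {
  check_expression_matrix(matrix)
  check_count(rank, "rank")
  check_count(n_restarts, "n_restarts")
  if (rank >= min(dim(matrix)))
    stop("`rank` must be smaller than both matrix dimensions", call. = FALSE)
  V <- matrix
  n_neg <- sum(V < 0)
  if (n_neg) {
    message(n_neg, " negative entr", if (n_neg == 1) "y" else "ies",
            " clipped to 0 before NMF")
    V[V < 0] <- 0
  }
  set.seed(seed)
  best <- NULL
  m <- ncol(V)
  co_count <- matrix(0, m, m, dimnames = list(colnames(V), colnames(V)))
  for (r in seq_len(n_restarts)) {
    fit <- nmf_run(V, rank, max_iter, tol)
    cl <- apply(fit$H, 2L, which.max)  # which.max: lowest index wins ties
    co_count <- co_count + outer(cl, cl, "==")
    if (is.null(best) || fit$error < best$error) best <- c(fit, list(cl = cl))
  }
  W <- best$W; H <- best$H
  dimnames(W) <- list(rownames(V), paste0("metagene", seq_len(rank)))
  dimnames(H) <- list(paste0("metagene", seq_len(rank)), colnames(V))
  structure(list(W = W, H = H,
                 assignments = setNames(best$cl, colnames(V)),
                 consensus = co_count / n_restarts,
                 recon_error = best$error,
                 error_trace = best$errors,
                 n_restarts = n_restarts, rank = rank, seed = seed),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("NMF: rank %d, %d restarts, reconstruction error %.4g\n",
              x$rank, x$n_restarts, x$recon_error))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Top-loading genes of one metagene
#'
#' @param nmf An `nmf_result`.
#' @param component Metagene index.
#' @param n Number of genes to return.
#' @return Data frame `gene`, `loading`, sorted by descending loading.
#' @export
metagene_top_genes <- function(nmf, component, n = 25) {
  stopifnot(inherits(nmf, "nmf_result"))
  check_count(component, "component")
  if (component > nmf$rank) stop("component exceeds rank", call. = FALSE)
  w <- nmf$W[, component]
  o <- order(w, decreasing = TRUE)[seq_len(min(n, length(w)))]
  data.frame(gene = rownames(nmf$W)[o], loading = unname(w[o]),
             stringsAsFactors = FALSE)
}

# cophenetic correlation of a consensus matrix: agreement between the
# consensus dissimilarity (1 - consensus) and the cophenetic distances of its
# average-linkage dendrogram; 1 means perfectly stable clustering
consensus_cophenetic <- function(consensus) {
  d <- as.dist(1 - consensus)
  if (sd(d) == 0) return(1)  # all pairs identical: perfectly stable
  hc <- hclust(d, method = "average")
  cor(d, cophenetic(hc))
}

#' Choose the NMF rank by consensus-cophenetic correlation
#'
#' Runs consensus NMF at each candidate rank and returns, among the ranks
#' whose cophenetic correlation of the consensus matrix reaches `threshold`,
#' the one where the cophenetic profile peaks (exact ties go to the smallest
#' such rank). Peak selection rather than "largest passing rank" is used
#' because consensus clusterings of strongly structured data remain highly
#' stable above the true rank: the profile typically rises to the true rank
#' and then begins a shallow decline, so the peak -- not the last rank above
#' a cutoff -- marks the planted structure. If no candidate passes, the
#' lowest candidate is returned with a warning: the data show no stable
#' cluster structure at any candidate rank.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param candidate_ranks Integer vector of ranks to try (>= 2 candidates).
#' @param n_restarts Restarts per rank.
#' @param seed Integer seed (a distinct substream is derived per rank).
#' @param threshold Minimum cophenetic correlation to accept a rank.
#' @param ... Passed to [nmf_factorize()] (`max_iter`, `tol`).
#' @return List: `rank` (chosen), `profile` (data frame rank x cophenetic),
#'   `fits` (the `nmf_result` per candidate).
#' @export
select_rank <- function(matrix, candidate_ranks = 2:6, n_restarts = 30,
                        seed = 1, threshold = 0.95, ...) {
  check_expression_matrix(matrix)
  if (length(candidate_ranks) < 2L) stop(">= 2 candidate ranks required", call. = FALSE)
  if (any(candidate_ranks >= min(dim(matrix))))
    stop("candidate rank(s) not smaller than both matrix dimensions", call. = FALSE)
  fits <- list(); coph <- numeric(length(candidate_ranks))
  for (i in seq_along(candidate_ranks)) {
    k <- candidate_ranks[[i]]
    fits[[as.character(k)]] <- nmf_factorize(matrix, k, n_restarts = n_restarts,
                                             seed = seed + 1000L * i, ...)
    coph[i] <- consensus_cophenetic(fits[[as.character(k)]]$consensus)
  }
  profile <- data.frame(rank = candidate_ranks, cophenetic = coph)
  passing <- coph >= threshold
  if (any(passing)) {
    coph_pass <- ifelse(passing, coph, -Inf)
    chosen <- candidate_ranks[which.max(coph_pass)]
  } else {
    chosen <- min(candidate_ranks)
    warning("no candidate rank reaches cophenetic correlation ", threshold,
            "; returning the lowest candidate", call. = FALSE)
  }
  list(rank = chosen, profile = profile, fits = fits)
}

#' Hierarchical clustering of samples on top-variable genes
#'
#' Ranks genes by variance (log scale), keeps the top `n_top_genes`, and
#' clusters samples on `1 - Pearson correlation` distance with average
#' linkage; the tree is cut at `k_clusters`.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param n_top_genes Number of most-variable genes to use.
#' @param k_clusters Number of clusters to cut the tree into.
#' @return List: `labels` (named integer vector), `tree` (hclust),
#'   `genes_used` (character vector).
#' @export
top_variable_hclust <- function(matrix, n_top_genes = 1000, k_clusters = 2) {
  check_expression_matrix(matrix)
  check_count(n_top_genes, "n_top_genes")
  check_count(k_clusters, "k_clusters")
  if (n_top_genes > nrow(matrix)) stop("`n_top_genes` exceeds gene count", call. = FALSE)
  v <- apply(matrix, 1L, var)
  top <- rownames(matrix)[order(v, decreasing = TRUE)[seq_len(n_top_genes)]]
  sub <- matrix[top, , drop = FALSE]
  const <- apply(sub, 2L, sd) == 0
  if (any(const))
    stop("constant sample profile(s): ", paste(colnames(sub)[const], collapse = ", "),
         call. = FALSE)
  d <- as.dist(1 - cor(sub))
  hc <- hclust(d, method = "average")
  list(labels = cutree(hc, k = k_clusters), tree = hc, genes_used = top)
}

#' Export an hclust merge tree as Newick text
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' PCA embedding of samples
#'
#' Centers each gene across samples and computes principal components of the
#' samples (no scaling).
#'
#' @param matrix Expression matrix (genes x samples).
#' @param n_components Number of components to return.
#' @return List: `coordinates` (samples x components),
#'   `variance_explained` (fractions, non-increasing, summing to <= 1).
#' @export
pca_embed <- function(matrix, n_components = 2) {
  check_expression_matrix(matrix)
  check_count(n_components, "n_components")
  if (n_components > min(dim(matrix)))
    stop("`n_components` exceeds min(genes, samples)", call. = FALSE)
  p <- prcomp(t(matrix), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       variance_explained = ve[seq_len(n_components)])
}
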