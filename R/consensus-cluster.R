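#' Preprocess a linear expression matrix for clustering
#'
#' Applies `log2(x + pseudocount)` followed by gene-wise centering and
#' scaling to unit variance, so every gene contributes on the same scale
#' regardless of its absolute expression. Genes with zero variance are
#' dropped with a warning (they carry no clustering information and break
#' scaling).
#'
#' @param x an [expr_matrix()] or gene x sample numeric matrix (linear scale).
#' @param genes optional character vector restricting to a gene panel (e.g.
#'   the metabolic signature being clustered on).
#' @param pseudocount log offset, default 1.
#' @return z-scored gene x sample matrix.
#' @export
preprocess_expression <- function(x, genes = NULL, pseudocount = 1) {
  v <- as_values(x)
  if (!is.null(genes)) {
    found <- intersect(genes, rownames(v))
    if (!length(found)) stop_fmt("none of the requested genes are present")
    if (length(found) < length(genes)) {
      warn_fmt("%d requested genes absent from the matrix", length(genes) - length(found))
    }
    v <- v[found, , drop = FALSE]
  }
  lg <- to_log2(v, pseudocount)
  sds <- apply(lg, 1, stats::sd)
  if (any(sds == 0)) {
    warn_fmt("%d zero-variance genes dropped before clustering", sum(sds == 0))
    lg <- lg[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (lg - rowMeans(lg)) / sds
}

#' Agglomerative base clustering
#'
#' The base learner of the consensus procedure: hierarchical agglomerative
#' clustering of the rows of `x` under the stated metric and linkage, with
#' the tree cut into exactly `k` groups.
#'
#' @param x items x features numeric matrix, or a `dist` object.
#' @param k number of clusters (>= 2, <= number of items).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return integer vector of cluster labels in `1..k`.
#' @export
base_cluster <- function(x, k, metric = "euclidean", linkage = "average") {
  if (k < 2) stop_fmt("k must be >= 2")
  d <- if (inherits(x, "dist")) x else stats::dist(x, method = metric)
  n <- attr(d, "Size")
  if (k > n) stop_fmt("k = %d exceeds the %d items available", k, n)
  stats::cutree(stats::hclust(d, method = linkage), k = k)
}

# Draw the resampling stream: a list of index vectors, deterministic in seed.
# Independent of k, so every candidate k sees the same subsamples.
draw_subsamples <- function(n, subsample_fraction, n_resamples, seed) {
  m <- ceiling(subsample_fraction * n)
  with_seed(seed, lapply(seq_len(n_resamples), function(i) sample.int(n, m)))
}

# Shared engine: tally co-clustering over one subsample stream for every k in
# `ks` at once (the tree per resample is built once and cut at each k).
consensus_engine <- function(x, ks, n_resamples, subsample_fraction, seed,
                             metric, linkage) {
  v <- if (inherits(x, "dist")) NULL else as.matrix(x)
  n <- if (is.null(v)) attr(x, "Size") else nrow(v)
  D <- if (is.null(v)) as.matrix(x) else as.matrix(stats::dist(v, method = metric))
  idx_list <- draw_subsamples(n, subsample_fraction, n_resamples, seed)
  co_sample <- matrix(0, n, n)
  co_cluster <- stats::setNames(lapply(ks, function(k) matrix(0, n, n)), ks)
  for (idx in idx_list) {
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = linkage)
    for (k in ks) {
      cl <- stats::cutree(hc, k = k)
      co_cluster[[as.character(k)]][idx, idx] <-
        co_cluster[[as.character(k)]][idx, idx] + outer(cl, cl, "==")
    }
  }
  items <- if (is.null(v)) attr(x, "Labels") else rownames(v)
  list(co_sample = co_sample, co_cluster = co_cluster, items = items)
}

finish_consensus <- function(engine, k, n_resamples, subsample_fraction) {
  co_sample <- engine$co_sample
  M <- engine$co_cluster[[as.character(k)]] / pmax(co_sample, 1)
  never <- co_sample == 0
  diag(never) <- FALSE
  if (any(never)) {
    warn_fmt("%d item pairs never co-sampled; consensus imputed as 0.5", sum(never) / 2)
    M[never] <- 0.5
  }
  diag(M) <- 1
  dimnames(M) <- list(engine$items, engine$items)
  structure(
    list(M = M, co_sample_counts = co_sample, k = k,
         n_resamples = n_resamples, subsample_fraction = subsample_fraction),
    class = "consensus_matrix"
  )
}

#' Build a resampling consensus matrix
#'
#' For each of `n_resamples` resamples, `ceiling(subsample_fraction * n)`
#' items are drawn without replacement, the base hierarchical clustering is
#' run at `k`, and co-clustering events are tallied. The consensus matrix is
#' the elementwise ratio of co-cluster to co-sample counts; pairs never drawn
#' together (vanishingly rare at the defaults) are imputed at the
#' uninformative value 0.5 with a warning.
#'
#' @inheritParams base_cluster
#' @param n_resamples number of resampling iterations (default 250).
#' @param subsample_fraction fraction of items drawn per resample (default 0.8).
#' @param seed integer seed; the subsample stream is deterministic given the
#'   seed and independent of `k`.
#' @return object of class `consensus_matrix`: list with `M` (symmetric,
#'   unit-diagonal, entries in `[0, 1]`), `co_sample_counts`, `k`,
#'   `n_resamples`, `subsample_fraction`.
#' @export
build_consensus_matrix <- function(x, k, n_resamples = 250,
                                   subsample_fraction = 0.8, seed = 1,
                                   metric = "euclidean", linkage = "average") {
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop_fmt("subsample_fraction must be in (0, 1]")
  }
  if (n_resamples < 1) stop_fmt("n_resamples must be >= 1")
  if (k < 2) stop_fmt("k must be >= 2")
  engine <- consensus_engine(x, k, n_resamples, subsample_fraction, seed, metric, linkage)
  finish_consensus(engine, k, n_resamples, subsample_fraction)
}

consensus_M <- function(M) {
  if (inherits(M, "consensus_matrix")) M$M else as.matrix(M)
}

#' Final partition from a consensus matrix
#'
#' Agglomerative clustering on the dissimilarity `1 - M`, cut at `k`.
#'
#' @param M a `consensus_matrix` or plain consensus matrix.
#' @param k number of clusters; defaults to the k the matrix was built at.
#' @param linkage agglomeration method.
#' @return integer labels in `1..k`, named by item when names are available.
#' @export
consensus_labels <- function(M, k = NULL, linkage = "average") {
  if (is.null(k)) {
    if (!inherits(M, "consensus_matrix")) stop_fmt("k must be given for a plain matrix")
    k <- M$k
  }
  m <- consensus_M(M)
  stats::cutree(stats::hclust(stats::as.dist(1 - m), method = linkage), k = k)
}

#' Normalized Euclidean distance to theoretical perfection (NED)
#'
#' Measures how far a consensus matrix is from the "theoretically perfect"
#' matrix implied by a partition: `P[i, j] = 1` if items i and j share a
#' label and 0 otherwise. The score is the root mean square deviation over
#' the strict upper triangle,
#' `sqrt(sum_{i<j} (M_ij - P_ij)^2 / (n(n-1)/2))`; 0 means the resampled
#' clusterings reproduce the partition perfectly, and 0.5 is the value of a
#' maximally uninformative consensus (all off-diagonal entries 0.5).
#'
#' @param M a `consensus_matrix` or plain numeric matrix.
#' @param labels partition of the items of `M`.
#' @return non-negative scalar.
#' @export
ned_score <- function(M, labels) {
  m <- consensus_M(M)
  if (length(labels) != nrow(m)) {
    stop_fmt("labels length %d does not match matrix size %d", length(labels), nrow(m))
  }
  P <- outer(labels, labels, "==")
  ut <- upper.tri(m)
  sqrt(mean((m[ut] - P[ut])^2))
}

#' Select the optimal number of clusters by NED
#'
#' Builds a consensus matrix and consensus partition for every candidate `k`,
#' scores each with [ned_score()], and selects the number of clusters. When
#' one or more candidates are essentially perfect (NED below `perfect_tol`),
#' the largest such `k` is chosen: coarser merges of perfectly separated
#' clusters are also perfectly stable, so the finest perfectly-reproducible
#' partition is the informative one. Otherwise the `k` minimizing NED is
#' chosen, with ties broken toward the smaller `k`. Runs lacking reproducible
#' structure are flagged (`weak_structure`): either no candidate comes close
#' to perfection and the chosen partition is outlier-degenerate (its smallest
#' cluster holds under 5% of items, the signature of hierarchical clustering
#' on unstructured data, which reproducibly splits off a handful of extreme
#' points), or even the best NED exceeds `weak_threshold`.
#'
#' @inheritParams build_consensus_matrix
#' @param k_range integer vector of candidate cluster numbers (each >= 2).
#' @param perfect_tol NED at or below which a partition counts as perfectly
#'   reproduced (default 0.005, under the one-pair resolution of the score
#'   for cohorts of 150+ items).
#' @param weak_threshold minimum NED above which the run is flagged as
#'   lacking reproducible structure (default 0.35).
#' @param keep_matrices retain every per-k consensus matrix (default TRUE).
#' @return object of class `clustering_result`: `ned_table` (data.frame of k
#'   and NED), `chosen_k`, `labels` (partition at `chosen_k`), `per_k`
#'   (per-k labels and consensus matrices), `item_order` (consensus-ordered
#'   permutation for heatmap export), `weak_structure`, `items`, `params`.
#' @export
select_optimal_k <- function(x, k_range = 2:8, n_resamples = 250,
                             subsample_fraction = 0.8, seed = 1,
                             metric = "euclidean", linkage = "average",
                             perfect_tol = 0.005, weak_threshold = 0.35,
                             keep_matrices = TRUE) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop_fmt("k_range is empty")
  if (any(k_range < 2)) stop_fmt("every k in k_range must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop_fmt("subsample_fraction must be in (0, 1]")
  }
  engine <- consensus_engine(x, k_range, n_resamples, subsample_fraction,
                             seed, metric, linkage)
  per_k <- list()
  neds <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cm <- finish_consensus(engine, k, n_resamples, subsample_fraction)
    labels <- consensus_labels(cm, k, linkage = linkage)
    neds[i] <- ned_score(cm, labels)
    per_k[[as.character(k)]] <- list(
      consensus = if (keep_matrices) cm else NULL,
      labels = labels,
      ned = neds[i]
    )
  }
  perfect <- which(neds <= perfect_tol)
  chosen_k <- if (length(perfect)) {
    k_range[max(perfect)]
  } else {
    k_range[which.min(neds)] # which.min takes the first = smallest k on ties
  }
  chosen <- per_k[[as.character(chosen_k)]]
  cm_chosen <- if (keep_matrices) chosen$consensus else {
    finish_consensus(engine, chosen_k, n_resamples, subsample_fraction)
  }
  item_order <- stats::hclust(stats::as.dist(1 - consensus_M(cm_chosen)),
                              method = linkage)$order
  labels <- chosen$labels
  names(labels) <- engine$items
  min_frac <- min(table(labels)) / length(labels)
  weak <- (min(neds) > perfect_tol && min_frac < 0.05) ||
    min(neds) > weak_threshold
  structure(list(
    ned_table = data.frame(k = k_range, ned = neds),
    chosen_k = chosen_k,
    labels = labels,
    per_k = per_k,
    item_order = item_order,
    weak_structure = weak,
    items = engine$items,
    params = list(n_resamples = n_resamples, subsample_fraction = subsample_fraction,
                  seed = seed, metric = metric, linkage = linkage,
                  perfect_tol = perfect_tol, weak_threshold = weak_threshold)
  ), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("consensus clustering over k = %s\n",
              paste(range(x$ned_table$k), collapse = "..")))
  cat(sprintf("chosen k = %d (NED = %.4f)%s\n", x$chosen_k,
              x$ned_table$ned[x$ned_table$k == x$chosen_k],
              if (x$weak_structure) " [weak structure]" else ""))
  invisible(x)
}

# Re-index cluster labels so cluster 1 has the highest mean signature value.
relabel_by_signature <- function(labels, signature_values) {
  means <- tapply(signature_values, labels, mean)
  ord <- order(-means)
  remap <- stats::setNames(seq_along(ord), names(means)[ord])
  out <- remap[as.character(labels)]
  names(out) <- names(labels)
  out
}

#' Two-way consensus clustering of an expression matrix
#'
#' Runs [select_optimal_k()] independently on samples (columns) and on genes
#' (rows) of the preprocessed matrix, mirroring two-way heatmap organization.
#' Sample clusters are re-indexed by descending mean expression of the
#' signature genes, so cluster 1 is the highest-signature cluster; gene
#' clusters are re-indexed by descending overall mean z-score.
#'
#' @param x an [expr_matrix()] or linear gene x sample matrix.
#' @param sample_k_range,gene_k_range candidate cluster numbers for samples
#'   and genes.
#' @param genes optional gene panel to cluster on (see
#'   [preprocess_expression()]).
#' @param signature_genes genes whose mean expression orders the sample
#'   clusters (default: all clustered genes).
#' @param pseudocount log offset for preprocessing.
#' @param preprocess apply [preprocess_expression()] (default); set FALSE
#'   when `x` is already on the clustering scale (e.g. z-scored), which also
#'   makes the procedure exactly symmetric under transposition.
#' @inheritParams build_consensus_matrix
#' @param ... further arguments passed to [select_optimal_k()].
#' @return list of class `two_way_clustering` with `sample_result`,
#'   `gene_result`, `sample_labels`, `gene_labels`, `sample_order`,
#'   `gene_order` and the preprocessed matrix `z`.
#' @export
two_way_cluster <- function(x, sample_k_range = 2:8, gene_k_range = 2:6,
                            genes = NULL, signature_genes = NULL,
                            pseudocount = 1, preprocess = TRUE,
                            n_resamples = 250,
                            subsample_fraction = 0.8, seed = 1, ...) {
  z <- if (preprocess) {
    preprocess_expression(x, genes = genes, pseudocount = pseudocount)
  } else {
    v <- as_values(x)
    if (!is.null(genes)) v[intersect(genes, rownames(v)), , drop = FALSE] else v
  }
  sample_result <- select_optimal_k(t(z), k_range = sample_k_range,
                                    n_resamples = n_resamples,
                                    subsample_fraction = subsample_fraction,
                                    seed = child_seed(seed, 11), ...)
  gene_result <- select_optimal_k(z, k_range = gene_k_range,
                                  n_resamples = n_resamples,
                                  subsample_fraction = subsample_fraction,
                                  seed = child_seed(seed, 12), ...)
  sig <- if (is.null(signature_genes)) rownames(z) else intersect(signature_genes, rownames(z))
  sample_sig <- colMeans(z[sig, , drop = FALSE])
  # cluster 1 = highest mean signature expression, matching heatmap convention
  sample_labels <- relabel_by_signature(sample_result$labels, sample_sig)
  names(sample_labels) <- colnames(z)
  gene_labels <- relabel_by_signature(gene_result$labels, rowMeans(z))
  names(gene_labels) <- rownames(z)
  structure(list(
    sample_result = sample_result,
    gene_result = gene_result,
    sample_labels = sample_labels,
    gene_labels = gene_labels,
    sample_order = sample_result$item_order,
    gene_order = gene_result$item_order,
    z = z
  ), class = "two_way_clustering")
}
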