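#' Per-cell-type mean profiles from annotated single-cell data
#'
#' Splits single cells into tumor and T-cells by the supplied annotation,
#' isolates the cytotoxic T-cell subset by consensus clustering the T-cells
#' on their immune-signature ssGSEA scores, and returns per-gene arithmetic
#' mean linear expression for tumor cells and cytotoxic T-cells. Cell-class
#' means are arithmetic because mixtures add linearly.
#'
#' @param sc_matrix gene x cell linear expression matrix.
#' @param annotations per-cell labels, `"tumor"` or `"t_cell"` (named by
#'   cell or aligned to columns).
#' @param immune_sets `gene_set_collection` of immune subset markers; must
#'   contain `cytotoxic_set`.
#' @param cytotoxic_set name of the cytotoxic signature used to pick the
#'   subset (default `"cytotoxic"`).
#' @param k_range candidate subset counts for the T-cell subclustering.
#' @param n_resamples consensus resamples for the subclustering.
#' @param seed integer seed.
#' @return data.frame of class `cell_profiles`: `gene`, `tumor_mean`,
#'   `tcell_mean`; attributes `n_tumor_cells`, `n_cytotoxic_cells`,
#'   `tcell_subcluster` (labels, or NULL when subclustering was skipped),
#'   `subclustering_skipped`.
#' @export
cell_profiles_from_annotated_sc <- function(sc_matrix, annotations, immune_sets,
                                            cytotoxic_set = "cytotoxic",
                                            k_range = 2:4, n_resamples = 100,
                                            seed = 1) {
  v <- as_values(sc_matrix)
  annotations <- align_labels(annotations, colnames(v))
  bad <- setdiff(unique(annotations), c("tumor", "t_cell"))
  if (length(bad)) stop_fmt("unknown cell annotations: %s", paste(bad, collapse = ", "))
  tumor_cells <- names(annotations)[annotations == "tumor"]
  t_cells <- names(annotations)[annotations == "t_cell"]
  if (!length(tumor_cells)) stop_fmt("no tumor cells annotated")
  if (!length(t_cells)) stop_fmt("no T-cells annotated")
  if (!cytotoxic_set %in% names(immune_sets)) {
    stop_fmt("immune sets lack the '%s' signature", cytotoxic_set)
  }
  skipped <- FALSE
  sub_labels <- NULL
  if (length(t_cells) == 1) {
    warn_fmt("single T-cell: subclustering skipped, cell used as cytotoxic")
    cytotoxic_cells <- t_cells
    skipped <- TRUE
  } else {
    scores <- ssgsea_table(v[, t_cells, drop = FALSE], immune_sets)
    feats <- scale(scores)
    feats <- feats[, colSums(!is.finite(feats)) == 0, drop = FALSE]
    k_range <- k_range[k_range < length(t_cells)]
    if (!length(k_range)) {
      warn_fmt("too few T-cells to subcluster; all treated as cytotoxic")
      cytotoxic_cells <- t_cells
      skipped <- TRUE
    } else {
      res <- select_optimal_k(feats, k_range = k_range,
                              n_resamples = n_resamples, seed = seed)
      sub_labels <- res$labels
      mean_cyt <- tapply(scores[, cytotoxic_set], sub_labels, mean)
      best <- names(mean_cyt)[which.max(mean_cyt)]
      cytotoxic_cells <- t_cells[sub_labels == as.integer(best)]
      if (!length(cytotoxic_cells)) {
        stop_fmt("no cytotoxic T-cell subset identifiable (clusters: %s)",
                 paste(names(mean_cyt), collapse = ", "))
      }
    }
  }
  out <- data.frame(
    gene = rownames(v),
    tumor_mean = rowMeans(v[, tumor_cells, drop = FALSE]),
    tcell_mean = rowMeans(v[, cytotoxic_cells, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_tumor_cells") <- length(tumor_cells)
  attr(out, "n_cytotoxic_cells") <- length(cytotoxic_cells)
  attr(out, "tcell_subcluster") <- sub_labels
  attr(out, "subclustering_skipped") <- skipped
  class(out) <- c("cell_profiles", "data.frame")
  out
}

#' Expected fold change under a T-cell contamination fraction
#'
#' The fold change each gene would show purely because a fraction `f` of a
#' bulk sample consists of cytotoxic T-cells instead of tumor cells:
#' `(f * tcell_mean + (1 - f) * tumor_mean + pseudocount) /
#' (tumor_mean + pseudocount)`.
#'
#' @param profiles data.frame with `gene`, `tumor_mean`, `tcell_mean`.
#' @param f contamination fraction in `[0, 1]`.
#' @param pseudocount added to both means (default 1).
#' @return named numeric vector of expected fold changes.
#' @export
expected_mixture_fc <- function(profiles, f, pseudocount = 1) {
  if (f < 0 || f > 1) stop_fmt("f must be in [0, 1]")
  denom <- profiles$tumor_mean + pseudocount
  if (any(denom <= 0)) stop_fmt("tumor mean must be positive after pseudocount")
  fc <- (f * profiles$tcell_mean + (1 - f) * profiles$tumor_mean + pseudocount) / denom
  stats::setNames(fc, profiles$gene)
}

#' Classify observed fold changes as explainable by contamination or not
#'
#' Works in log2 space with `x = log2(observed)` and `y = log2(expected)`.
#' Because the contamination fraction is an upper bound, the expected fold
#' change is the largest change admixture could produce: an observed change
#' is potentially explainable when it points in the same direction as the
#' expectation and does not exceed it (identity-line boundary assigned to
#' explainable). A zero-change tolerance of `log2(zero_tol_fold)` absorbs
#' negligible fold changes: observed changes within it are always
#' explainable, expected changes within it explain nothing beyond it, and
#' the same tolerance pads the identity comparison.
#'
#' @param expected_fc,observed_fc positive fold changes (vectors align).
#' @param significant optional logical flag per gene, carried through.
#' @param zero_tol_fold fold change treated as "no change" (default 1.05).
#' @return data.frame: `expected_fc`, `observed_fc`, `class`
#'   (`"potentially_explainable"` / `"not_explainable"`), `significant`.
#' @export
classify_explainability <- function(expected_fc, observed_fc,
                                    significant = NULL,
                                    zero_tol_fold = 1.05) {
  if (length(expected_fc) != length(observed_fc)) {
    stop_fmt("expected and observed fold changes must align")
  }
  if (any(expected_fc <= 0) || any(observed_fc <= 0)) {
    stop_fmt("fold changes must be positive")
  }
  x <- log2(observed_fc)
  y <- log2(expected_fc)
  tol <- log2(zero_tol_fold)
  explainable <- abs(x) <= tol |                        # no meaningful observed change
    (abs(y) > tol & sign(x) == sign(y) & abs(x) <= abs(y) + tol)
  cls <- ifelse(explainable, "potentially_explainable", "not_explainable")
  data.frame(
    gene = if (!is.null(names(expected_fc))) names(expected_fc) else seq_along(x),
    expected_fc = unname(expected_fc),
    observed_fc = unname(observed_fc),
    class = cls,
    significant = if (is.null(significant)) NA else significant,
    stringsAsFactors = FALSE
  )
}

#' Contamination mixture model report
#'
#' Compares the fold changes observed between a cluster of interest and a
#' comparator group against the fold changes expected if the cluster's
#' samples carried a fraction `f` of cytotoxic T-cells and the comparator
#' none. Observed fold changes are ratios of group geometric means
#' ([gm_ratio_annotation()]); expected fold changes come from
#' [expected_mixture_fc()]; classification from
#' [classify_explainability()].
#'
#' @param x an [expr_matrix()] or linear gene x sample matrix.
#' @param labels cluster labels over the samples.
#' @param profiles `cell_profiles` data.frame (`gene`, `tumor_mean`,
#'   `tcell_mean`).
#' @param f assumed contamination fraction of the cluster of interest.
#' @param de_result optional [welch_tests_by_gene()] result supplying
#'   per-gene significance flags.
#' @param cluster_one cluster assumed contaminated (default 1).
#' @param comparator clusters compared against (default: all others).
#' @param pseudocount pseudocount for geometric means and expected ratios.
#' @param gene_category optional named vector tagging genes (e.g. block
#'   membership) for the summary counts.
#' @return object of class `mixture_result`: `per_gene` data.frame
#'   (expected/observed fold changes, class, significance, category) and
#'   `summary` count table, plus `f`.
#' @export
mixture_report <- function(x, labels, profiles, f, de_result = NULL,
                           cluster_one = 1, comparator = NULL,
                           pseudocount = 1, gene_category = NULL) {
  v <- as_values(x)
  labels <- align_labels(labels, colnames(v))
  if (is.null(comparator)) comparator <- setdiff(unique(labels), cluster_one)
  genes <- intersect(profiles$gene, rownames(v))
  if (!length(genes)) stop_fmt("no profile genes present in the expression matrix")
  obs <- gm_ratio_annotation(v[genes, , drop = FALSE], labels,
                             numerator_group = cluster_one,
                             denominator_group = comparator,
                             pseudocount = pseudocount,
                             fold_threshold = 1.4)
  prof <- profiles[match(genes, profiles$gene), , drop = FALSE]
  exp_fc <- expected_mixture_fc(prof, f, pseudocount)
  sig <- if (!is.null(de_result)) {
    de_result$significant[match(genes, de_result$gene)]
  } else {
    NULL
  }
  per_gene <- classify_explainability(exp_fc, stats::setNames(obs$ratio, obs$gene),
                                      significant = sig)
  per_gene$category <- if (!is.null(gene_category)) {
    unname(gene_category[per_gene$gene])
  } else {
    NA_character_
  }
  summary_tab <- as.data.frame(table(
    category = ifelse(is.na(per_gene$category), "all", per_gene$category),
    class = per_gene$class,
    significant = ifelse(is.na(per_gene$significant), "untested", per_gene$significant)
  ), stringsAsFactors = FALSE)
  summary_tab <- summary_tab[summary_tab$Freq > 0, , drop = FALSE]
  rownames(summary_tab) <- NULL
  structure(list(per_gene = per_gene, summary = summary_tab, f = f,
                 cluster_one = cluster_one, comparator = comparator),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  n <- nrow(x$per_gene)
  ne <- sum(x$per_gene$class == "not_explainable")
  cat(sprintf(
    "mixture model at f = %.2f: %d genes, %d (%.1f%%) not explainable by contamination\n",
    x$f, n, ne, 100 * ne / n
  ))
  invisible(x)
}
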