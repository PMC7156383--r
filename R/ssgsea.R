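#' Single-sample gene set enrichment score
#'
#' Computes the rank-weighted enrichment statistic for one gene set in one
#' sample. Genes are ranked by decreasing expression (ties broken by gene
#' symbol, C-locale order, so scores are deterministic across platforms);
#' the score is the sum over ranked positions of the difference between the
#' weighted in-set empirical distribution (weights `rank^alpha`, where the
#' top gene has rank N) and the unweighted out-of-set empirical
#' distribution. Genes of the set absent from the expression vector are
#' skipped (intersection scoring).
#'
#' @param expr_values named numeric vector of linear expression values for
#'   one sample.
#' @param set a [gene_set()] or character vector of gene symbols.
#' @param alpha rank-weight exponent (default 0.75, the published default).
#' @return scalar enrichment score.
#' @export
ssgsea_single <- function(expr_values, set, alpha = 0.75) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  set_name <- if (inherits(set, "gene_set")) set$name else "gene set"
  nm <- names(expr_values)
  if (is.null(nm)) stop_fmt("expression vector must be named by gene symbol")
  in_universe <- intersect(genes, nm)
  if (!length(in_universe)) {
    stop_fmt("no genes of '%s' are present in the expression vector", set_name)
  }
  n <- length(expr_values)
  m <- length(in_universe)
  if (m == n) {
    stop_fmt("'%s' covers every gene; out-of-set distribution is undefined", set_name)
  }
  ord <- order(-expr_values, nm, method = "radix")
  sorted_names <- nm[ord]
  rank_value <- n - seq_len(n) + 1 # top-expressed gene has rank N
  in_set <- sorted_names %in% in_universe
  w <- ifelse(in_set, rank_value^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA score table over samples and gene sets
#'
#' Scores every sample of a linear expression matrix against every set of a
#' collection. With `normalize = TRUE` all raw scores are divided by the
#' global range (maximum minus minimum) of the table, so the normalized
#' table has range exactly 1.
#'
#' @param x an [expr_matrix()] or linear gene x sample matrix.
#' @param sets a `gene_set_collection` (or list of [gene_set()]).
#' @param alpha rank-weight exponent.
#' @param normalize divide by the global score range (GenePattern-style).
#' @return numeric samples x signatures matrix; attribute `provenance` is a
#'   data.frame of set sizes and per-set matched gene counts, attribute
#'   `normalized` records the flag.
#' @export
ssgsea_table <- function(x, sets, alpha = 0.75, normalize = FALSE) {
  v <- as_values(x)
  set_names <- vapply(sets, function(s) if (inherits(s, "gene_set")) s$name else "", "")
  if (any(!nzchar(set_names))) set_names <- names(sets)
  scores <- matrix(
    NA_real_, ncol(v), length(sets),
    dimnames = list(colnames(v), set_names)
  )
  matched <- integer(length(sets))
  for (j in seq_along(sets)) {
    genes <- if (inherits(sets[[j]], "gene_set")) sets[[j]]$genes else sets[[j]]
    matched[j] <- length(intersect(genes, rownames(v)))
    for (i in seq_len(ncol(v))) {
      scores[i, j] <- ssgsea_single(stats::setNames(v[, i], rownames(v)), sets[[j]], alpha)
    }
  }
  if (normalize) scores <- scores / (max(scores) - min(scores))
  attr(scores, "provenance") <- data.frame(
    signature = set_names,
    set_size = vapply(sets, function(s) length(if (inherits(s, "gene_set")) s$genes else s), 0L),
    n_matched = matched,
    stringsAsFactors = FALSE
  )
  attr(scores, "normalized") <- normalize
  scores
}

#' Z-score a score table per signature
#'
#' Each signature column is centered and scaled across samples using the
#' population (divide-by-n) standard deviation, so for two samples with
#' distinct scores the transform yields exactly -1 and +1.
#'
#' @param scores samples x signatures numeric matrix.
#' @return matrix of the same shape; columns have mean 0 and population sd 1.
#' @export
zscore_scores <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop_fmt("Z-scoring needs at least 2 samples")
  out <- scores
  for (j in seq_len(ncol(scores))) {
    s <- sd_pop(scores[, j])
    if (s == 0) {
      stop_fmt("signature '%s' has zero variance across samples",
               colnames(scores)[j])
    }
    out[, j] <- (scores[, j] - mean(scores[, j])) / s
  }
  attr(out, "provenance") <- attr(scores, "provenance")
  out
}

#' Combined subtractive score between two signatures
#'
#' The per-sample difference of signature Z-scores, e.g. cytotoxic minus
#' Treg to express the effector-to-regulatory balance of the tumor immune
#' microenvironment.
#'
#' @param scores samples x signatures matrix of raw ssGSEA scores.
#' @param minuend,subtrahend signature names.
#' @return named numeric vector `z(minuend) - z(subtrahend)` with attribute
#'   `components`.
#' @export
combined_subtractive_score <- function(scores, minuend, subtrahend) {
  scores <- as.matrix(scores)
  for (s in c(minuend, subtrahend)) {
    if (!s %in% colnames(scores)) stop_fmt("unknown signature '%s'", s)
  }
  z <- zscore_scores(scores)
  out <- z[, minuend] - z[, subtrahend]
  names(out) <- rownames(scores)
  attr(out, "components") <- c(minuend = minuend, subtrahend = subtrahend)
  out
}

#' Derive a tissue-specific marker panel
#'
#' Retains genes whose mean expression in the target tissue is at least
#' `fold_threshold` times the maximum mean across every other tissue
#' (boundary inclusive). This is the rule used to distil a skeletal-muscle
#' contamination panel from tissue-level expression atlases.
#'
#' @param tissue_means gene x tissue matrix of mean linear expression.
#' @param target_tissue column name of the tissue of interest.
#' @param fold_threshold required fold difference (default 10).
#' @param name name for the resulting set.
#' @param category category tag.
#' @return a [gene_set()] (possibly empty, with a warning).
#' @export
derive_tissue_specific_panel <- function(tissue_means, target_tissue,
                                         fold_threshold = 10,
                                         name = paste0(target_tissue, "_panel"),
                                         category = "tissue_marker") {
  tissue_means <- as.matrix(tissue_means)
  if (!target_tissue %in% colnames(tissue_means)) {
    stop_fmt("target tissue '%s' not present", target_tissue)
  }
  if (ncol(tissue_means) < 2) stop_fmt("need at least 2 tissues")
  target <- tissue_means[, target_tissue]
  others <- tissue_means[, setdiff(colnames(tissue_means), target_tissue), drop = FALSE]
  keep <- target >= fold_threshold * apply(others, 1, max)
  genes <- rownames(tissue_means)[keep]
  if (!length(genes)) {
    warn_fmt("no genes pass the %g-fold specificity filter", fold_threshold)
    return(structure(list(name = name, genes = character(0), category = category),
                     class = "gene_set"))
  }
  gene_set(name, genes, category)
}

#' Filter marker sets for leukocyte specificity
#'
#' Removes marker genes whose mean leukocyte expression is below
#' `ratio_threshold` times their mean background (bulk tissue) expression;
#' markers absent from the reference profiles are dropped with a warning.
#'
#' @param markers a `gene_set_collection` (or list of [gene_set()]).
#' @param leukocyte_expr,background_expr named per-gene mean expression
#'   vectors for the leukocyte and background reference profiles.
#' @param ratio_threshold minimum leukocyte/background ratio (default 4).
#' @return filtered collection; attribute `removal_report` is a data.frame
#'   of removed genes and reasons.
#' @export
filter_markers_by_specificity <- function(markers, leukocyte_expr,
                                          background_expr, ratio_threshold = 4) {
  eps <- 1e-9
  removed <- list()
  out <- lapply(markers, function(s) {
    present <- s$genes %in% names(leukocyte_expr) & s$genes %in% names(background_expr)
    if (any(!present)) {
      warn_fmt("set '%s': %d markers absent from reference profiles dropped",
               s$name, sum(!present))
      removed[[length(removed) + 1]] <<- data.frame(
        set = s$name, gene = s$genes[!present], reason = "absent",
        stringsAsFactors = FALSE
      )
    }
    genes <- s$genes[present]
    ratio <- (leukocyte_expr[genes] + eps) / (background_expr[genes] + eps)
    low <- ratio < ratio_threshold
    if (any(low)) {
      removed[[length(removed) + 1]] <<- data.frame(
        set = s$name, gene = genes[low], reason = "low_specificity",
        stringsAsFactors = FALSE
      )
    }
    kept <- genes[!low]
    if (!length(kept)) {
      warn_fmt("set '%s' emptied by the specificity filter", s$name)
      return(structure(list(name = s$name, genes = character(0), category = s$category),
                       class = "gene_set"))
    }
    gene_set(s$name, kept, s$category)
  })
  names(out) <- names(markers)
  out <- structure(out, class = "gene_set_collection")
  attr(out, "removal_report") <- if (length(removed)) {
    do.call(rbind, removed)
  } else {
    data.frame(set = character(0), gene = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  out
}
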