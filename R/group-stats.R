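# Resolve a labels argument against the columns of an expression matrix:
# named vectors are matched by sample id, unnamed must align positionally.
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing_samples <- setdiff(sample_ids, names(labels))
    labels <- labels[match(sample_ids, names(labels))]
    names(labels) <- sample_ids
    return(labels)
  }
  if (length(labels) != length(sample_ids)) {
    stop_fmt("unnamed labels must match the number of samples")
  }
  stats::setNames(labels, sample_ids)
}

#' Per-gene Welch t-tests between two clusters
#'
#' Two-sided Welch (unequal-variance) t-test per gene on `log2(x + 1)`
#' values, with Benjamini-Hochberg adjustment across all tested genes.
#'
#' @param x an [expr_matrix()] or linear gene x sample matrix.
#' @param labels cluster labels (named by sample or aligned to columns).
#' @param group_a,group_b the two cluster labels to compare (each needs >= 2
#'   samples).
#' @param fdr false discovery rate for the significance flag (default 0.05).
#' @param log_transform test on `log2(x + pseudocount)` (default) or raw
#'   values.
#' @param pseudocount log offset.
#' @return data.frame of class `differential_result`: per gene, group means
#'   (log2 scale), Welch `t`, degrees of freedom, raw and BH-adjusted p,
#'   `significant` flag at `fdr`, and `direction` (`"up"` = higher in
#'   `group_a`).
#' @export
welch_tests_by_gene <- function(x, labels, group_a, group_b, fdr = 0.05,
                                log_transform = TRUE, pseudocount = 1) {
  v <- as_values(x)
  labels <- align_labels(labels, colnames(v))
  a <- which(labels == group_a)
  b <- which(labels == group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop_fmt("both groups need >= 2 samples (got %d and %d)", length(a), length(b))
  }
  vals <- if (log_transform) to_log2(v, pseudocount) else v
  res <- t(vapply(seq_len(nrow(vals)), function(g) {
    xa <- vals[g, a]
    xb <- vals[g, b]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      # degenerate constant gene: no evidence if means agree, certainty if not
      if (mean(xa) == mean(xb)) {
        return(c(mean(xa), mean(xb), 0, length(xa) + length(xb) - 2, 1))
      }
      return(c(mean(xa), mean(xb), sign(mean(xa) - mean(xb)) * Inf,
               length(xa) + length(xb) - 2, 0))
    }
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    c(mean(xa), mean(xb), unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }, numeric(5)))
  out <- data.frame(
    gene = rownames(vals),
    mean_a = res[, 1],
    mean_b = res[, 2],
    t = res[, 3],
    df = res[, 4],
    p = res[, 5],
    stringsAsFactors = FALSE
  )
  adj <- bh_adjust(out$p, fdr)
  out$p_adj <- adj$p_adj
  out$significant <- adj$significant
  out$direction <- ifelse(out$mean_a >= out$mean_b, "up", "down")
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "fdr") <- fdr
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up adjusted p-values (monotone-enforced, via [stats::p.adjust()])
#' and flags at the configured false discovery rate.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param fdr target false discovery rate.
#' @return list with `p_adj` and logical `significant`.
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adj = p_adj, significant = p_adj <= fdr)
}

#' Fold annotation by ratio of group geometric means
#'
#' Per-gene ratio of the geometric means of `value + pseudocount` between
#' two groups on the linear scale, classified as `up` (ratio at or above the
#' fold threshold), `down` (at or below its reciprocal), or `unchanged`.
#'
#' @inheritParams welch_tests_by_gene
#' @param numerator_group,denominator_group group labels.
#' @param fold_threshold annotation threshold (default 1.4).
#' @return data.frame of class `fold_annotation`: `gene`, `ratio`, `class`.
#' @export
gm_ratio_annotation <- function(x, labels, numerator_group, denominator_group,
                                pseudocount = 1, fold_threshold = 1.4) {
  v <- as_values(x)
  labels <- align_labels(labels, colnames(v))
  num <- which(labels %in% numerator_group)
  den <- which(labels %in% denominator_group)
  if (!length(num) || !length(den)) stop_fmt("both groups must be non-empty")
  ratio <- vapply(seq_len(nrow(v)), function(g) {
    geometric_mean(v[g, num], pseudocount) / geometric_mean(v[g, den], pseudocount)
  }, 0)
  cls <- ifelse(ratio >= fold_threshold, "up",
                ifelse(ratio <= 1 / fold_threshold, "down", "unchanged"))
  out <- data.frame(gene = rownames(v), ratio = ratio, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("fold_annotation", "data.frame")
  out
}

#' Mutation-cluster association by chi-square tests
#'
#' Per gene, a contingency table of mutated/not-mutated against cluster
#' membership (reference cluster versus all others by default, or the full
#' k-way layout), tested with Pearson's chi-square without continuity
#' correction and adjusted by Benjamini-Hochberg. Genes mutated in zero (or
#' all) samples give degenerate tables: they are flagged and excluded from
#' the BH family rather than treated as errors.
#'
#' @param mutations a `mutation_table` data.frame (see [read_maf()]).
#' @param labels named cluster labels over the cohort's samples.
#' @param genes genes to test (default: every gene in the table).
#' @param fdr false discovery rate (default 0.01).
#' @param layout `"reference_vs_rest"` (default) or `"k_way"`.
#' @param reference_cluster reference cluster for the 2 x 2 layout.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return data.frame of class `association_result`: per gene `n_mutated`,
#'   `statistic`, `df`, `p`, `p_adj`, `significant`, `degenerate`.
#' @export
mutation_cluster_association <- function(mutations, labels, genes = NULL,
                                         fdr = 0.01,
                                         layout = c("reference_vs_rest", "k_way"),
                                         reference_cluster = 1,
                                         correct = FALSE) {
  layout <- match.arg(layout)
  if (is.null(names(labels))) stop_fmt("labels must be named by sample id")
  unknown <- setdiff(unique(mutations$sample_id), names(labels))
  if (length(unknown)) {
    warn_fmt("%d mutated samples not in the labeled cohort are ignored", length(unknown))
  }
  if (is.null(genes)) genes <- sort(unique(mutations$gene))
  samples <- names(labels)
  grouping <- if (layout == "reference_vs_rest") {
    factor(ifelse(labels == reference_cluster, "reference", "rest"),
           levels = c("reference", "rest"))
  } else {
    factor(labels)
  }
  rows <- lapply(genes, function(g) {
    mutated <- samples %in% mutations$sample_id[mutations$gene == g]
    n_mut <- sum(mutated)
    degenerate <- n_mut == 0 || n_mut == length(samples) || nlevels(droplevels(grouping)) < 2
    if (degenerate) {
      return(data.frame(gene = g, n_mutated = n_mut, statistic = NA_real_,
                        df = NA_real_, p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tab <- table(factor(mutated, levels = c(FALSE, TRUE)), grouping)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(gene = g, n_mutated = n_mut,
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$significant <- NA
  testable <- !out$degenerate
  if (any(testable)) {
    adj <- bh_adjust(out$p[testable], fdr)
    out$p_adj[testable] <- adj$p_adj
    out$significant[testable] <- adj$significant
  }
  attr(out, "layout") <- layout
  attr(out, "fdr") <- fdr
  class(out) <- c("association_result", "data.frame")
  out
}

#' Filter a mutation table to impactful mutations
#'
#' Retains mutations whose SIFT label is `deleterious` or whose PolyPhen
#' label is `probably_damaging` or `possibly_damaging`. Mutations missing
#' both annotations are treated as non-impactful (the conservative reading
#' of the OR rule).
#'
#' @param mutations a `mutation_table` data.frame.
#' @return filtered `mutation_table`.
#' @export
impactful_filter <- function(mutations) {
  keep <- mutations$sift_label == "deleterious" |
    mutations$polyphen_label %in% c("probably_damaging", "possibly_damaging")
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a numeric covariate across clusters
#'
#' Per-cluster means with t-based 95% confidence intervals, one-way ANOVA,
#' Tukey HSD adjusted pairwise comparisons, and a monotone-trend summary
#' (Spearman correlation of the covariate against the cluster index).
#' Clusters with fewer than 2 samples are excluded with a warning.
#'
#' @param values named numeric vector (sample id -> value).
#' @param labels named cluster labels covering the samples of `values`.
#' @return list of class `covariate_report`: `cluster_summary`, `anova`
#'   (`F`, `df`, `p`), `tukey` (data.frame of adjusted pairwise p),
#'   `trend` (`rho`, `p`).
#' @export
covariate_by_cluster <- function(values, labels) {
  if (!is.null(names(values)) && !is.null(names(labels))) {
    common <- intersect(names(values), names(labels))
    values <- values[common]
    labels <- labels[common]
  } else if (length(values) != length(labels)) {
    stop_fmt("values and labels must align")
  }
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn_fmt("clusters excluded with < 2 samples: %s", paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    values <- values[keep]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop_fmt("need >= 2 clusters with >= 2 samples")
  f <- factor(labels)
  cluster_summary <- do.call(rbind, lapply(levels(f), function(cl) {
    x <- values[f == cl]
    se <- stats::sd(x) / sqrt(length(x))
    half <- stats::qt(0.975, length(x) - 1) * se
    data.frame(cluster = cl, n = length(x), mean = mean(x),
               ci_lo = mean(x) - half, ci_hi = mean(x) + half,
               stringsAsFactors = FALSE)
  }))
  fit <- stats::aov(values ~ f)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$f
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  idx <- suppressWarnings(as.numeric(as.character(f)))
  if (any(is.na(idx))) idx <- as.numeric(f) # non-numeric labels: factor order
  trend <- suppressWarnings(stats::cor.test(values, idx, method = "spearman"))
  structure(list(
    cluster_summary = cluster_summary,
    anova = list(F = an$`F value`[1], df = an$Df[1:2], p = an$`Pr(>F)`[1]),
    tukey = tukey,
    trend = list(rho = unname(trend$estimate), p = trend$p.value)
  ), class = "covariate_report")
}

#' Genome-wide correlation screen against a sample score
#'
#' Pearson correlation (and t-distribution p-value) of every gene's
#' expression against a per-sample score, sorted by absolute correlation.
#' Constant genes have undefined correlation and are reported as missing.
#'
#' @param x an [expr_matrix()] or gene x sample matrix.
#' @param score named numeric vector over the samples.
#' @return data.frame of class `correlation_screen`: `gene`, `r`, `p`, `n`.
#' @export
correlate_genes_with_score <- function(x, score) {
  v <- as_values(x)
  if (!is.null(names(score))) {
    score <- score[match(colnames(v), names(score))]
  }
  n <- ncol(v)
  if (n < 3) stop_fmt("need >= 3 samples")
  if (any(is.na(score))) stop_fmt("score missing for some samples")
  sc <- score - mean(score)
  sc_ss <- sum(sc^2)
  if (sc_ss == 0) stop_fmt("score is constant")
  cv <- v - rowMeans(v)
  num <- as.vector(cv %*% sc)
  den <- sqrt(rowSums(cv^2) * sc_ss)
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(gene = rownames(v), r = r, p = p, n = n,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r), na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_screen", "data.frame")
  out
}
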