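test_that("per-gene Welch tests match the direct formula oracle", {
  set.seed(51)
  m <- random_expr(50, 12, seed = 51)
  labels <- stats::setNames(rep(c(1, 2), each = 6), colnames(m))
  res <- welch_tests_by_gene(m, labels, 1, 2)
  lg <- log2(m + 1)
  for (g in seq_len(50)) {
    o <- oracle_welch(lg[g, 1:6], lg[g, 7:12])
    expect_equal(res$t[g], o$t, tolerance = 1e-10)
    expect_equal(res$p[g], o$p, tolerance = 1e-10)
  }
  expect_true(all(res$p_adj >= res$p))

  # identical gene across groups: t = 0, p = 1
  flat <- m
  flat[1, ] <- 100
  res_flat <- welch_tests_by_gene(flat, labels, 1, 2)
  expect_equal(res_flat$t[1], 0)
  expect_equal(res_flat$p[1], 1)

  # permuting samples within groups changes nothing
  perm <- c(sample(1:6), sample(7:12))
  res_perm <- welch_tests_by_gene(m[, perm], labels[perm], 1, 2)
  expect_equal(res_perm$t, res$t, tolerance = 1e-12)

  expect_error(welch_tests_by_gene(m, labels, 1, 99), ">= 2 samples")
})

test_that("BH adjustment reproduces the step-up formula and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05))$p_adj,
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)   # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5))$p_adj, rep(0.2, 5)) # all equal: unchanged

  set.seed(60)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)$p_adj
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])$p_adj, adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("geometric-mean ratios classify fold changes symmetrically", {
  m <- matrix(c(4, 4, 1, 1,
                2, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("up_gene", "flat_gene"), sprintf("S%d", 1:4)))
  labels <- stats::setNames(c(1, 1, 2, 2), colnames(m))
  ann <- gm_ratio_annotation(m, labels, 1, 2, pseudocount = 1, fold_threshold = 1.4)
  expect_equal(ann$ratio[ann$gene == "up_gene"], 2.5) # (4+1)/(1+1)
  expect_equal(ann$class, c("up", "unchanged"))

  # swapping groups inverts every ratio
  rev_ann <- gm_ratio_annotation(m, labels, 2, 1, pseudocount = 1)
  expect_equal(rev_ann$ratio, 1 / ann$ratio, tolerance = 1e-12)

  # identical groups: all ratios 1
  same <- gm_ratio_annotation(m, stats::setNames(c(1, 2, 1, 2), colnames(m)), 1, 2)
  expect_equal(same$ratio, c(1, 1), tolerance = 1e-12)
})

test_that("chi-square association matches direct computation and handles degeneracy", {
  # balanced table: statistic 0, p 1
  muts <- data.frame(
    gene = rep("A", 20),
    sample_id = sprintf("S%02d", c(1:10, 21:30)),
    variant_classification = "Missense_Mutation",
    sift_label = "deleterious", polyphen_label = "benign",
    stringsAsFactors = FALSE
  )
  labels <- stats::setNames(rep(c(1, 2), each = 20), sprintf("S%02d", 1:40))
  res <- mutation_cluster_association(muts, labels, fdr = 0.01)
  expect_equal(res$statistic[1], 0, tolerance = 1e-12)
  expect_equal(res$p[1], 1)

  # [[20, 5], [5, 20]] has chi-square exactly 18
  muts2 <- data.frame(
    gene = "B",
    sample_id = sprintf("S%02d", c(1:20, 26:30)),
    variant_classification = "x", sift_label = "deleterious",
    polyphen_label = "benign", stringsAsFactors = FALSE
  )
  labels2 <- stats::setNames(rep(c(1, 2), each = 25), sprintf("S%02d", 1:50))
  res2 <- mutation_cluster_association(muts2, labels2)
  expect_equal(res2$statistic[1], 18, tolerance = 1e-12)
  expect_equal(res2$statistic[1],
               oracle_chisq(matrix(c(5, 20, 20, 5), 2)), tolerance = 1e-12)

  # unmutated gene: degenerate, flagged, excluded from the BH family
  res3 <- mutation_cluster_association(muts2, labels2, genes = c("B", "ZZZ"))
  expect_true(res3$degenerate[res3$gene == "ZZZ"])
  expect_true(is.na(res3$p_adj[res3$gene == "ZZZ"]))
  expect_false(res3$degenerate[res3$gene == "B"])

  # proportional rows give statistic 0
  tab <- matrix(c(10, 20, 5, 10), 2)
  expect_equal(oracle_chisq(tab), 0, tolerance = 1e-12)
})

test_that("impactful mutation filtering applies the OR rule", {
  muts <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    sample_id = sprintf("S%d", 1:5),
    variant_classification = "Missense_Mutation",
    sift_label = c("deleterious", "tolerated", "tolerated", "missing", "tolerated"),
    polyphen_label = c("benign", "benign", "possibly_damaging", "missing", "probably_damaging"),
    stringsAsFactors = FALSE
  )
  kept <- impactful_filter(muts)
  expect_setequal(kept$gene, c("A", "C", "E"))
})

test_that("covariate comparison recovers planted trends and algebraic identities", {
  set.seed(71)
  labels <- stats::setNames(rep(1:4, each = 15), sprintf("S%02d", 1:60))
  values <- stats::setNames(c(800, 550, 420, 300)[labels] + rnorm(60, 0, 60),
                            names(labels))
  rep_out <- covariate_by_cluster(values, labels)
  expect_lt(rep_out$trend$rho, -0.5) # declining with cluster index
  expect_lt(rep_out$anova$p, 1e-6)
  expect_equal(nrow(rep_out$tukey), 6)

  # two clusters: F equals the squared pooled-variance t statistic
  two_lab <- stats::setNames(rep(1:2, each = 10), sprintf("T%02d", 1:20))
  two_val <- stats::setNames(rnorm(20, rep(c(0, 1), each = 10)), names(two_lab))
  rep2 <- covariate_by_cluster(two_val, two_lab)
  t_eq <- t.test(two_val[1:10], two_val[11:20], var.equal = TRUE)$statistic
  expect_equal(rep2$anova$F, unname(t_eq)^2, tolerance = 1e-10)

  expect_warning(
    covariate_by_cluster(
      stats::setNames(c(two_val, 5), c(names(two_val), "LONE")),
      stats::setNames(c(two_lab, 3), c(names(two_lab), "LONE"))
    ),
    "excluded"
  )
})

test_that("the correlation screen matches cor.test on random instances", {
  set.seed(81)
  m <- random_expr(40, 10, seed = 81)
  score <- stats::setNames(rnorm(10), colnames(m))
  res <- correlate_genes_with_score(m, score)
  for (g in sample(rownames(m), 15)) {
    ct <- cor.test(m[g, ], score)
    row <- res[res$gene == g, ]
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p, ct$p.value, tolerance = 1e-12)
    expect_equal(row$r, oracle_pearson(m[g, ], score), tolerance = 1e-12)
  }
  # results sorted by |r| descending
  expect_true(all(diff(abs(res$r[!is.na(res$r)])) <= 1e-12))

  # a gene equal to the score has r exactly 1; negated, -1
  m2 <- rbind(m, pos = pmax(score, 0) * 0 + score - min(score) + 1,
              neg = max(score) - score + 1)
  res2 <- correlate_genes_with_score(m2, score)
  expect_equal(res2$r[res2$gene == "pos"], 1, tolerance = 1e-12)
  expect_equal(res2$r[res2$gene == "neg"], -1, tolerance = 1e-12)

  # constant gene reported as missing
  m3 <- rbind(m, flat = rep(3, 10))
  res3 <- correlate_genes_with_score(m3, score)
  expect_true(is.na(res3$r[res3$gene == "flat"]))
  expect_error(correlate_genes_with_score(m[, 1:2], score[1:2]), "3 samples")
})
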