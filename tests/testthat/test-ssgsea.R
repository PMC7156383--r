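test_that("single-sample scores match the explicit running-sum oracle", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(15:40, 1)
    v <- stats::setNames(2^rnorm(n, 5, 2), sprintf("G%03d", sample(500, n)))
    genes <- sample(names(v), sample(3:8, 1))
    alpha <- sample(c(0, 0.25, 0.75, 1), 1)
    expect_equal(ssgsea_single(v, genes, alpha),
                 oracle_ssgsea(v, genes, alpha), tolerance = 1e-12)
  }
})

test_that("scoring is deterministic, rank-based, and degenerate-safe", {
  v <- stats::setNames(c(5, 3, 8, 1, 2), c("A", "B", "C", "D", "E"))
  s <- gene_set("s", c("A", "C"))
  expect_equal(ssgsea_single(v, s), ssgsea_single(v, s))

  # invariant to strictly monotone transforms at alpha = 0 (fully rank-based)
  expect_equal(ssgsea_single(v, s, alpha = 0),
               ssgsea_single(v^3 + 1, s, alpha = 0), tolerance = 1e-12)
  expect_equal(ssgsea_single(v, s, alpha = 0),
               ssgsea_single(stats::setNames(rank(v), names(v)), s, alpha = 0),
               tolerance = 1e-12)

  expect_error(ssgsea_single(v, gene_set("all", names(v))), "out-of-set")
  expect_error(ssgsea_single(v, gene_set("none", c("X", "Y"))), "present")
})

test_that("the score table equals per-sample scoring and is order-invariant", {
  m <- random_expr(25, 4, seed = 6)
  sets <- list(gene_set("s1", rownames(m)[1:5]), gene_set("s2", rownames(m)[10:16]))
  tab <- ssgsea_table(m, sets)
  for (j in 1:2) {
    for (i in 1:4) {
      expect_equal(tab[i, j],
                   ssgsea_single(stats::setNames(m[, i], rownames(m)), sets[[j]]),
                   tolerance = 1e-12)
    }
  }
  # scrambling gene order leaves the table unchanged
  perm <- sample(nrow(m))
  expect_equal(ssgsea_table(m[perm, ], sets), tab, tolerance = 1e-12)

  # identical samples score identically
  m2 <- cbind(m[, 1, drop = FALSE], m[, 1, drop = FALSE])
  colnames(m2) <- c("X1", "X2")
  t2 <- ssgsea_table(m2, sets)
  expect_equal(t2[1, ], t2[2, ])

  # normalization: global range of the normalized table is exactly 1
  tn <- ssgsea_table(m, sets, normalize = TRUE)
  expect_equal(max(tn) - min(tn), 1, tolerance = 1e-12)

  prov <- attr(tab, "provenance")
  expect_equal(prov$n_matched, c(5L, 7L))
})

test_that("Z-scoring uses the population sd and is affine-invariant", {
  m <- random_expr(30, 5, seed = 8)
  tab <- ssgsea_table(m, list(gene_set("s1", rownames(m)[1:6])))
  z <- zscore_scores(tab)
  expect_equal(mean(z[, 1]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z[, 1]^2)), 1, tolerance = 1e-9)

  # two samples: z is exactly -1 / +1 ordered by value
  two <- matrix(c(1, 5), 2, 1, dimnames = list(c("a", "b"), "sig"))
  expect_equal(unname(zscore_scores(two)[, 1]), c(-1, 1))

  # affine transform of a column changes nothing
  expect_equal(unname(zscore_scores(tab * 3 + 7)), unname(z), tolerance = 1e-12)

  const <- matrix(2, 3, 1, dimnames = list(letters[1:3], "flat"))
  expect_error(zscore_scores(const), "flat")
  expect_error(zscore_scores(two[1, , drop = FALSE]), "2 samples")
})

test_that("combined subtractive scores behave like z-differences", {
  m <- random_expr(30, 6, seed = 10)
  sets <- list(gene_set("cd8", rownames(m)[1:5]), gene_set("treg", rownames(m)[8:12]))
  tab <- ssgsea_table(m, sets)
  comb <- combined_subtractive_score(tab, "cd8", "treg")
  z <- zscore_scores(tab)
  expect_equal(as.numeric(comb), unname(z[, "cd8"] - z[, "treg"]), tolerance = 1e-12)
  # antisymmetry
  expect_equal(as.numeric(combined_subtractive_score(tab, "treg", "cd8")),
               -as.numeric(comb), tolerance = 1e-12)
  # minuend == subtrahend: identically zero
  expect_equal(as.numeric(combined_subtractive_score(tab, "cd8", "cd8")), rep(0, 6))
  expect_error(combined_subtractive_score(tab, "cd8", "nope"), "unknown")
})

test_that("tissue-specific panel derivation applies the inclusive fold rule", {
  tm <- matrix(c(
    100, 9, 5,     # included: 100 >= 10 * 9
    100, 10, 2,    # boundary: 100 >= 10 * 10 -> included
    100, 11, 3,    # excluded: 100 < 110
    50, 1, 2       # included: 50 >= 20
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("g1", "g2", "g3", "g4"), c("muscle", "lung", "skin")))
  panel <- derive_tissue_specific_panel(tm, "muscle", fold_threshold = 10)
  expect_true("g2" %in% panel$genes)  # boundary inclusive
  expect_false("g3" %in% panel$genes)
  expect_true("g4" %in% panel$genes)
  expect_true("g1" %in% panel$genes)  # 100 >= 90
  expect_warning(
    empty <- derive_tissue_specific_panel(tm, "skin", fold_threshold = 1000),
    "no genes"
  )
  expect_length(empty$genes, 0)
})

test_that("leukocyte specificity filter keeps high-ratio markers only", {
  markers <- structure(list(
    immune = gene_set("immune", c("HI", "LO", "GONE"), "immune")
  ), class = "gene_set_collection")
  leuk <- c(HI = 20, LO = 2)
  bg <- c(HI = 1, LO = 2)
  expect_warning(
    filtered <- filter_markers_by_specificity(markers, leuk, bg, ratio_threshold = 4),
    "absent"
  )
  expect_equal(filtered$immune$genes, "HI")
  report <- attr(filtered, "removal_report")
  expect_setequal(report$gene, c("GONE", "LO"))

  # threshold 0 is vacuous for genes present in both profiles
  markers2 <- structure(list(immune = gene_set("immune", c("HI", "LO"), "immune")),
                        class = "gene_set_collection")
  same <- filter_markers_by_specificity(markers2, leuk, bg, ratio_threshold = 0)
  expect_equal(same$immune$genes, c("HI", "LO"))
})
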