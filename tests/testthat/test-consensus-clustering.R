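test_that("base clustering recovers planted partitions and handles edge cases", {
  p <- planted_points(n_per = 8, k = 2, sep = 10, seed = 2)
  labels <- base_cluster(p$x, 2)
  expect_equal(ari(labels, p$labels), 1)

  # k = n: every item its own cluster
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(sort(unique(base_cluster(x, 6))), 1:6)

  # duplicated rows always co-labeled (zero distance)
  xd <- rbind(x, x[3, , drop = FALSE])
  ld <- base_cluster(xd, 3)
  expect_equal(ld[7], ld[3])

  expect_error(base_cluster(x, 1), ">= 2")
  expect_error(base_cluster(x, 9), "exceeds")
})

test_that("consensus matrix equals an independent brute-force tally", {
  set.seed(42)
  x <- matrix(rnorm(6 * 4), 6, 4)
  cm <- build_consensus_matrix(x, k = 2, n_resamples = 10,
                               subsample_fraction = 0.8, seed = 7)
  M_oracle <- oracle_consensus(x, k = 2, n_resamples = 10, fraction = 0.8, seed = 7)
  expect_equal(unname(cm$M), M_oracle, tolerance = 1e-12)
  # structural invariants
  expect_true(isSymmetric(cm$M))
  expect_true(all(diag(cm$M) == 1))
  expect_true(all(cm$M >= 0 & cm$M <= 1))
})

test_that("planted two-block data produces a near-binary consensus", {
  p <- planted_points(n_per = 12, k = 2, sep = 8, seed = 5)
  cm <- build_consensus_matrix(p$x, k = 2, n_resamples = 100, seed = 1)
  same <- outer(p$labels, p$labels, "==")
  off_diag <- !diag(nrow(cm$M))
  expect_true(all(cm$M[same & off_diag] >= 0.95))
  expect_true(all(cm$M[!same] <= 0.05))
})

test_that("full subsampling with a deterministic learner gives binary consensus", {
  set.seed(8)
  x <- matrix(rnorm(10 * 3), 10, 3)
  cm <- build_consensus_matrix(x, k = 3, n_resamples = 20,
                               subsample_fraction = 1, seed = 2)
  expect_true(all(cm$M %in% c(0, 1)))
  # and the consensus cut reproduces the base partition, hence NED = 0
  expect_equal(ned_score(cm, consensus_labels(cm)), 0)
})

test_that("consensus labels recover block-diagonal structure and permutation invariance", {
  blocks <- rep(1:3, times = c(4, 5, 3))
  M <- outer(blocks, blocks, function(a, b) as.numeric(a == b))
  expect_equal(ari(consensus_labels(M, 3), blocks), 1)

  set.seed(30)
  noisy <- pmin(pmax(M + matrix(rnorm(144, 0, 0.1), 12, 12), 0), 1)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 1
  perm <- sample(12)
  l1 <- consensus_labels(noisy, 3)
  l2 <- consensus_labels(noisy[perm, perm], 3)
  expect_equal(ari(l1[perm], l2), 1)
})

test_that("NED matches the naive double-loop formula on random instances", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    M <- matrix(runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(ned_score(M, labels), oracle_ned(M, labels), tolerance = 1e-12)
  }
})

test_that("NED has its documented anchor values and invariances", {
  labels <- rep(1:2, each = 4)
  P <- outer(labels, labels, function(a, b) as.numeric(a == b))
  diag(P) <- 1
  expect_equal(ned_score(P, labels), 0) # perfection

  U <- matrix(0.5, 8, 8)
  diag(U) <- 1
  expect_equal(ned_score(U, labels), 0.5) # maximally uninformative

  set.seed(12)
  M <- matrix(runif(64), 8, 8)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  perm <- sample(8)
  expect_equal(ned_score(M, labels), ned_score(M[perm, perm], labels[perm]))
  expect_error(ned_score(M, labels[-1]), "match")
})

test_that("select_optimal_k agrees with per-k consensus construction", {
  p <- planted_points(n_per = 6, k = 3, sep = 6, seed = 3)
  res <- select_optimal_k(p$x, k_range = 2:4, n_resamples = 25, seed = 17)
  for (k in 2:4) {
    cm <- build_consensus_matrix(p$x, k = k, n_resamples = 25, seed = 17)
    expect_equal(res$per_k[[as.character(k)]]$consensus$M, cm$M, tolerance = 1e-12)
    expect_equal(res$per_k[[as.character(k)]]$ned,
                 ned_score(cm, consensus_labels(cm)), tolerance = 1e-12)
  }
})

test_that("singleton k range is chosen trivially and labels are seed-stable", {
  p <- planted_points(n_per = 6, k = 3, sep = 6, seed = 3)
  res <- select_optimal_k(p$x, k_range = 3, n_resamples = 20, seed = 5)
  expect_equal(res$chosen_k, 3)
  res2 <- select_optimal_k(p$x, k_range = 3, n_resamples = 20, seed = 5)
  expect_identical(res$labels, res2$labels)
})

test_that("two-way clustering separates gene blocks and sample clusters", {
  cfg <- cohort_config(n_tumor = 90, n_normal = 0, master_seed = 31)
  co <- generate_cohort(cfg)
  sig <- c(co$gene_sets$oxphos$genes, co$gene_sets$glycolysis$genes)
  tw <- two_way_cluster(co$expression$values[, names(co$truth_labels)],
                        sample_k_range = 2:6, gene_k_range = 2,
                        genes = sig, signature_genes = co$gene_sets$oxphos$genes,
                        n_resamples = 60, seed = 2)
  expect_gte(ari(tw$sample_labels, co$truth_labels), 0.9)
  block <- co$gene_table$block[match(names(tw$gene_labels), co$gene_table$gene)]
  expect_gte(ari(tw$gene_labels, block), 0.9) # exact two-block recovery at k = 2
  # cluster 1 = highest mean signature expression
  sigz <- colMeans(tw$z[co$gene_sets$oxphos$genes, ])
  means <- tapply(sigz, tw$sample_labels, mean)
  expect_equal(order(-means), seq_along(means))
})

test_that("transposing a preprocessed matrix swaps the two partitions", {
  p <- planted_points(n_per = 7, k = 2, n_features = 30, sep = 4, seed = 9)
  z <- t(p$x) # features x items, pretend genes x samples
  tw1 <- two_way_cluster(z, sample_k_range = 2:3, gene_k_range = 2:3,
                         preprocess = FALSE, n_resamples = 10,
                         subsample_fraction = 1, seed = 1)
  tw2 <- two_way_cluster(t(z), sample_k_range = 2:3, gene_k_range = 2:3,
                         preprocess = FALSE, n_resamples = 10,
                         subsample_fraction = 1, seed = 1)
  expect_equal(ari(tw1$sample_labels, tw2$gene_labels), 1)
  expect_equal(ari(tw1$gene_labels, tw2$sample_labels), 1)
})
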