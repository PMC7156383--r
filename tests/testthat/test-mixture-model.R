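test_that("expected mixture fold changes follow the linear admixture formula", {
  prof <- data.frame(gene = c("same", "up", "down"),
                     tumor_mean = c(5, 1, 8),
                     tcell_mean = c(5, 3, 2))
  # tcell == tumor: 1.0 for any f
  expect_equal(unname(expected_mixture_fc(prof, 0.3)["same"]), 1)
  # f = 0: 1.0 everywhere
  expect_equal(unname(expected_mixture_fc(prof, 0)), rep(1, 3))
  # arithmetic case without pseudocount
  expect_equal(unname(expected_mixture_fc(prof, 0.5, pseudocount = 0)["up"]), 2)
  expect_error(expected_mixture_fc(prof, 1.4), "0, 1")
})

test_that("expected fold change is monotone in f with the sign of the cell contrast", {
  prof <- data.frame(gene = c("up", "down"), tumor_mean = c(2, 9), tcell_mean = c(10, 1))
  fs <- seq(0, 1, by = 0.1)
  fcs <- sapply(fs, function(f) expected_mixture_fc(prof, f))
  expect_true(all(diff(fcs["up", ]) > 0))
  expect_true(all(diff(fcs["down", ]) < 0))
})

test_that("explainability follows the enumerated sign-grid truth table", {
  # exhaustive {-1, 0, +1}^2 grid in log2 units (x = observed, y = expected)
  grid <- expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1))
  expected_class <- c(
    # x = -1, 0, 1 for each y
    "potentially_explainable", "potentially_explainable", "not_explainable",   # y = -1
    "not_explainable", "potentially_explainable", "not_explainable",           # y = 0
    "not_explainable", "potentially_explainable", "potentially_explainable"    # y = 1
  )
  res <- classify_explainability(2^grid$y, 2^grid$x)
  expect_equal(res$class, expected_class)

  # identity line is explainable (conservative toward contamination)
  on_line <- classify_explainability(c(2, 0.5), c(2, 0.5))
  expect_equal(unique(on_line$class), "potentially_explainable")

  # observed change with expected no-change is never explainable
  res2 <- classify_explainability(1, 2)
  expect_equal(res2$class, "not_explainable")
  expect_error(classify_explainability(c(1, -1), c(1, 1)), "positive")
})

test_that("classification is invariant to rescaling all expression", {
  set.seed(4)
  prof <- data.frame(gene = sprintf("G%02d", 1:30),
                     tumor_mean = 2^runif(30, 2, 8),
                     tcell_mean = 2^runif(30, 2, 8))
  x1 <- generate_pseudobulk_mixture(prof, 0.5, 40, noise_sd = 0.1, seed = 3)
  x2 <- generate_pseudobulk_mixture(prof, 0, 40, noise_sd = 0.1, seed = 4)
  m <- cbind(x1$values, x2$values)
  colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  labels <- stats::setNames(rep(c(1, 2), each = 40), colnames(m))
  r1 <- mixture_report(m, labels, prof, f = 0.5, pseudocount = 1e-6)
  big <- mixture_report(m * 64, labels,
                        transform(prof, tumor_mean = tumor_mean * 64,
                                  tcell_mean = tcell_mean * 64),
                        f = 0.5, pseudocount = 1e-6)
  expect_equal(r1$per_gene$class, big$per_gene$class)
})

test_that("cytotoxic subset recovery from annotated single cells", {
  # two T-cell subpopulations: planted cytotoxic markers high in one
  set.seed(6)
  genes <- c(sprintf("CYT%02d", 1:6), sprintf("TRG%02d", 1:6), sprintf("BGD%02d", 1:20))
  base <- runif(length(genes), 4, 8)
  n_tumor <- 20
  n_cyt <- 15
  n_other <- 15
  mk <- function(n, cyt_shift, trg_shift) {
    sapply(seq_len(n), function(i) {
      shift <- ifelse(grepl("^CYT", genes), cyt_shift,
                      ifelse(grepl("^TRG", genes), trg_shift, 0))
      2^(base + shift + rnorm(length(genes), 0, 0.4))
    })
  }
  sc <- cbind(mk(n_tumor, 0, 0), mk(n_cyt, 3, -1), mk(n_other, -1, 3))
  rownames(sc) <- genes
  colnames(sc) <- sprintf("CELL%03d", seq_len(ncol(sc)))
  ann <- stats::setNames(rep(c("tumor", "t_cell"), c(n_tumor, n_cyt + n_other)),
                         colnames(sc))
  sets <- list(cytotoxic = gene_set("cytotoxic", grep("^CYT", genes, value = TRUE)),
               treg = gene_set("treg", grep("^TRG", genes, value = TRUE)))
  prof <- cell_profiles_from_annotated_sc(sc, ann, sets, k_range = 2:3,
                                          n_resamples = 40, seed = 2)
  truth <- rep(c(1, 2), c(n_cyt, n_other))
  expect_gte(ari(attr(prof, "tcell_subcluster"), truth), 0.9)
  expect_equal(attr(prof, "n_cytotoxic_cells"), n_cyt)
  expect_equal(prof$tumor_mean, rowMeans(sc[, 1:n_tumor]), ignore_attr = TRUE)
  expect_equal(prof$tcell_mean,
               rowMeans(sc[, n_tumor + seq_len(n_cyt)]), ignore_attr = TRUE)

  # single T-cell: subclustering skipped with a flag
  expect_warning(
    single <- cell_profiles_from_annotated_sc(sc[, 1:(n_tumor + 1)],
                                              ann[1:(n_tumor + 1)], sets),
    "skipped"
  )
  expect_true(attr(single, "subclustering_skipped"))
})

test_that("pure-contamination cohorts are explainable; intrinsic shifts are not", {
  set.seed(10)
  prof <- data.frame(
    gene = sprintf("G%03d", 1:80),
    tumor_mean = 2^runif(80, 3, 9),
    tcell_mean = 2^(runif(80, 3, 9))
  )
  contaminated <- generate_pseudobulk_mixture(prof, 0.5, 150, noise_sd = 0.2, seed = 11)
  clean <- generate_pseudobulk_mixture(prof, 0, 150, noise_sd = 0.2, seed = 12,
                                       prefix = "CLN")
  m <- cbind(contaminated$values, clean$values)
  labels <- stats::setNames(rep(c(1, 2), each = 150), colnames(m))
  rep_mix <- mixture_report(m, labels, prof, f = 0.5)
  frac_expl <- mean(rep_mix$per_gene$class == "potentially_explainable")
  expect_gte(frac_expl, 0.95)

  # f = 0 given to the model: every really-changed gene is not explainable
  rep0 <- mixture_report(m, labels, prof, f = 0)
  changed <- abs(log2(rep0$per_gene$observed_fc)) > log2(1.3)
  expect_true(all(rep0$per_gene$class[changed] == "not_explainable"))
})
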