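#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated tumor cohort: planted
#' expression clusters that differ in an oxidative-phosphorylation-like and a
#' glycolysis-like gene block, exponential survival whose hazard may be a
#' non-monotone (threshold) function of cluster, immune-subset marker signals
#' declining across clusters, a muscle-contaminated sample subset, matched
#' normal samples, mitochondrial copy numbers trending with cluster, annotated
#' mutation tables, and per-cell-type mean profiles for the contamination
#' mixture model.
#'
#' Defaults describe a cohort with four well-separated clusters of 50 tumors
#' each; cluster 1 has the highest oxidative-phosphorylation block and reduced
#' glycolysis block, and the best (lowest-hazard) survival, while the
#' adjacent cluster 2 has the worst, mirroring the threshold relationship the
#' pipeline is designed to detect.
#'
#' @param n_tumor number of tumor samples (assigned to clusters in balanced
#'   fashion).
#' @param n_normal number of matched normal samples.
#' @param k_true planted number of tumor clusters (>= 2).
#' @param genes_per_block named integer vector with elements `oxphos`,
#'   `glycolysis`, `background`.
#' @param block_shift list with per-cluster mean log2 shift vectors `oxphos`,
#'   `glycolysis`, `background` (each length `k_true`; `background` may be a
#'   single 0).
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param hazard_by_cluster per-cluster exponential hazard (per month, > 0);
#'   non-monotone vectors are allowed and are the interesting case.
#' @param censoring_rate target expected fraction of censored subjects;
#'   censoring times are Uniform(0, T_max) with T_max solved from this rate.
#' @param immune_gradient per-cluster mean log2 shift applied to cytotoxic and
#'   CD8 marker genes (Treg markers stay flat).
#' @param muscle_fraction_range range of the skeletal-muscle mixing fraction
#'   applied to the contaminated sample subset.
#' @param muscle_sample_prop proportion of tumor samples receiving muscle
#'   contamination.
#' @param mtdna_mean_by_cluster per-cluster mean mitochondrial copy number.
#' @param mtdna_sd standard deviation of mitochondrial copy number.
#' @param contamination_fraction assumed cytotoxic T-cell fraction `f` used by
#'   downstream mixture modelling (in `[0, 1]`).
#' @param mutation_rate_by_gene named per-gene baseline mutation probability.
#' @param enriched_mutation list(gene=, cluster=, rate=) planting one
#'   cluster-associated mutation; `NULL` for none.
#' @param master_seed integer; every random component derives its stream from
#'   this seed by fixed offsets.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 200,
                          n_normal = 20,
                          k_true = 4,
                          genes_per_block = c(oxphos = 50, glycolysis = 50, background = 100),
                          block_shift = list(
                            oxphos = c(3.2, 1.6, 0, -1.6),
                            glycolysis = c(-2, 1.6, 0.4, -0.4),
                            background = 0
                          ),
                          noise_sd = 0.8,
                          hazard_by_cluster = c(0.005, 0.03, 0.015, 0.01),
                          censoring_rate = 0.3,
                          immune_gradient = c(1.5, 0.5, -0.5, -1.5),
                          muscle_fraction_range = c(0, 0.4),
                          muscle_sample_prop = 0.15,
                          mtdna_mean_by_cluster = c(800, 550, 420, 300),
                          mtdna_sd = 80,
                          contamination_fraction = 0.5,
                          mutation_rate_by_gene = stats::setNames(rep(0.08, 8), paste0("MUT", 1:8)),
                          enriched_mutation = list(gene = "MUT1", cluster = 1, rate = 0.4),
                          master_seed = 1) {
  cfg <- list(
    n_tumor = n_tumor, n_normal = n_normal, k_true = k_true,
    genes_per_block = genes_per_block, block_shift = block_shift,
    noise_sd = noise_sd, hazard_by_cluster = hazard_by_cluster,
    censoring_rate = censoring_rate, immune_gradient = immune_gradient,
    muscle_fraction_range = muscle_fraction_range,
    muscle_sample_prop = muscle_sample_prop,
    mtdna_mean_by_cluster = mtdna_mean_by_cluster, mtdna_sd = mtdna_sd,
    contamination_fraction = contamination_fraction,
    mutation_rate_by_gene = mutation_rate_by_gene,
    enriched_mutation = enriched_mutation,
    master_seed = master_seed
  )
  if (k_true < 2) stop_fmt("k_true must be >= 2")
  if (!all(c("oxphos", "glycolysis", "background") %in% names(genes_per_block))) {
    stop_fmt("genes_per_block needs oxphos, glycolysis and background entries")
  }
  for (b in c("oxphos", "glycolysis", "background")) {
    s <- block_shift[[b]]
    if (is.null(s)) stop_fmt("block_shift lacks '%s'", b)
    if (!length(s) %in% c(1L, k_true)) {
      stop_fmt("block_shift$%s must have length 1 or k_true = %d", b, k_true)
    }
    if (any(!is.finite(s))) stop_fmt("block_shift$%s must be finite", b)
    cfg$block_shift[[b]] <- rep_len(s, k_true)
  }
  if (length(hazard_by_cluster) != k_true || any(hazard_by_cluster <= 0)) {
    stop_fmt("hazard_by_cluster must have length k_true with all hazards > 0")
  }
  if (length(immune_gradient) != k_true) stop_fmt("immune_gradient must have length k_true")
  if (length(mtdna_mean_by_cluster) != k_true) {
    stop_fmt("mtdna_mean_by_cluster must have length k_true")
  }
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    stop_fmt("contamination_fraction must be in [0, 1]")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) stop_fmt("censoring_rate must be in [0, 1)")
  structure(cfg, class = "cohort_config")
}

# Gene universe implied by a config: the two signature blocks, background,
# immune subset markers (8 genes each), and a skeletal-muscle panel.
cohort_gene_table <- function(config) {
  g <- config$genes_per_block
  data.frame(
    gene = c(
      sprintf("OXP%03d", seq_len(g[["oxphos"]])),
      sprintf("GLY%03d", seq_len(g[["glycolysis"]])),
      sprintf("BGD%03d", seq_len(g[["background"]])),
      sprintf("CYT%02d", 1:8), sprintf("CD8G%02d", 1:8), sprintf("TRG%02d", 1:8),
      sprintf("MUS%02d", 1:12)
    ),
    block = c(
      rep("oxphos", g[["oxphos"]]),
      rep("glycolysis", g[["glycolysis"]]),
      rep("background", g[["background"]]),
      rep("cytotoxic", 8), rep("cd8", 8), rep("treg", 8),
      rep("muscle", 12)
    ),
    stringsAsFactors = FALSE
  )
}

# T_max of Uniform(0, T_max) censoring such that the expected censored
# fraction over the cohort's hazard mixture equals `rate`.
censoring_tmax <- function(hazards, rate) {
  if (rate <= 0) return(Inf)
  frac_censored <- function(tmax) {
    mean((1 - exp(-hazards * tmax)) / (hazards * tmax)) - rate
  }
  stats::uniroot(frac_censored, lower = 1e-6, upper = 1e6, tol = 1e-8)$root
}

#' Generate a synthetic cohort with known ground truth
#'
#' Expression is generated on the log2 scale as
#' `baseline + block_shift[cluster] + Normal(0, noise_sd)` and mapped to the
#' linear scale as `2^value - 1`, clipped at zero. Survival times are
#' exponential with the per-cluster hazard, censored by an independent
#' Uniform(0, T_max) time calibrated to the configured censoring rate.
#' All random streams derive from `master_seed` by fixed offsets, so the
#' same configuration always reproduces the same cohort.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `expression`
#'   ([expr_matrix()], tumors then normals), `truth_labels` (named integer
#'   vector over tumor samples), `clinical` (data.frame), `immune_truth`
#'   (named numeric), `mtdna` (named numeric), `mutations`
#'   (`mutation_table`), `cell_profiles` (data.frame gene/tumor_mean/
#'   tcell_mean), `gene_sets` (gene blocks and marker panels as a
#'   `gene_set_collection`), `gene_table`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$master_seed
  gt <- cohort_gene_table(config)
  n_genes <- nrow(gt)
  k <- config$k_true
  labels <- sort(rep_len(seq_len(k), config$n_tumor))
  tumor_ids <- sprintf("TUMOR%04d", seq_len(config$n_tumor))
  normal_ids <- if (config$n_normal > 0) sprintf("NORMAL%03d", seq_len(config$n_normal)) else character(0)
  names(labels) <- tumor_ids

  baseline <- with_seed(child_seed(seed, 1), stats::runif(n_genes, 3, 9))
  names(baseline) <- gt$gene

  immune_truth <- with_seed(
    child_seed(seed, 2),
    config$immune_gradient[labels] + stats::rnorm(config$n_tumor, 0, 0.3)
  )
  names(immune_truth) <- tumor_ids

  shift_for <- function(cluster) {
    s <- numeric(n_genes)
    s[gt$block == "oxphos"] <- config$block_shift$oxphos[cluster]
    s[gt$block == "glycolysis"] <- config$block_shift$glycolysis[cluster]
    s[gt$block == "background"] <- config$block_shift$background[cluster]
    s
  }

  log2_expr <- with_seed(child_seed(seed, 3), {
    m <- matrix(stats::rnorm(n_genes * (config$n_tumor + config$n_normal), 0, config$noise_sd),
                nrow = n_genes)
    for (i in seq_len(config$n_tumor)) {
      m[, i] <- m[, i] + baseline + shift_for(labels[i])
      imm <- gt$block %in% c("cytotoxic", "cd8")
      m[imm, i] <- m[imm, i] + immune_truth[i]
    }
    if (config$n_normal > 0) {
      for (j in seq_len(config$n_normal)) {
        m[, config$n_tumor + j] <- m[, config$n_tumor + j] + baseline
      }
    }
    m
  })
  values <- pmax(2^log2_expr - 1, 0)
  dimnames(values) <- list(gt$gene, c(tumor_ids, normal_ids))

  # skeletal-muscle contamination: linear mixing of a muscle tissue profile
  # into a random subset of tumor samples
  muscle_profile <- 2^(baseline + ifelse(gt$block == "muscle", 6, 0)) - 1
  n_muscle <- round(config$muscle_sample_prop * config$n_tumor)
  muscle_truth <- stats::setNames(numeric(config$n_tumor), tumor_ids)
  if (n_muscle > 0) {
    with_seed(child_seed(seed, 4), {
      contaminated <- sample(tumor_ids, n_muscle)
      fr <- stats::runif(n_muscle, config$muscle_fraction_range[1], config$muscle_fraction_range[2])
      muscle_truth[contaminated] <- fr
      for (ii in seq_along(contaminated)) {
        s <- contaminated[ii]
        values[, s] <- (1 - fr[ii]) * values[, s] + fr[ii] * muscle_profile
      }
    })
  }

  sample_meta <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    tissue_class = c(rep("tumor", config$n_tumor), rep("normal", config$n_normal)),
    cohort = "synthetic",
    stringsAsFactors = FALSE
  )

  clinical <- with_seed(child_seed(seed, 5), {
    hz <- config$hazard_by_cluster[labels]
    death <- stats::rexp(config$n_tumor, rate = hz)
    tmax <- censoring_tmax(hz, config$censoring_rate)
    cens <- if (is.finite(tmax)) stats::runif(config$n_tumor, 0, tmax) else rep(Inf, config$n_tumor)
    data.frame(
      sample_id = tumor_ids,
      os_time = pmin(death, cens),
      os_event = as.integer(death <= cens),
      race = sample(c("groupA", "groupB"), config$n_tumor, replace = TRUE, prob = c(0.7, 0.3)),
      tp53_status = sample(c("mutant", "wildtype"), config$n_tumor, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })

  mtdna <- with_seed(
    child_seed(seed, 6),
    pmax(config$mtdna_mean_by_cluster[labels] + stats::rnorm(config$n_tumor, 0, config$mtdna_sd), 1)
  )
  names(mtdna) <- tumor_ids

  mutations <- with_seed(child_seed(seed, 7), {
    rows <- list()
    for (g in names(config$mutation_rate_by_gene)) {
      p <- rep(config$mutation_rate_by_gene[[g]], config$n_tumor)
      em <- config$enriched_mutation
      if (!is.null(em) && identical(em$gene, g)) p[labels == em$cluster] <- em$rate
      hit <- stats::runif(config$n_tumor) < p
      if (!any(hit)) next
      n_hit <- sum(hit)
      impactful <- stats::runif(n_hit) < 0.5
      sift <- ifelse(impactful & stats::runif(n_hit) < 0.7, "deleterious",
                     sample(c("tolerated", "missing"), n_hit, replace = TRUE, prob = c(0.8, 0.2)))
      polyphen <- ifelse(impactful & sift != "deleterious",
                         sample(c("probably_damaging", "possibly_damaging"), n_hit, replace = TRUE),
                         sample(c("benign", "missing"), n_hit, replace = TRUE, prob = c(0.8, 0.2)))
      rows[[g]] <- data.frame(
        gene = g, sample_id = tumor_ids[hit],
        variant_classification = "Missense_Mutation",
        sift_label = sift, polyphen_label = polyphen,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(gene = character(0), sample_id = character(0),
                        variant_classification = character(0),
                        sift_label = character(0), polyphen_label = character(0),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    class(out) <- c("mutation_table", "data.frame")
    out
  })

  # per-cell-type mean profiles for the contamination mixture model:
  # cytotoxic T-cells are high on immune markers, modestly lower on the
  # metabolic blocks, identical elsewhere
  tcell_shift <- numeric(n_genes)
  tcell_shift[gt$block %in% c("cytotoxic", "cd8")] <- 4
  tcell_shift[gt$block == "treg"] <- 0
  tcell_shift[gt$block == "oxphos"] <- -1
  tcell_shift[gt$block == "glycolysis"] <- -0.5
  cell_profiles <- data.frame(
    gene = gt$gene,
    tumor_mean = 2^baseline,
    tcell_mean = 2^(baseline + tcell_shift),
    stringsAsFactors = FALSE
  )

  gene_sets <- structure(list(
    oxphos = gene_set("oxphos", gt$gene[gt$block == "oxphos"], "oxphos"),
    glycolysis = gene_set("glycolysis", gt$gene[gt$block == "glycolysis"], "glycolysis"),
    cytotoxic = gene_set("cytotoxic", gt$gene[gt$block == "cytotoxic"], "immune"),
    cd8 = gene_set("cd8", gt$gene[gt$block == "cd8"], "immune"),
    treg = gene_set("treg", gt$gene[gt$block == "treg"], "immune"),
    muscle = gene_set("muscle", gt$gene[gt$block == "muscle"], "muscle")
  ), class = "gene_set_collection")

  structure(list(
    expression = expr_matrix(values, sample_meta),
    truth_labels = labels,
    clinical = clinical,
    immune_truth = immune_truth,
    muscle_truth = muscle_truth,
    mtdna = mtdna,
    mutations = mutations,
    cell_profiles = cell_profiles,
    gene_sets = gene_sets,
    gene_table = gt,
    config = config
  ), class = "synthetic_cohort")
}

#' Generate pseudobulk samples as tumor/T-cell mixtures
#'
#' Each sample's per-gene expectation is the linear mixture
#' `f * tcell_mean + (1 - f) * tumor_mean`, multiplied by log-normal noise
#' (log2-scale standard deviation `noise_sd`, mean-corrected so the
#' arithmetic per-gene expectation equals the mixture exactly).
#'
#' @param cell_profiles data.frame with columns `gene`, `tumor_mean`,
#'   `tcell_mean` (linear scale).
#' @param f cytotoxic T-cell fraction in `[0, 1]`.
#' @param n_samples number of pseudobulk samples.
#' @param noise_sd log2-scale noise standard deviation.
#' @param seed integer seed.
#' @param prefix sample id prefix.
#' @return an [expr_matrix()] of `n_samples` pseudobulk profiles.
#' @export
generate_pseudobulk_mixture <- function(cell_profiles, f, n_samples,
                                        noise_sd = 0.2, seed = 1,
                                        prefix = "MIX") {
  if (f < 0 || f > 1) stop_fmt("f must be in [0, 1]")
  mix <- f * cell_profiles$tcell_mean + (1 - f) * cell_profiles$tumor_mean
  n_genes <- length(mix)
  vals <- with_seed(seed, {
    eps <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), nrow = n_genes)
    # divide by E[2^eps] so arithmetic means are unbiased for the mixture
    mix * 2^eps / exp((noise_sd * log(2))^2 / 2)
  })
  dimnames(vals) <- list(cell_profiles$gene, sprintf("%s%04d", prefix, seq_len(n_samples)))
  expr_matrix(vals)
}

#' Write a synthetic cohort to standard pipeline files
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    mutations = file.path(dir, "mutations.maf.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    cell_profiles = file.path(dir, "cell_profiles.tsv"),
    mtdna = file.path(dir, "mtdna.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_tsv(cohort$expression, paths[["expression"]])
  utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_maf(cohort$mutations, paths[["mutations"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  utils::write.table(cohort$cell_profiles, paths[["cell_profiles"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$mtdna), mtdna = cohort$mtdna),
    paths[["mtdna"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(
      sample_id = names(cohort$truth_labels),
      cluster = cohort$truth_labels,
      immune_truth = cohort$immune_truth[names(cohort$truth_labels)],
      muscle_fraction = cohort$muscle_truth[names(cohort$truth_labels)]
    ),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
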