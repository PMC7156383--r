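# Recognized configuration keys and their defaults. validate_config() rejects
# anything else so typos never silently fall back to defaults.
pipeline_defaults <- function() {
  list(
    # input files; when expression is NULL the synthetic generator runs
    expression = NULL,
    clinical = NULL,
    mutations = NULL,
    gene_sets = NULL,
    cell_profiles = NULL,
    mtdna = NULL,
    # simulation
    simulate = TRUE,
    n_tumor = 200,
    n_normal = 20,
    k_true = 4,
    # clustering
    sample_k_min = 2,
    sample_k_max = 8,
    gene_k_min = 2,
    gene_k_max = 4,
    resamples = 250,
    fraction = 0.8,
    linkage = "average",
    # scoring
    alpha = 0.75,
    normalize_scores = FALSE,
    # statistics
    fdr_de = 0.05,
    fdr_mutation = 0.01,
    fold_threshold = 1.4,
    # mixture model
    contamination_fraction = 0.5,
    # survival
    reference_cluster = 1,
    # reproducibility / output
    master_seed = 1,
    output_dir = "metabostrat_out"
  )
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML key-value configuration, rejects unknown keys (so typos are
#' errors, never silently ignored defaults), fills in documented defaults,
#' and validates ranges and referenced files.
#'
#' @param path YAML file path, or a named list of settings.
#' @return fully resolved list of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  supplied <- if (is.character(path)) {
    if (!file.exists(path)) stop_fmt("config file not found: %s", path)
    yaml::read_yaml(path)
  } else {
    as.list(path)
  }
  if (is.null(supplied)) supplied <- list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, supplied)
  for (key in c("fdr_de", "fdr_mutation")) {
    if (cfg[[key]] <= 0 || cfg[[key]] >= 1) stop_fmt("%s must be in (0, 1)", key)
  }
  if (cfg$fraction <= 0 || cfg$fraction > 1) stop_fmt("fraction must be in (0, 1]")
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction > 1) {
    stop_fmt("contamination_fraction must be in [0, 1]")
  }
  if (cfg$sample_k_min < 2 || cfg$sample_k_max < cfg$sample_k_min) {
    stop_fmt("invalid sample k range")
  }
  for (key in c("expression", "clinical", "mutations", "gene_sets",
                "cell_profiles", "mtdna")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_fmt("configured %s file does not exist: %s", key, cfg[[key]])
    }
  }
  if (is.null(cfg$expression)) cfg$simulate <- TRUE
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, manifest_env, expr) {
  result <- tryCatch(expr, error = function(e) {
    stop_fmt("stage '%s' failed: %s", name, conditionMessage(e))
  })
  manifest_env$stages <- c(manifest_env$stages, name)
  result
}

record_output <- function(manifest_env, name, path) {
  manifest_env$outputs[[name]] <- list(
    path = path,
    md5 = unname(tools::md5sum(path))
  )
  path
}

#' Run the full stratification pipeline
#'
#' Sequences simulation (or file loading), preprocessing, two-way consensus
#' clustering, ssGSEA scoring, survival stratification, differential
#' expression, mutation association, the genome-wide correlation screen and
#' the contamination mixture model, writing every intermediate artifact as
#' TSV plus a JSON manifest with parameters, seeds and file checksums.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' @param config a [validate_config()] result, a path to a YAML config, or a
#'   named list of settings.
#' @param output_dir overrides the configured output directory.
#' @return the manifest (list), invisibly; written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$stages <- character(0)
  env$outputs <- list()

  # --- inputs ---------------------------------------------------------------
  cohort <- NULL
  if (config$simulate || is.null(config$expression)) {
    cohort <- run_stage("simulate", env, {
      cc <- cohort_config(n_tumor = config$n_tumor, n_normal = config$n_normal,
                          k_true = config$k_true,
                          contamination_fraction = config$contamination_fraction,
                          master_seed = child_seed(config$master_seed, 1))
      co <- generate_cohort(cc)
      paths <- write_cohort(co, file.path(out, "cohort"))
      for (nm in names(paths)) record_output(env, paste0("cohort_", nm), paths[[nm]])
      co
    })
    expression <- cohort$expression
    clinical <- cohort$clinical
    mutations <- cohort$mutations
    sets <- cohort$gene_sets
    profiles <- cohort$cell_profiles
    mtdna <- cohort$mtdna
  } else {
    loaded <- run_stage("load", env, {
      list(
        expression = read_expression_tsv(config$expression),
        clinical = if (!is.null(config$clinical)) read_clinical_tsv(config$clinical),
        mutations = if (!is.null(config$mutations)) read_maf(config$mutations),
        sets = if (!is.null(config$gene_sets)) read_gmt(config$gene_sets),
        profiles = if (!is.null(config$cell_profiles)) {
          utils::read.delim(config$cell_profiles, stringsAsFactors = FALSE)
        },
        mtdna = if (!is.null(config$mtdna)) {
          m <- utils::read.delim(config$mtdna, stringsAsFactors = FALSE)
          stats::setNames(m[[2]], m[[1]])
        }
      )
    })
    expression <- loaded$expression
    clinical <- loaded$clinical
    mutations <- loaded$mutations
    sets <- loaded$sets
    profiles <- loaded$profiles
    mtdna <- loaded$mtdna
  }

  signature_genes <- if (!is.null(sets)) {
    unique(c(sets[["oxphos"]]$genes, sets[["glycolysis"]]$genes))
  } else {
    rownames(as_values(expression))
  }
  tumor_ids <- expression$sample_meta$sample_id[expression$sample_meta$tissue_class == "tumor"]
  tumor_expr <- as_values(expression)[, tumor_ids, drop = FALSE]

  # --- clustering -----------------------------------------------------------
  clustering <- run_stage("cluster", env, {
    tw <- two_way_cluster(
      tumor_expr,
      sample_k_range = config$sample_k_min:config$sample_k_max,
      gene_k_range = config$gene_k_min:config$gene_k_max,
      genes = signature_genes,
      signature_genes = if (!is.null(sets)) sets[["oxphos"]]$genes else NULL,
      n_resamples = config$resamples,
      subsample_fraction = config$fraction,
      seed = child_seed(config$master_seed, 2),
      linkage = config$linkage
    )
    labs <- data.frame(sample_id = names(tw$sample_labels),
                       cluster = unname(tw$sample_labels))
    utils::write.table(labs, file.path(out, "sample_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record_output(env, "sample_clusters", file.path(out, "sample_clusters.tsv"))
    utils::write.table(tw$sample_result$ned_table, file.path(out, "ned_by_k.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record_output(env, "ned_by_k", file.path(out, "ned_by_k.tsv"))
    ordered <- tw$z[tw$gene_order, tw$sample_order]
    write_expression_tsv(ordered, file.path(out, "ordered_matrix.tsv"))
    record_output(env, "ordered_matrix", file.path(out, "ordered_matrix.tsv"))
    tw
  })
  labels <- clustering$sample_labels

  # --- scoring --------------------------------------------------------------
  scores <- run_stage("score", env, {
    s <- ssgsea_table(tumor_expr, sets, alpha = config$alpha,
                      normalize = config$normalize_scores)
    tab <- data.frame(sample_id = rownames(s), s, check.names = FALSE)
    utils::write.table(tab, file.path(out, "ssgsea_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record_output(env, "ssgsea_scores", file.path(out, "ssgsea_scores.tsv"))
    s
  })
  if (all(c("cytotoxic", "treg") %in% colnames(scores))) {
    run_stage("combined_scores", env, {
      comb <- data.frame(
        sample_id = rownames(scores),
        cytotoxic_minus_treg = combined_subtractive_score(scores, "cytotoxic", "treg"),
        cd8_minus_treg = if ("cd8" %in% colnames(scores)) {
          combined_subtractive_score(scores, "cd8", "treg")
        } else {
          NA_real_
        }
      )
      utils::write.table(comb, file.path(out, "combined_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "combined_scores", file.path(out, "combined_scores.tsv"))
    })
  }

  # --- survival -------------------------------------------------------------
  if (!is.null(clinical)) {
    run_stage("survival", env, {
      rep <- cluster_survival_report(clinical, labels,
                                     reference_cluster = config$reference_cluster)
      utils::write.table(rep$medians, file.path(out, "survival_medians.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "survival_medians", file.path(out, "survival_medians.tsv"))
      if (!is.null(rep$pairwise)) {
        utils::write.table(rep$pairwise, file.path(out, "survival_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        record_output(env, "survival_tests", file.path(out, "survival_tests.tsv"))
      }
      rep
    })
  }

  # --- differential expression ---------------------------------------------
  de <- NULL
  if (all(c(1, 2) %in% labels)) {
    de <- run_stage("de", env, {
      d <- welch_tests_by_gene(tumor_expr[signature_genes, , drop = FALSE],
                               labels, 1, 2, fdr = config$fdr_de)
      fold <- gm_ratio_annotation(tumor_expr[signature_genes, , drop = FALSE],
                                  labels, 1, 2,
                                  fold_threshold = config$fold_threshold)
      d$gm_ratio <- fold$ratio[match(d$gene, fold$gene)]
      d$fold_class <- fold$class[match(d$gene, fold$gene)]
      utils::write.table(d, file.path(out, "differential_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "differential_expression",
                    file.path(out, "differential_expression.tsv"))
      d
    })
  }

  # --- mutation association -------------------------------------------------
  if (!is.null(mutations) && nrow(mutations) > 0) {
    run_stage("assoc", env, {
      imp <- impactful_filter(mutations)
      assoc <- mutation_cluster_association(imp, labels,
                                            fdr = config$fdr_mutation,
                                            reference_cluster = config$reference_cluster)
      utils::write.table(assoc, file.path(out, "mutation_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "mutation_association",
                    file.path(out, "mutation_association.tsv"))
      assoc
    })
  }

  # --- correlation screen ---------------------------------------------------
  if (!is.null(sets) && "oxphos" %in% names(sets)) {
    run_stage("correlate", env, {
      oxscore <- ssgsea_table(tumor_expr, sets["oxphos"], alpha = config$alpha)[, 1]
      screen <- correlate_genes_with_score(tumor_expr, oxscore)
      utils::write.table(screen, file.path(out, "correlation_screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "correlation_screen",
                    file.path(out, "correlation_screen.tsv"))
    })
  }

  # --- mitochondrial copy number trend --------------------------------------
  if (!is.null(mtdna)) {
    run_stage("mtdna_trend", env, {
      cov <- covariate_by_cluster(mtdna, labels)
      utils::write.table(cov$cluster_summary, file.path(out, "mtdna_by_cluster.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "mtdna_by_cluster", file.path(out, "mtdna_by_cluster.tsv"))
      cov
    })
  }

  # --- contamination mixture model ------------------------------------------
  if (!is.null(profiles)) {
    run_stage("mixture", env, {
      mix <- mixture_report(tumor_expr[signature_genes, , drop = FALSE],
                            labels, profiles,
                            f = config$contamination_fraction,
                            de_result = de)
      utils::write.table(mix$per_gene, file.path(out, "mixture_model.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record_output(env, "mixture_model", file.path(out, "mixture_model.tsv"))
      mix
    })
  }

  manifest <- list(
    package = "metabostrat",
    version = as.character(utils::packageVersion("metabostrat")),
    master_seed = config$master_seed,
    parameters = unclass(config),
    stages = env$stages,
    outputs = env$outputs
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
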