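#' Expression matrix container
#'
#' A light container for a linear-scale (RSEM-like), non-negative
#' gene-by-sample expression matrix together with per-sample annotations.
#'
#' @param values numeric gene x sample matrix with unique rownames (gene
#'   symbols) and colnames (sample identifiers); all values finite and >= 0.
#' @param sample_meta optional data.frame with one row per sample and columns
#'   `tissue_class` (`"tumor"` or `"normal"`) and `cohort`. Defaults to all
#'   tumor, cohort `"cohort1"`.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `sample_meta`.
#' @export
expr_matrix <- function(values, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_fmt("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fmt("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_fmt("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop_fmt("duplicate sample identifiers")
  if (any(!is.finite(values))) stop_fmt("expression values must be finite")
  if (any(values < 0)) stop_fmt("expression values must be non-negative")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(
      sample_id = colnames(values),
      tissue_class = "tumor",
      cohort = "cohort1",
      stringsAsFactors = FALSE
    )
  }
  if (!all(colnames(values) %in% sample_meta$sample_id)) {
    stop_fmt("sample_meta must cover every sample")
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  bad <- setdiff(unique(sample_meta$tissue_class), c("tumor", "normal"))
  if (length(bad)) stop_fmt("unknown tissue_class: %s", paste(bad, collapse = ", "))
  structure(list(values = values, sample_meta = sample_meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d genes x %d samples (%d tumor, %d normal)\n",
    nrow(x$values), ncol(x$values),
    sum(x$sample_meta$tissue_class == "tumor"),
    sum(x$sample_meta$tissue_class == "normal")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Accept either an expr_matrix or a plain numeric matrix.
as_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values else x
}

#' Read a gene-by-sample expression TSV
#'
#' Reads a tab-separated expression table whose first column holds gene
#' symbols and whose header row holds sample identifiers. Duplicate gene rows
#' are collapsed to a single row by the per-sample maximum (conservative for
#' rank-based enrichment scoring); pass `duplicate_rule = "error"` to forbid
#' duplicates instead.
#'
#' @param path file path.
#' @param orientation `"genes_by_samples"` (default on-disk dialect) or
#'   `"samples_by_genes"` for transposed files.
#' @param duplicate_rule `"max"` or `"error"`.
#' @param sample_meta optional annotation data.frame passed to [expr_matrix()].
#' @return an [expr_matrix()].
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_by_samples", "samples_by_genes"),
                                duplicate_rule = c("max", "error"),
                                sample_meta = NULL) {
  orientation <- match.arg(orientation)
  duplicate_rule <- match.arg(duplicate_rule)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fmt("malformed expression file %s: need id column plus data", path)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop_fmt("malformed expression file %s: non-numeric values", path)
  rownames(mat) <- ids
  if (orientation == "samples_by_genes") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) {
    if (duplicate_rule == "error") stop_fmt("duplicate gene rows in %s", path)
    warn_fmt(
      "%d duplicated gene symbols in %s collapsed by per-sample maximum",
      sum(duplicated(rownames(mat))), path
    )
    mat <- do.call(rbind, lapply(split(seq_len(nrow(mat)), rownames(mat)), function(i) {
      apply(mat[i, , drop = FALSE], 2, max)
    }))
  }
  if (any(mat < 0)) stop_fmt("negative expression values in %s", path)
  expr_matrix(mat, sample_meta = sample_meta)
}

#' Write an expression matrix as TSV
#'
#' @param x an [expr_matrix()] or plain matrix.
#' @param path output path.
#' @param id_column name of the gene id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene") {
  v <- as_values(x)
  df <- data.frame(rownames(v), v, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols (non-empty; duplicates are
#'   removed with a warning).
#' @param category free-text category tag (e.g. `"oxphos"`, `"immune"`).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, category = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop_fmt("gene set '%s' is empty", name)
  if (anyDuplicated(genes)) {
    warn_fmt("gene set '%s': duplicate symbols removed", name)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, category = category),
            class = "gene_set")
}

#' Read a GMT gene set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' kept as the set's category tag.
#'
#' @param path file path.
#' @return a named list of [gene_set()] objects (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_fmt("GMT line %d in %s has fewer than 3 fields", i, path)
    gene_set(f[1], f[-(1:2)], category = f[2])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets))) stop_fmt("duplicate set names in %s", path)
  structure(sets, class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, ifelse(nzchar(s$category), s$category, "na"), s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Controlled vocabularies for variant impact annotations.
.sift_levels <- c("deleterious", "tolerated", "missing")
.polyphen_levels <- c("probably_damaging", "possibly_damaging", "benign", "missing")

# "deleterious(0.01)" -> "deleterious"; "probably damaging" -> "probably_damaging".
parse_impact_label <- function(x, levels) {
  x <- tolower(trimws(sub("\\(.*$", "", as.character(x))))
  x <- gsub("[ ]+", "_", x)
  x[is.na(x) | !nzchar(x)] <- "missing"
  unknown <- setdiff(unique(x), levels)
  if (length(unknown)) {
    warn_fmt("unrecognized impact labels mapped to missing: %s",
             paste(unknown, collapse = ", "))
    x[x %in% unknown] <- "missing"
  }
  x
}

#' Read a MAF-style mutation table
#'
#' Reads a tab-separated mutation annotation file and normalizes the SIFT and
#' PolyPhen columns to controlled vocabularies. Labels are parsed as the text
#' prefix before an optional parenthesized score, case-insensitively, with
#' spaces and underscores both accepted; unrecognized labels map to
#' `"missing"` with a warning.
#'
#' @param path file path.
#' @param col_map named character vector mapping the logical columns
#'   `gene`, `sample_id`, `variant_classification`, `sift`, `polyphen` to the
#'   file's column names.
#' @return a data.frame of class `mutation_table` with columns `gene`,
#'   `sample_id`, `variant_classification`, `sift_label`, `polyphen_label`.
#' @export
read_maf <- function(path,
                     col_map = c(
                       gene = "Hugo_Symbol",
                       sample_id = "Tumor_Sample_Barcode",
                       variant_classification = "Variant_Classification",
                       sift = "SIFT",
                       polyphen = "PolyPhen"
                     )) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  required <- c("gene", "sample_id", "sift", "polyphen")
  missing_cols <- setdiff(col_map[required], names(df))
  if (length(missing_cols)) {
    stop_fmt("MAF %s lacks mandatory columns: %s", path,
             paste(missing_cols, collapse = ", "))
  }
  vc <- if (col_map[["variant_classification"]] %in% names(df)) {
    as.character(df[[col_map[["variant_classification"]]]])
  } else {
    rep(NA_character_, nrow(df))
  }
  out <- data.frame(
    gene = as.character(df[[col_map[["gene"]]]]),
    sample_id = as.character(df[[col_map[["sample_id"]]]]),
    variant_classification = vc,
    sift_label = parse_impact_label(df[[col_map[["sift"]]]], .sift_levels),
    polyphen_label = parse_impact_label(df[[col_map[["polyphen"]]]], .polyphen_levels),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Write a mutation table in MAF-style TSV
#'
#' @param mutations a `mutation_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  df <- data.frame(
    Hugo_Symbol = mutations$gene,
    Tumor_Sample_Barcode = mutations$sample_id,
    Variant_Classification = mutations$variant_classification,
    SIFT = mutations$sift_label,
    PolyPhen = mutations$polyphen_label,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' @param path TSV path.
#' @param col_map named vector mapping `sample_id`, `os_time`, `os_event` to
#'   the file's column names; any further columns are carried as covariates.
#' @return data.frame with columns `sample_id`, `os_time` (months),
#'   `os_event` (0 censored / 1 death) plus covariates.
#' @export
read_clinical_tsv <- function(path,
                              col_map = c(sample_id = "sample_id",
                                          os_time = "os_time",
                                          os_event = "os_event")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(col_map, names(df))
  if (length(missing_cols)) {
    stop_fmt("clinical table %s lacks columns: %s", path,
             paste(missing_cols, collapse = ", "))
  }
  out <- df
  names(out)[match(col_map, names(df))] <- names(col_map)
  validate_clinical(out)
  out
}

validate_clinical <- function(clinical) {
  if (anyDuplicated(clinical$sample_id)) stop_fmt("duplicate sample_id in clinical table")
  if (any(!is.finite(clinical$os_time)) || any(clinical$os_time <= 0)) {
    stop_fmt("os_time must be finite and positive")
  }
  if (!all(clinical$os_event %in% c(0, 1))) stop_fmt("os_event must be 0 or 1")
  invisible(clinical)
}

#' Log2 transform with pseudocount
#'
#' @param x an [expr_matrix()] or numeric matrix/vector of linear values.
#' @param pseudocount positive offset added before the log (default 1).
#' @return matrix (or vector) of `log2(x + pseudocount)`.
#' @export
to_log2 <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop_fmt("pseudocount must be > 0")
  log2(as_values(x) + pseudocount)
}
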