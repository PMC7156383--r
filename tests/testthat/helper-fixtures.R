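# Small in-code fixtures shared across tests.

# Random linear expression matrix with named genes/samples.
random_expr <- function(n_genes = 20, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 6, 1.5), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# Items-by-features matrix with k planted, well-separated clusters.
planted_points <- function(n_per = 10, k = 2, n_features = 5, sep = 8, seed = 1) {
  set.seed(seed)
  labels <- rep(seq_len(k), each = n_per)
  centers <- matrix(rnorm(k * n_features), k, n_features) * sep
  x <- centers[labels, ] + matrix(rnorm(n_per * k * n_features), n_per * k)
  rownames(x) <- sprintf("I%03d", seq_len(nrow(x)))
  list(x = x, labels = labels)
}

# Random censored survival instance.
random_survival <- function(n = 25, seed = 1) {
  set.seed(seed)
  list(times = round(rexp(n, 0.05), 2) + 0.01,
       events = rbinom(n, 1, 0.7))
}

# Partition agreement up to label renaming (adjusted Rand index).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

tiny_clinical <- function(times, events, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(times))
  data.frame(sample_id = ids, os_time = times, os_event = events,
             stringsAsFactors = FALSE)
}
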