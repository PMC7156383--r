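# Independent brute-force / naive-loop oracles. These deliberately avoid the
# package's implementation paths (and the library calls those paths use), so
# agreement is evidence, not tautology.

# Explicit running-sum ssGSEA oracle.
oracle_ssgsea <- function(values, genes, alpha) {
  nm <- names(values)
  n <- length(values)
  ord <- order(-values, nm, method = "radix")
  m <- sum(nm %in% genes)
  wsum <- 0
  for (i in seq_len(n)) {
    if (nm[ord[i]] %in% genes) wsum <- wsum + (n - i + 1)^alpha
  }
  es <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_len(n)) {
    if (nm[ord[i]] %in% genes) {
      p_in <- p_in + (n - i + 1)^alpha / wsum
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    es <- es + (p_in - p_out)
  }
  es
}

# Naive double-loop NED.
oracle_ned <- function(M, labels) {
  n <- nrow(M)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- as.numeric(labels[i] == labels[j])
      total <- total + (M[i, j] - p)^2
    }
  }
  sqrt(total / (n * (n - 1) / 2))
}

# Naive risk-set product-limit estimator at death times.
oracle_km <- function(times, events) {
  dt <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(dt))
  for (i in seq_along(dt)) {
    at_risk <- sum(times >= dt[i])
    deaths <- sum(times == dt[i] & events == 1)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  list(time = dt, surv = surv)
}

# Direct scan for the median: first death time with survival <= 0.5.
oracle_median_survival <- function(times, events) {
  km <- oracle_km(times, events)
  hit <- which(km$surv <= 0.5)
  if (!length(hit)) NA_real_ else km$time[min(hit)]
}

# Two-group log-rank chi-square by explicit risk-set enumeration.
oracle_logrank2 <- function(t1, e1, t2, e2) {
  dt <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o_minus_e <- 0
  v <- 0
  for (t in dt) {
    n1 <- sum(t1 >= t)
    n2 <- sum(t2 >= t)
    n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1)
    d <- d1 + sum(t2 == t & e2 == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Step-through Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, m * p[ord[i]] / i)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# Direct sum((O - E)^2 / E) Pearson chi-square.
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Direct covariance-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Direct Welch statistic and p-value.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Brute-force consensus tally reusing only the documented subsample stream.
oracle_consensus <- function(x, k, n_resamples, fraction, seed,
                             metric = "euclidean", linkage = "average") {
  n <- nrow(x)
  idx_list <- metabostrat:::draw_subsamples(n, fraction, n_resamples, seed)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (idx in idx_list) {
    cl <- cutree(hclust(dist(x[idx, , drop = FALSE], method = metric),
                        method = linkage), k = k)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        i <- idx[a]
        j <- idx[b]
        co_sample[i, j] <- co_sample[i, j] + 1
        if (cl[a] == cl[b]) co_cluster[i, j] <- co_cluster[i, j] + 1
      }
    }
  }
  M <- co_cluster / pmax(co_sample, 1)
  M[co_sample == 0] <- 0.5
  diag(M) <- 1
  M
}
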