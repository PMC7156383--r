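#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Ties of deaths and
#' censorings at the same time follow the standard convention: deaths are
#' processed first, so subjects censored at a death time are still in the
#' risk set for that death.
#'
#' @param times positive follow-up times (months).
#' @param events event indicators, 1 = death, 0 = censored.
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`
#'   aligned vectors plus totals `n` and `n_events`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_fmt("no subjects")
  if (length(times) != length(events)) stop_fmt("times and events differ in length")
  if (any(!is.finite(times)) || any(times <= 0)) stop_fmt("times must be finite and > 0")
  if (!all(events %in% c(0, 1))) stop_fmt("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  structure(list(
    time = fit$time,
    surv = fit$surv,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n = length(times),
    n_events = sum(events)
  ), class = "km_curve")
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` (median not reached) when the curve never does.
#'
#' @param curve a [km_estimate()] result.
#' @return months, or `NA_real_` when not reached.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  at <- curve$n_event > 0 & curve$surv <= 0.5
  if (!any(at)) return(NA_real_)
  min(curve$time[at])
}

#' Log-rank (Mantel-Cox) test
#'
#' Standard Mantel-Cox statistic over the pooled risk sets of two or more
#' groups, with `length(groups) - 1` degrees of freedom and an upper-tail
#' chi-square p-value.
#'
#' @param groups list of per-group lists with elements `times` and `events`.
#' @return object of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `group_sizes`.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2) stop_fmt("need at least 2 groups")
  sizes <- vapply(groups, function(g) length(g$times), 0L)
  if (any(sizes == 0)) stop_fmt("group %d has zero subjects", which(sizes == 0)[1])
  df <- data.frame(
    time = unlist(lapply(groups, `[[`, "times")),
    event = unlist(lapply(groups, `[[`, "events")),
    group = factor(rep(seq_along(groups), sizes))
  )
  chisq <- if (sum(df$event) == 0) {
    0 # no deaths anywhere: observed = expected = 0 in every group
  } else {
    survival::survdiff(survival::Surv(time, event) ~ group, data = df, rho = 0)$chisq
  }
  dof <- length(groups) - 1
  structure(list(
    chi_square = as.numeric(chisq),
    df = dof,
    p_value = stats::pchisq(as.numeric(chisq), dof, lower.tail = FALSE),
    group_sizes = sizes
  ), class = "logrank_result")
}

#' Survival stratification report for expression clusters
#'
#' Kaplan-Meier curve and median survival per cluster, a pairwise log-rank
#' test of every other cluster against the reference cluster, and a pooled
#' comparison of the reference cluster against the remaining clusters
#' combined (or against an explicit pooling set). Pairwise p-values are
#' reported unadjusted, matching the per-cluster reporting convention of
#' survival figures in this setting; a BH-adjusted column is emitted
#' alongside for transparency.
#'
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`.
#' @param labels named integer vector, sample id -> cluster.
#' @param reference_cluster cluster every other cluster is compared to.
#' @param pool clusters pooled for the combined comparison (default: all
#'   clusters other than the reference).
#' @return object of class `survival_report`: `curves` (per cluster),
#'   `medians` (data.frame cluster/n/events/median_survival), `pairwise`
#'   (data.frame with chi-square, raw and BH-adjusted p), `pooled`
#'   (a [logrank_test()] result or NULL), `reference_cluster`.
#' @export
cluster_survival_report <- function(clinical, labels, reference_cluster = 1,
                                    pool = NULL) {
  validate_clinical(clinical)
  missing_samples <- setdiff(names(labels), clinical$sample_id)
  if (length(missing_samples)) {
    stop_fmt("samples without clinical data: %s",
             paste(utils::head(missing_samples, 10), collapse = ", "))
  }
  idx <- match(names(labels), clinical$sample_id)
  times <- clinical$os_time[idx]
  events <- clinical$os_event[idx]
  clusters <- sort(unique(labels))
  grp <- function(cl) {
    keep <- labels %in% cl
    list(times = times[keep], events = events[keep])
  }
  curves <- lapply(clusters, function(cl) km_estimate(grp(cl)$times, grp(cl)$events))
  names(curves) <- clusters
  medians <- data.frame(
    cluster = clusters,
    n = as.integer(table(factor(labels, levels = clusters))),
    events = vapply(clusters, function(cl) as.numeric(sum(grp(cl)$events)), 0),
    median_survival = vapply(curves, median_survival, 0)
  )
  if (length(clusters) == 1) {
    return(structure(list(curves = curves, medians = medians,
                          pairwise = NULL, pooled = NULL,
                          reference_cluster = reference_cluster),
                     class = "survival_report"))
  }
  if (!reference_cluster %in% clusters) {
    stop_fmt("reference cluster %s has no samples", reference_cluster)
  }
  others <- setdiff(clusters, reference_cluster)
  pairwise <- do.call(rbind, lapply(others, function(cl) {
    lr <- logrank_test(list(grp(reference_cluster), grp(cl)))
    data.frame(cluster = cl, vs = reference_cluster,
               chi_square = lr$chi_square, df = lr$df, p = lr$p_value)
  }))
  pairwise$p_bh <- stats::p.adjust(pairwise$p, method = "BH")
  pool <- if (is.null(pool)) others else intersect(pool, clusters)
  pooled <- if (length(pool)) {
    logrank_test(list(grp(reference_cluster), grp(pool)))
  } else {
    NULL
  }
  structure(list(curves = curves, medians = medians, pairwise = pairwise,
                 pooled = pooled, pooled_clusters = pool,
                 reference_cluster = reference_cluster),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("cluster survival report\n")
  print(x$medians, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat(sprintf("pairwise log-rank vs cluster %s:\n", x$reference_cluster))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
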