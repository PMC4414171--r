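#' Dichotomize samples by k=2 partition around medoids
#'
#' One-dimensional PAM with absolute-difference dissimilarity, solved
#' exactly by searching all medoid pairs (feasible at cohort scale). Each
#' sample is assigned to the nearer medoid (ties to the lower-valued
#' medoid); ties in total cost are broken by the lexicographically smaller
#' (sorted) medoid value pair, so the split is deterministic. The group
#' whose medoid value is larger is labelled `high`.
#'
#' @param values Named numeric vector of per-sample locus expression
#'   (n >= 4, not all equal).
#' @return Named character vector of labels `"high"`/`"low"`.
#' @export
pam_two_groups <- function(values) {
  if (length(values) < 4L)
    abort_input("pam_two_groups() needs at least 4 samples")
  if (length(unique(values)) < 2L)
    abort_input("pam_two_groups(): all values equal, no partition exists")
  v <- as.numeric(values)
  n <- length(v)
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      m <- sort(c(v[i], v[j]))
      if (m[1] == m[2]) next
      cost <- sum(pmin(abs(v - m[1]), abs(v - m[2])))
      key <- c(cost, m)
      if (is.null(best) ||
          cost < best$cost - 1e-12 ||
          (abs(cost - best$cost) <= 1e-12 &&
           (m[1] < best$m[1] || (m[1] == best$m[1] && m[2] < best$m[2])))) {
        best <- list(cost = cost, m = m)
      }
    }
  }
  d_lo <- abs(v - best$m[1]); d_hi <- abs(v - best$m[2])
  lab <- ifelse(d_hi < d_lo, "high", "low")  # distance ties go low (lower medoid)
  stats::setNames(lab, names(values))
}

#' Label-permutation test of endpoint enrichment in the high group
#'
#' The observed statistic is the number of event-positive patients in the
#' high-expression group. Event labels are permuted `n_iter` times and
#' reassigned to groups of the same sizes; the p-value is the fraction of
#' permutations with a statistic at least as large as observed (the `>=`
#' convention guarantees p > 0 and validity). Only enrichment in the high
#' group counts: the test targets overexpression markers of poor outcome.
#'
#' @param group_labels Character vector `"high"`/`"low"` per patient.
#' @param endpoint_events 0/1 event indicators, aligned with
#'   `group_labels`.
#' @param n_iter Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List: `observed`, `p`.
#' @export
bootstrap_association <- function(group_labels, endpoint_events,
                                  n_iter = 10000, seed = 1) {
  if (length(group_labels) != length(endpoint_events))
    abort_input("group labels and events must be aligned")
  if (n_iter < 1) abort_input("n_iter must be >= 1")
  if (!all(endpoint_events %in% c(0, 1)))
    abort_input("events must be 0/1")
  n_high <- sum(group_labels == "high")
  observed <- sum(endpoint_events[group_labels == "high"])
  set.seed(split_seed(seed, 17))
  ev <- as.integer(endpoint_events)
  stats_perm <- vapply(seq_len(n_iter), function(i) {
    sum(ev[sample.int(length(ev), n_high)])
  }, numeric(1))
  list(observed = observed, p = mean(stats_perm >= observed))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order, each >= its p-value, bounded
#'   by 1.
#' @export
fdr_bh <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    abort_input("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank statistic (chi-squared, 1 df). When no event occurs in either
#' group the test is undefined; the function warns and reports p = 1 with
#' both curves constant at 1.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param groups `"high"`/`"low"` labels from [pam_two_groups()].
#' @return List: `curves` (`data.frame`: group, time, n_risk, n_event,
#'   survival), `chisq`, `p`.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times <= 0)) abort_input("times must be > 0")
  tab <- table(groups)
  if (length(tab) != 2L || any(tab == 0))
    abort_input("km_logrank() needs two non-empty groups")
  grp <- factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ grp)
  strata_names <- sub("^grp=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_names, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       survival = fit$surv, stringsAsFactors = FALSE)
  if (sum(events) == 0) {
    warning("no events in either group: log-rank undefined, reporting p = 1")
    return(list(curves = curves, chisq = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd$chisq), p = p)
}

#' Prognostic screen across loci
#'
#' For each locus: PAM dichotomization of its expression, permutation
#' association p per clinical endpoint, BH correction across loci within
#' each endpoint, and a log-rank p for the same split.
#'
#' @param expr_matrix Loci x samples expression matrix.
#' @param clinical `data.frame` with `sample_id` and, per endpoint
#'   `<e>`, columns `<e>_event` (0/1) and `<e>_time` (months).
#' @param endpoints Endpoint names (default `c("BCR", "PCaMets", "PCaD")`).
#' @param n_iter Permutations per test (default 10000).
#' @param seed Integer seed.
#' @return `data.frame`: name, endpoint, n_high, n_low, observed,
#'   perm_p, q_value, logrank_p.
#' @export
prognostic_screen <- function(expr_matrix, clinical,
                              endpoints = c("BCR", "PCaMets", "PCaD"),
                              n_iter = 10000, seed = 1) {
  samples <- intersect(colnames(expr_matrix), clinical$sample_id)
  if (length(samples) < 4L)
    abort_input("prognostic_screen(): fewer than 4 samples with clinical data")
  clinical <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  rows <- list()
  for (nm in rownames(expr_matrix)) {
    labels <- pam_two_groups(expr_matrix[nm, samples])
    for (e in endpoints) {
      ev_col <- paste0(e, "_event"); t_col <- paste0(e, "_time")
      if (!ev_col %in% names(clinical))
        abort_input(sprintf("clinical table lacks column '%s'", ev_col))
      ev <- clinical[[ev_col]]
      ba <- bootstrap_association(labels, ev, n_iter = n_iter,
                                  seed = split_seed(seed, 100 + length(rows)))
      lr <- if (sum(ev) == 0) {
        list(p = 1)
      } else {
        suppressWarnings(km_logrank(clinical[[t_col]], ev, labels))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, endpoint = e,
        n_high = sum(labels == "high"), n_low = sum(labels == "low"),
        observed = ba$observed, perm_p = ba$p, logrank_p = lr$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  for (e in endpoints) {
    i <- res$endpoint == e
    res$q_value[i] <- fdr_bh(res$perm_p[i])
  }
  res
}
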