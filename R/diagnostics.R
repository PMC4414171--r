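#' Empirical AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with ties counted half:
#' `P(score_case > score_control) + 0.5 P(tie)`.
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = case) or two-level vector; the positive
#'   level is given by `positive`.
#' @param positive Label treated as the case class when `labels` is not
#'   logical (default `"cancer"`).
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels, positive = "cancer") {
  pos <- if (is.logical(labels)) labels else labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    abort_input("empirical_auc() needs both classes present")
  r <- rank(scores)  # midranks handle ties exactly
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimize linear panel weights for training AUC
#'
#' Searches for a weight vector `w` maximizing the empirical AUC of the
#' linear score `X w` on the training cohort. Because empirical AUC is
#' piecewise constant, the search is derivative-free: multi-start
#' Nelder-Mead from every single-marker unit vector, the equal-weight
#' vector, and `n_random` random directions. Candidates are normalized to
#' unit L2 norm (AUC is scale-invariant). The best candidate over all
#' starts and their optima is returned, so the training AUC is never below
#' the best single marker's.
#'
#' @param x Samples x markers numeric matrix (named columns).
#' @param labels Class labels (see [empirical_auc()]).
#' @param positive Positive class label (default `"cancer"`).
#' @param seed Integer seed for the random starts.
#' @param n_random Number of random starting directions (default 20).
#' @return Named numeric weight vector (unit norm), with attribute
#'   `train_auc`.
#' @export
optimize_panel_weights <- function(x, labels, positive = "cancer", seed = 1,
                                   n_random = 20) {
  if (!is.matrix(x) || ncol(x) < 2L)
    abort_input("optimize_panel_weights() needs a matrix of >= 2 markers")
  if (is.null(colnames(x)))
    abort_input("marker matrix must have column names")
  pos <- if (is.logical(labels)) labels else labels == positive
  if (!any(pos) || all(pos))
    abort_input("training set must contain both classes")
  p <- ncol(x)
  normalize <- function(w) {
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) rep(1 / sqrt(p), p) else w / nrm
  }
  objective <- function(w) -empirical_auc(drop(x %*% normalize(w)), pos, TRUE)
  set.seed(split_seed(seed, 23))
  starts <- c(
    lapply(seq_len(p), function(j) { w <- rep(0, p); w[j] <- 1; w }),
    list(rep(1, p)),
    lapply(seq_len(n_random), function(i) stats::rnorm(p))
  )
  best_w <- NULL; best_val <- Inf
  for (w0 in starts) {
    v0 <- objective(w0)
    if (v0 < best_val) { best_val <- v0; best_w <- normalize(w0) }
    opt <- stats::optim(w0, objective, method = "Nelder-Mead",
                        control = list(maxit = 500))
    if (opt$value < best_val) {
      best_val <- opt$value
      best_w <- normalize(opt$par)
    }
  }
  w <- stats::setNames(best_w, colnames(x))
  attr(w, "train_auc") <- -best_val
  w
}

#' Apply a fixed panel to a validation cohort
#'
#' @param weights Named weight vector from [optimize_panel_weights()].
#' @param x Samples x markers matrix; columns must match the weight names.
#' @param labels Class labels.
#' @param positive Positive class label (default `"cancer"`).
#' @return Validation AUC.
#' @export
apply_panel <- function(weights, x, labels, positive = "cancer") {
  if (!setequal(colnames(x), names(weights)))
    abort_input("validation markers do not match panel weights")
  empirical_auc(drop(x[, names(weights), drop = FALSE] %*% weights),
                labels, positive)
}

#' Binary in-situ-hybridization panel metrics
#'
#' A core is positive for a marker iff its integer score exceeds 0; the
#' combined panel call is positive iff any marker is. Sensitivity is
#' computed over cores in `case_categories`, specificity over
#' `control_categories`, and the AUC of the binary combined score follows
#' the Mann-Whitney formula (equal to `(sens + spec) / 2`).
#'
#' @param table `data.frame` with a `tissue` column and one integer score
#'   column per marker.
#' @param markers Marker column names.
#' @param case_categories,control_categories Tissue categories forming the
#'   case and control sets.
#' @return List: `per_marker_sensitivity`, `combined_sensitivity`,
#'   `specificity`, `auc`, `n_cases`, `n_controls`.
#' @export
binary_panel_metrics <- function(table, markers, case_categories,
                                 control_categories) {
  if (!length(case_categories) || !length(control_categories))
    abort_input("case and control categories must be non-empty")
  cases <- table[table$tissue %in% case_categories, , drop = FALSE]
  controls <- table[table$tissue %in% control_categories, , drop = FALSE]
  if (!nrow(cases) || !nrow(controls))
    abort_input("no cores in case or control categories")
  if (any(vapply(markers, function(m) any(table[[m]] < 0), logical(1))))
    abort_input("scores must be >= 0")
  pos_mat <- function(df) vapply(markers, function(m) df[[m]] > 0,
                                 logical(nrow(df)))
  case_pos <- matrix(pos_mat(cases), nrow = nrow(cases))
  ctrl_pos <- matrix(pos_mat(controls), nrow = nrow(controls))
  per_marker <- stats::setNames(colMeans(case_pos), markers)
  comb_case <- apply(case_pos, 1, any)
  comb_ctrl <- apply(ctrl_pos, 1, any)
  sens <- mean(comb_case)
  spec <- mean(!comb_ctrl)
  auc <- empirical_auc(c(as.numeric(comb_case), as.numeric(comb_ctrl)),
                       c(rep(TRUE, length(comb_case)),
                         rep(FALSE, length(comb_ctrl))))
  list(per_marker_sensitivity = per_marker, combined_sensitivity = sens,
       specificity = spec, auc = auc,
       n_cases = nrow(cases), n_controls = nrow(controls))
}

#' Fisher's exact test (two-sided, point-probability method)
#'
#' Sums, over all 2x2 tables with the observed margins, the hypergeometric
#' probabilities not exceeding that of the observed table (the "minlike"
#' two-sided convention).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table)))
    abort_input("fisher_exact() needs a 2x2 matrix of nonnegative integers")
  a <- table[1, 1]
  m <- sum(table[1, ])   # row-1 total
  n <- sum(table[2, ])   # row-2 total
  k <- sum(table[, 1])   # column-1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Positivity percentage at a printed precision
#'
#' `100 * n_positive / n_total`, rounded half-away-from-zero to `decimals`
#' digits — the convention matching printed staining percentages such as
#' 46/73 -> 63.0 or 12/113 -> 10.62.
#'
#' @param n_positive,n_total Counts with `0 <= n_positive <= n_total`,
#'   `n_total > 0`.
#' @param decimals Digits after the decimal point (default 1).
#' @return Percentage on the 0-100 scale.
#' @export
positivity_rate <- function(n_positive, n_total, decimals = 1) {
  if (n_total <= 0) abort_input("n_total must be > 0")
  if (n_positive < 0 || n_positive > n_total)
    abort_input("need 0 <= n_positive <= n_total")
  round_half_away(100 * n_positive / n_total, decimals)
}

#' ROC curve points of a score
#'
#' @param scores Numeric scores.
#' @param labels Class labels (see [empirical_auc()]).
#' @param positive Positive class label.
#' @return `data.frame` of (fpr, tpr) sorted from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels, positive = "cancer") {
  pos <- if (is.logical(labels)) labels else labels == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    c(fpr = mean(scores[!pos] >= t), tpr = mean(scores[pos] >= t))
  }, numeric(2)))
  rbind(data.frame(fpr = 0, tpr = 0), as.data.frame(pts),
        data.frame(fpr = 1, tpr = 1))
}
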