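#' COPA transformation of one expression row
#'
#' Cancer outlier profile analysis (COPA) rescales a feature's log2
#' expression vector by centering on the median and dividing by the
#' unscaled median absolute deviation (MAD, no normal-consistency
#' constant). This accentuates samples whose expression departs from the
#' bulk — the signature of a transcript overexpressed in a subset of
#' tumors only, which mean/SD statistics wash out.
#'
#' Rows whose raw MAD is zero (flat probes) are degenerate: all scores are
#' defined as 0 and the row is flagged via the `"degenerate"` attribute.
#'
#' @param x Numeric vector of log2 expression values for one transcript
#'   cluster across all samples of a dataset (length >= 3).
#' @return Numeric vector of COPA scores, same length and names as `x`,
#'   with attribute `degenerate` (logical scalar).
#' @examples
#' copa_transform(c(0, 0, 2, 2, 10))  # -1 -1 0 0 4
#' @export
copa_transform <- function(x) {
  if (!is.numeric(x) || length(x) < 3L)
    abort_input("copa_transform() requires a numeric vector of >= 3 samples")
  med <- stats::median(x)
  m <- stats::median(abs(x - med))
  if (m == 0) {
    s <- rep(0, length(x))
    names(s) <- names(x)
    attr(s, "degenerate") <- TRUE
    return(s)
  }
  s <- (x - med) / m
  attr(s, "degenerate") <- FALSE
  s
}

#' Call outlier samples from COPA scores
#'
#' The per-feature threshold is `2 * MAD(scores) / 0.6745`, where the MAD of
#' the COPA scores is again unscaled and 0.6745 is the usual
#' normal-consistency constant. Calling is one-sided: only samples whose
#' score strictly exceeds the threshold are outliers (the method targets
#' subset-specific overexpression). Degenerate rows yield an empty outlier
#' set.
#'
#' @param copa_scores Output of [copa_transform()].
#' @param tc_id Optional feature identifier carried through.
#' @return An object of class `outlier_call`: list with `tc_id`,
#'   `copa_scores`, `threshold`, `outlier_mask` (named logical), and
#'   `degenerate`.
#' @export
detect_outliers <- function(copa_scores, tc_id = NA_character_) {
  if (!is.numeric(copa_scores) || length(copa_scores) < 3L)
    abort_input("detect_outliers() requires COPA scores over >= 3 samples")
  degenerate <- isTRUE(attr(copa_scores, "degenerate"))
  scores <- as.numeric(copa_scores)
  names(scores) <- names(copa_scores)
  thr <- 2 * stats::median(abs(scores - stats::median(scores))) / 0.6745
  mask <- if (degenerate) {
    stats::setNames(rep(FALSE, length(scores)), names(scores))
  } else {
    scores > thr
  }
  structure(
    list(tc_id = tc_id, copa_scores = scores, threshold = thr,
         outlier_mask = mask, degenerate = degenerate),
    class = "outlier_call"
  )
}

#' @export
print.outlier_call <- function(x, ...) {
  cat(sprintf("<outlier_call> %s: threshold %.4f, %d/%d outliers%s\n",
              x$tc_id, x$threshold, sum(x$outlier_mask),
              length(x$outlier_mask),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Run COPA outlier calling over every row of a dataset
#'
#' @param dataset An [expression_dataset()].
#' @return Named list of `outlier_call`, one per transcript cluster.
#' @export
call_outliers <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  m <- dataset$matrix
  calls <- lapply(rownames(m), function(id) {
    detect_outliers(copa_transform(m[id, ]), tc_id = id)
  })
  stats::setNames(calls, rownames(m))
}

#' Filter transcript clusters on annotation and outlier structure
#'
#' Retains transcript clusters (TCs) that are (a) not assigned to a known
#' gene, (b) have no outlier sample in any control-class group, and (c)
#' have outlier fraction at least `min_cancer_outlier_fraction` among
#' cancer-class samples. A TC at exactly the boundary fraction is retained.
#'
#' @param dataset An [expression_dataset()].
#' @param tcs Transcript-cluster table (`data.frame` with at least `tc_id`
#'   and `annotated`).
#' @param calls Named list of `outlier_call` covering every TC (see
#'   [call_outliers()]).
#' @param min_cancer_outlier_fraction Minimum fraction of cancer-class
#'   samples that must be outliers; default 0.05.
#' @return Character vector of retained `tc_id`s.
#' @export
filter_transcript_clusters <- function(dataset, tcs, calls,
                                       min_cancer_outlier_fraction = 0.05) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  check_fraction(min_cancer_outlier_fraction, "min_cancer_outlier_fraction")
  missing <- setdiff(tcs$tc_id, names(calls))
  if (length(missing))
    abort_input(paste0("no outlier call for TC(s): ",
                       paste(utils::head(missing, 5), collapse = ", ")))
  cls <- sample_classes(dataset)
  cancer_ids <- names(cls)[cls == "cancer"]
  control_ids <- names(cls)[cls == "control"]
  keep <- vapply(seq_len(nrow(tcs)), function(i) {
    if (isTRUE(tcs$annotated[i])) return(FALSE)
    mask <- calls[[tcs$tc_id[i]]]$outlier_mask
    if (any(mask[control_ids])) return(FALSE)
    mean(mask[cancer_ids]) >= min_cancer_outlier_fraction
  }, logical(1))
  tcs$tc_id[keep]
}
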