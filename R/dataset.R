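#' Construct an expression dataset
#'
#' One cohort's log2 feature-by-sample matrix together with its sample
#' grouping. Groups (e.g. NAP, PCa, TURP, LNPCa) are mapped to the two
#' classes the outlier filters operate on: `control` and `cancer`.
#'
#' @param dataset_id Cohort identifier.
#' @param matrix Numeric matrix, rows = transcript-cluster ids (rownames),
#'   columns = sample ids (colnames), log2 scale.
#' @param sample_groups Named character vector: sample id -> group label.
#' @param group_classes Named character vector: group label -> `"control"`
#'   or `"cancer"`.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, sample_groups, group_classes) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    abort_input("'matrix' must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    abort_input("'matrix' must have rownames (TC ids) and colnames (sample ids)")
  missing_meta <- setdiff(colnames(matrix), names(sample_groups))
  if (length(missing_meta))
    abort_input(paste0("sample(s) missing from metadata: ",
                       paste(utils::head(missing_meta, 5), collapse = ", ")))
  sample_groups <- sample_groups[colnames(matrix)]
  bad_group <- setdiff(unique(sample_groups), names(group_classes))
  if (length(bad_group))
    abort_input(paste0("group(s) without a class assignment: ",
                       paste(bad_group, collapse = ", ")))
  if (!all(group_classes %in% c("control", "cancer")))
    abort_input("group classes must be 'control' or 'cancer'")
  cls <- unname(group_classes[sample_groups])
  if (!any(cls == "control") || !any(cls == "cancer"))
    abort_input("dataset needs at least one control and one cancer sample")
  structure(
    list(dataset_id = dataset_id, matrix = matrix,
         sample_groups = sample_groups, group_classes = group_classes),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cls <- sample_classes(x)
  cat(sprintf("<ExpressionDataset> %s: %d TCs x %d samples (%d control, %d cancer)\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              sum(cls == "control"), sum(cls == "cancer")))
  invisible(x)
}

#' Per-sample class labels of a dataset
#'
#' @param dataset An [expression_dataset()].
#' @return Named character vector (sample id -> `"control"`/`"cancer"`).
#' @export
sample_classes <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  stats::setNames(unname(dataset$group_classes[dataset$sample_groups]),
                  names(dataset$sample_groups))
}

#' Construct a transcript-cluster table
#'
#' Validates the probe-level feature table used throughout discovery:
#' genomic interval (0-based half-open), strand, probe count and the
#' known-gene annotation flag.
#'
#' @param tc_id,chrom,start,end,strand,probe_count,annotated Column vectors.
#' @return `data.frame` with class `tc_table` prepended.
#' @export
tc_table <- function(tc_id, chrom, start, end, strand, probe_count, annotated) {
  df <- data.frame(tc_id = as.character(tc_id), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   probe_count = as.integer(probe_count),
                   annotated = as.logical(annotated),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$tc_id))
    abort_input("duplicate tc_id in transcript-cluster table")
  if (any(df$start >= df$end))
    abort_input("transcript cluster with start >= end")
  if (!all(df$strand %in% c("+", "-")))
    abort_input("strand must be '+' or '-'")
  if (any(df$probe_count < 1L))
    abort_input("probe_count must be >= 1")
  class(df) <- c("tc_table", class(df))
  df
}
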