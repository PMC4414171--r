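#' Per-sample expression of a candidate locus
#'
#' A locus is summarized as the mean of the log2 values of its member
#' transcript clusters in each sample.
#'
#' @param dataset An [expression_dataset()].
#' @param tc_ids Member TC ids present in the dataset.
#' @return Named numeric vector over the dataset's samples.
#' @export
epcat_expression <- function(dataset, tc_ids) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  missing <- setdiff(tc_ids, rownames(dataset$matrix))
  if (length(missing))
    abort_input(paste0("TC(s) absent from dataset: ",
                       paste(utils::head(missing, 5), collapse = ", ")))
  colMeans(dataset$matrix[tc_ids, , drop = FALSE])
}

#' Androgen-response screen over candidate loci
#'
#' Welch's unequal-variance t-test compares treated vs untreated log2
#' values per locus; p-values are Benjamini-Hochberg corrected across all
#' tested loci. A locus is called `up` when q < `alpha` and linear fold
#' change exceeds `fold_threshold`, `down` when q < `alpha` and fold change
#' is below `1/fold_threshold`, otherwise `ns`. Loci whose overall mean is
#' below `expressed_threshold` are excluded from testing (call
#' `not_expressed`) and do not enter the correction.
#'
#' @param treated,untreated Numeric matrices (loci x samples, log2), same
#'   rownames, >= 2 columns each.
#' @param fold_threshold Linear fold-change cutoff; default 1.5 (a "more
#'   than 50% change" call).
#' @param alpha FDR level for calls (default 0.05).
#' @param expressed_threshold Minimum mean log2 intensity to be tested
#'   (default `-Inf`, i.e. no filter).
#' @return `data.frame`: name, mean_treated, mean_untreated, fold_change,
#'   p_value, q_value, call.
#' @export
androgen_response <- function(treated, untreated, fold_threshold = 1.5,
                              alpha = 0.05, expressed_threshold = -Inf) {
  if (!is.matrix(treated) || !is.matrix(untreated) ||
      !identical(rownames(treated), rownames(untreated)))
    abort_input("treated/untreated must be matrices with identical rownames")
  if (ncol(treated) < 2L || ncol(untreated) < 2L)
    abort_input("androgen_response() needs >= 2 replicates per condition")
  overall <- (rowSums(treated) + rowSums(untreated)) /
    (ncol(treated) + ncol(untreated))
  tested <- overall >= expressed_threshold
  res <- data.frame(
    name = rownames(treated),
    mean_treated = rowMeans(treated),
    mean_untreated = rowMeans(untreated),
    p_value = NA_real_, q_value = NA_real_,
    call = "not_expressed", stringsAsFactors = FALSE, row.names = NULL
  )
  res$fold_change <- 2^(res$mean_treated - res$mean_untreated)
  for (i in which(tested)) {
    res$p_value[i] <- tryCatch(
      stats::t.test(treated[i, ], untreated[i, ], var.equal = FALSE)$p.value,
      error = function(e) 1)  # zero-variance rows: no evidence
  }
  res$q_value[tested] <- fdr_bh(res$p_value[tested])
  res$call[tested] <- "ns"
  up <- tested & res$q_value < alpha & res$fold_change > fold_threshold
  dn <- tested & res$q_value < alpha & res$fold_change < 1 / fold_threshold
  res$call[up] <- "up"
  res$call[dn] <- "down"
  res
}

#' Spearman coexpression with a driver gene
#'
#' @param epcat_values,driver_values Paired numeric vectors (n >= 5).
#' @param min_rho Correlation cutoff for the flag (default 0.5).
#' @param alpha p-value cutoff for the flag (default 0.05).
#' @return List: `rho`, `p`, `flag` (rho >= min_rho and p < alpha).
#' @export
coexpression <- function(epcat_values, driver_values, min_rho = 0.5,
                         alpha = 0.05) {
  if (length(epcat_values) != length(driver_values) || length(epcat_values) < 5L)
    abort_input("coexpression() needs paired vectors of n >= 5")
  if (stats::sd(epcat_values) == 0 || stats::sd(driver_values) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, flag = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(epcat_values, driver_values, method = "spearman",
                    exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p = ct$p.value, flag = rho >= min_rho && ct$p.value < alpha)
}

#' Peak support within a flanked locus window
#'
#' @param span List or one-row data.frame with `chrom`, `start`, `end`.
#' @param peaks BED-like `data.frame` (`chrom`, `start`, `end`).
#' @param flank_bp Symmetric flank in bp (default 50000).
#' @return `TRUE` iff at least one peak intersects
#'   `[start - flank, end + flank)`.
#' @export
peak_overlap <- function(span, peaks, flank_bp = 50000) {
  if (flank_bp < 0) abort_input("flank_bp must be >= 0")
  if (is.null(peaks) || nrow(peaks) == 0L) return(FALSE)
  any(peaks$chrom == span$chrom &
        intervals_overlap(peaks$start, peaks$end,
                          span$start - flank_bp, span$end + flank_bp))
}

#' Coexpression with same-strand overlapping genes
#'
#' For every annotated gene overlapping the locus on the same strand,
#' correlates the locus expression with the gene's (median-summarized)
#' expression.
#'
#' @param epcat An `epcat` (or list with `chrom`, `strand`, `start`, `end`).
#' @param epcat_values Locus expression per sample.
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param gene_expression Matrix, rows = gene ids, columns matching
#'   `epcat_values`.
#' @return `data.frame`: gene_id, rho, p (0 rows when no same-strand
#'   overlap).
#' @export
overlapping_gene_coexpression <- function(epcat, epcat_values, genes,
                                          gene_expression) {
  hit <- genes$chrom == epcat$chrom & genes$strand == epcat$strand &
    intervals_overlap(genes$start, genes$end, epcat$start, epcat$end)
  ids <- intersect(genes$gene_id[hit], rownames(gene_expression))
  if (!length(ids))
    return(data.frame(gene_id = character(), rho = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(ids, function(g) {
    cx <- coexpression(epcat_values, gene_expression[g, ])
    data.frame(gene_id = g, rho = cx$rho, p = cx$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
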