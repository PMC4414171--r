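#' Construct a conservation track
#'
#' A per-base (or run-length) score track in 0-based half-open
#' coordinates, as read from a bedGraph. Queried bases not covered by any
#' row are treated as missing.
#'
#' @param df `data.frame` with `chrom`, `start`, `end`, `score`; rows may
#'   cover runs of more than one base.
#' @return Object of class `conservation_track`.
#' @export
conservation_track <- function(df) {
  need <- c("chrom", "start", "end", "score")
  if (!all(need %in% names(df)))
    abort_input("conservation track needs columns chrom, start, end, score")
  if (any(df$start >= df$end))
    abort_input("conservation track row with start >= end")
  df <- df[order(df$chrom, df$start), need]
  rownames(df) <- NULL
  class(df) <- c("conservation_track", "data.frame")
  df
}

# Per-base scores for one interval; NA where the track is silent.
track_scores <- function(track, chrom, start, end) {
  out <- rep(NA_real_, end - start)
  rows <- track[track$chrom == chrom & track$end > start & track$start < end, ,
                drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    s <- max(rows$start[i], start); e <- min(rows$end[i], end)
    out[(s - start + 1):(e - start)] <- rows$score[i]
  }
  out
}

#' Representative conservation score of a locus
#'
#' Concatenates the exon bases in genomic order, tiles them into
#' non-overlapping windows of `window_bp` bases, and returns the maximum
#' window mean. A final short window stands alone if it has at least
#' `min_tail_bp` bases, otherwise it is merged into the previous window
#' (the whole sequence forms one window when shorter than `window_bp`).
#' Missing bases are excluded from window means; windows with no scored
#' base are dropped.
#'
#' @param exons `data.frame` with `chrom`, `start`, `end`; non-overlapping,
#'   sorted by start.
#' @param track A [conservation_track()].
#' @param window_bp Window size in bases (default 50).
#' @param min_tail_bp Minimum size of a stand-alone final window
#'   (default 10).
#' @return Maximum window mean score (NA if no base is scored).
#' @export
locus_conservation_score <- function(exons, track, window_bp = 50,
                                     min_tail_bp = 10) {
  if (is.null(exons) || nrow(exons) == 0L)
    abort_input("locus_conservation_score() needs at least one exon")
  if (is.unsorted(exons$start))
    exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$end[-nrow(exons)] > exons$start[-1]))
    abort_input("exons must be non-overlapping")
  scores <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    track_scores(track, exons$chrom[i], exons$start[i], exons$end[i])
  }))
  n <- length(scores)
  k <- n %/% window_bp
  tail_len <- n - k * window_bp
  if (k == 0L) {
    win <- rep(1L, n)
  } else {
    win <- rep(seq_len(k), each = window_bp)
    if (tail_len > 0) {
      win <- c(win, rep(if (tail_len >= min_tail_bp) k + 1L else k, tail_len))
    }
  }
  means <- tapply(scores, win, mean, na.rm = TRUE)
  means <- means[is.finite(means)]
  if (!length(means)) return(NA_real_)
  max(means)
}

#' Compare locus conservation against coding and repeat controls
#'
#' Wilcoxon rank-sum tests of the locus score distribution against
#' protein-coding and repeat-region control distributions, in both
#' directions, plus group medians. The expectation for genuine lncRNA loci
#' is: less conserved than coding sequence, more conserved than repeats.
#'
#' @param locus_scores,coding_scores,repeat_scores Numeric score vectors,
#'   each of length >= 2.
#' @return List: `medians` (named), `p_locus_less_coding`,
#'   `p_locus_greater_coding`, `p_locus_greater_repeat`,
#'   `p_locus_less_repeat`.
#' @export
compare_to_controls <- function(locus_scores, coding_scores, repeat_scores) {
  for (v in list(locus_scores, coding_scores, repeat_scores))
    if (length(v) < 2L)
      abort_input("compare_to_controls() needs >= 2 scores per group")
  wt <- function(x, y, alt) {
    suppressWarnings(stats::wilcox.test(x, y, alternative = alt))$p.value
  }
  list(
    medians = c(locus = stats::median(locus_scores),
                coding = stats::median(coding_scores),
                repeat_ = stats::median(repeat_scores)),
    p_locus_less_coding = wt(locus_scores, coding_scores, "less"),
    p_locus_greater_coding = wt(locus_scores, coding_scores, "greater"),
    p_locus_greater_repeat = wt(locus_scores, repeat_scores, "greater"),
    p_locus_less_repeat = wt(locus_scores, repeat_scores, "less")
  )
}
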