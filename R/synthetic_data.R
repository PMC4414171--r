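#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic multi-cohort
#' world: a small set of "true" unannotated loci overexpressed in a subset
#' of cancer samples only, a background of noise transcript clusters (TCs),
#' and annotated decoy TCs that carry an outlier profile but must be
#' discarded by the annotation filter.
#'
#' The same array design (TC coordinates) is shared by all datasets, as on
#' a real exon-array platform; expression matrices differ per cohort.
#'
#' @param n_datasets Number of cohorts (default 3, as in a three-dataset
#'   meta-analysis).
#' @param n_control Named integer vector of control-group sample counts per
#'   dataset (default `c(NAP = 12)`).
#' @param n_cancer Named integer vector of cancer-group sample counts per
#'   dataset (default `c(PCa = 30, LNPCa = 12)`).
#' @param n_background_tcs Unannotated pure-noise TCs (default 300).
#' @param n_true_loci Implanted outlier loci (default 5).
#' @param tcs_per_locus Integer range `c(lo, hi)` of member TCs per locus.
#' @param probes_per_tc Integer range of probes per TC.
#' @param outlier_fraction Fraction of cancer samples overexpressing a true
#'   locus, drawn per locus and dataset (default 0.3).
#' @param effect_size Log2 shift added to outlier samples (default 4).
#' @param noise_sd Log2-scale residual SD (default 0.3).
#' @param annotated_decoy_fraction Fraction of background TCs flagged as
#'   annotated; half of the decoys also receive an outlier profile so the
#'   annotation filter is exercised (default 0.2).
#' @param baseline_range Uniform range of per-TC baseline log2 intensity
#'   (default `c(4, 8)`).
#' @param locus_span_bp Genomic span available to one locus's TCs.
#' @param inter_locus_bp Spacing between consecutive locus anchors.
#' @param seed Root seed; all generator randomness derives from it.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_datasets = 3,
                              n_control = c(NAP = 12),
                              n_cancer = c(PCa = 30, LNPCa = 12),
                              n_background_tcs = 300,
                              n_true_loci = 5,
                              tcs_per_locus = c(3, 5),
                              probes_per_tc = c(4, 10),
                              outlier_fraction = 0.3,
                              effect_size = 4,
                              noise_sd = 0.3,
                              annotated_decoy_fraction = 0.2,
                              baseline_range = c(4, 8),
                              locus_span_bp = 100000,
                              inter_locus_bp = 2000000,
                              seed = 1) {
  cfg <- list(
    n_datasets = check_count(n_datasets, "n_datasets"),
    n_control = n_control, n_cancer = n_cancer,
    n_background_tcs = check_count(n_background_tcs, "n_background_tcs", min = 0L),
    n_true_loci = check_count(n_true_loci, "n_true_loci", min = 0L),
    tcs_per_locus = tcs_per_locus, probes_per_tc = probes_per_tc,
    outlier_fraction = check_fraction(outlier_fraction, "outlier_fraction",
                                      lo = 0, lo_open = TRUE),
    effect_size = {
      if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
        abort_config("'effect_size' must be a single number >= 0")
      as.numeric(effect_size)
    },
    noise_sd = check_positive(noise_sd, "noise_sd"),
    annotated_decoy_fraction = check_fraction(annotated_decoy_fraction,
                                              "annotated_decoy_fraction"),
    baseline_range = baseline_range,
    locus_span_bp = check_positive(locus_span_bp, "locus_span_bp"),
    inter_locus_bp = check_positive(inter_locus_bp, "inter_locus_bp"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(n_control) < 1L || is.null(names(n_control)) || any(n_control < 1))
    abort_config("'n_control' must be a named vector of counts >= 1")
  if (length(n_cancer) < 1L || is.null(names(n_cancer)) || any(n_cancer < 1))
    abort_config("'n_cancer' must be a named vector of counts >= 1")
  for (nm in c("tcs_per_locus", "probes_per_tc")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(v < 1) || v[1] > v[2])
      abort_config(sprintf("'%s' must be an increasing count range c(lo, hi)", nm))
  }
  if (!is.numeric(baseline_range) || length(baseline_range) != 2L ||
      baseline_range[1] > baseline_range[2])
    abort_config("'baseline_range' must be c(lo, hi)")
  structure(cfg, class = "simulation_config")
}

# Deterministic genomic layout: loci are anchored every inter_locus_bp on
# cycling synthetic chromosomes chr1..chr4, alternating strand; background
# TCs fill the space between anchors.
synthetic_chroms <- c("chr1", "chr2", "chr3", "chr4")

locus_layout <- function(config) {
  n <- config$n_true_loci
  if (n == 0L)
    return(data.frame(locus_id = character(), chrom = character(),
                      strand = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  i <- seq_len(n)
  chrom <- synthetic_chroms[((i - 1L) %% length(synthetic_chroms)) + 1L]
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  start <- 1e6 + ((i - 1L) %/% length(synthetic_chroms)) * config$inter_locus_bp
  data.frame(locus_id = sprintf("locus_%02d", i), chrom = chrom,
             strand = strand, start = start,
             end = start + config$locus_span_bp, stringsAsFactors = FALSE)
}

#' Generate synthetic expression cohorts with known ground truth
#'
#' Background TC rows are baseline + Gaussian noise in every sample. Member
#' TCs of a true locus additionally receive an `effect_size` log2 shift in
#' a random subset (`outlier_fraction`) of cancer samples; the subset is
#' drawn once per locus and dataset and shared by all member TCs, so the
#' members exhibit one common outlier profile. A fraction of background TCs
#' are annotated decoys, half of which also carry an outlier profile.
#'
#' @param config A [simulation_config()].
#' @return List with `datasets` (list of [expression_dataset()]), `tcs`
#'   (shared [tc_table()]) and `truth` (list: `loci` layout table,
#'   `members` named list locus -> TC ids, `outliers` nested list
#'   dataset -> locus -> outlier sample ids, `decoy_tcs`).
#' @export
generate_expression_datasets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- locus_layout(config)

  # --- shared array design ------------------------------------------------
  set.seed(split_seed(config$seed, 1))
  tc_rows <- list()
  members <- list()
  for (i in seq_len(nrow(layout))) {
    k <- sample(seq(config$tcs_per_locus[1], config$tcs_per_locus[2]), 1)
    # evenly spaced member TCs within the locus span, ~1 kb each
    pos <- layout$start[i] +
      round(seq(0, config$locus_span_bp - 1000, length.out = k))
    ids <- sprintf("%s_tc%d", layout$locus_id[i], seq_len(k))
    tc_rows[[length(tc_rows) + 1L]] <- data.frame(
      tc_id = ids, chrom = layout$chrom[i], start = pos, end = pos + 1000,
      strand = layout$strand[i],
      probe_count = sample(seq(config$probes_per_tc[1], config$probes_per_tc[2]),
                           k, replace = TRUE),
      annotated = FALSE, stringsAsFactors = FALSE)
    members[[layout$locus_id[i]]] <- ids
  }
  n_bg <- config$n_background_tcs
  decoy_ids <- character(0)
  outlier_decoys <- character(0)
  if (n_bg > 0L) {
    i <- seq_len(n_bg)
    chrom <- synthetic_chroms[((i - 1L) %% length(synthetic_chroms)) + 1L]
    # background TCs sit midway between locus anchors, never within
    # max_gap of a true locus or of each other
    start <- 5e7 + ((i - 1L) %/% length(synthetic_chroms)) * config$inter_locus_bp
    bg <- data.frame(
      tc_id = sprintf("bg_tc%04d", i), chrom = chrom, start = start,
      end = start + 1000,
      strand = ifelse(i %% 2L == 0L, "+", "-"),
      probe_count = sample(seq(config$probes_per_tc[1], config$probes_per_tc[2]),
                           n_bg, replace = TRUE),
      annotated = FALSE, stringsAsFactors = FALSE)
    n_decoy <- round(config$annotated_decoy_fraction * n_bg)
    if (n_decoy > 0L) {
      decoy_idx <- sample(i, n_decoy)
      bg$annotated[decoy_idx] <- TRUE
      decoy_ids <- bg$tc_id[decoy_idx]
      # half the decoys mimic a true outlier profile; the annotation flag
      # alone must remove them
      outlier_decoys <- decoy_ids[seq_len(ceiling(n_decoy / 2))]
    }
    tc_rows[[length(tc_rows) + 1L]] <- bg
  }
  tcs <- do.call(rbind, tc_rows)
  tcs <- tc_table(tcs$tc_id, tcs$chrom, tcs$start, tcs$end, tcs$strand,
                  tcs$probe_count, tcs$annotated)

  # --- per-dataset matrices ----------------------------------------------
  groups <- c(config$n_control, config$n_cancer)
  cls <- stats::setNames(
    c(rep("control", length(config$n_control)),
      rep("cancer", length(config$n_cancer))), names(groups))
  datasets <- list()
  outliers <- list()
  for (d in seq_len(config$n_datasets)) {
    set.seed(split_seed(config$seed, 100 + d))
    ds_id <- sprintf("dataset%d", d)
    sample_groups <- stats::setNames(
      rep(names(groups), times = groups),
      sprintf("%s_s%03d", ds_id, seq_len(sum(groups))))
    cancer_ids <- names(sample_groups)[cls[sample_groups] == "cancer"]
    baseline <- stats::runif(nrow(tcs), config$baseline_range[1],
                             config$baseline_range[2])
    m <- matrix(stats::rnorm(nrow(tcs) * length(sample_groups),
                             mean = baseline, sd = config$noise_sd),
                nrow = nrow(tcs), dimnames = list(tcs$tc_id, names(sample_groups)))
    out_d <- list()
    shift_rows <- function(row_ids) {
      n_out <- max(1L, round(config$outlier_fraction * length(cancer_ids)))
      picked <- sample(cancer_ids, n_out)
      m[row_ids, picked] <<- m[row_ids, picked] + config$effect_size
      picked
    }
    for (loc in names(members)) out_d[[loc]] <- sort(shift_rows(members[[loc]]))
    for (tc in outlier_decoys) shift_rows(tc)
    outliers[[ds_id]] <- out_d
    datasets[[ds_id]] <- expression_dataset(ds_id, m, sample_groups, cls)
  }

  list(datasets = datasets, tcs = tcs,
       truth = list(loci = layout, members = members, outliers = outliers,
                    decoy_tcs = decoy_ids))
}

#' Generate known-gene annotation around the true loci
#'
#' Places genes (with a simple two-exon structure) relative to each true
#' locus so that the locus classifies into a requested positional class.
#' `"intergenic"` leaves the locus without overlapping genes.
#'
#' @param config A [simulation_config()].
#' @param classes Character vector of requested classes, recycled over the
#'   true loci; subset of `c("intergenic", "antisense", "overlap_5prime",
#'   "overlap_3prime", "intronic")`.
#' @return List with `genes` (`data.frame`: gene_id, chrom, start, end,
#'   strand) and `exons` (`data.frame`: gene_id, start, end), plus the
#'   per-locus `requested` class vector.
#' @export
generate_annotation <- function(config,
                                classes = c("intergenic", "antisense",
                                            "overlap_5prime", "overlap_3prime",
                                            "intronic")) {
  stopifnot(inherits(config, "simulation_config"))
  bad <- setdiff(classes, c("intergenic", "antisense", "overlap_5prime",
                            "overlap_3prime", "intronic"))
  if (length(bad)) abort_config(paste0("unknown positional class: ", bad[1]))
  layout <- locus_layout(config)
  req <- if (nrow(layout)) rep(classes, length.out = nrow(layout)) else character(0)
  genes <- list(); exons <- list()
  add_gene <- function(id, chrom, start, end, strand) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, chrom = chrom, start = start, end = end, strand = strand,
      stringsAsFactors = FALSE)
    # two terminal exons of 500 bp; everything between is intron
    exons[[length(exons) + 1L]] <<- data.frame(
      gene_id = id, start = c(start, end - 500), end = c(start + 500, end),
      stringsAsFactors = FALSE)
  }
  opp <- function(s) if (s == "+") "-" else "+"
  for (i in seq_along(req)) {
    L <- layout[i, ]
    id <- sprintf("gene_%s", L$locus_id)
    span <- L$end - L$start
    switch(req[i],
      intergenic = NULL,
      antisense = add_gene(id, L$chrom, L$start + span %/% 4,
                           L$end + span, opp(L$strand)),
      overlap_5prime = if (L$strand == "+") {
        # gene 5' end (its start) inside the locus, gene extends beyond
        add_gene(id, L$chrom, L$start + span %/% 2, L$end + 2 * span, "+")
      } else {
        add_gene(id, L$chrom, L$start - 2 * span, L$start + span %/% 2, "-")
      },
      overlap_3prime = if (L$strand == "+") {
        add_gene(id, L$chrom, L$start - 2 * span, L$start + span %/% 2, "+")
      } else {
        add_gene(id, L$chrom, L$start + span %/% 2, L$end + 2 * span, "-")
      },
      intronic = add_gene(id, L$chrom, L$start - span, L$end + span, L$strand)
    )
  }
  list(
    genes = if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), stringsAsFactors = FALSE),
    exons = if (length(exons)) do.call(rbind, exons) else
      data.frame(gene_id = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE),
    requested = stats::setNames(req, layout$locus_id)
  )
}

#' Generate synthetic clinical follow-up
#'
#' Each patient receives a Bernoulli event indicator at the rate of their
#' expression group and an exponential time: scale `scale_event` months for
#' events, `scale_censor` months for censored patients.
#'
#' @param samples Character vector of sample ids.
#' @param high_group_ids Samples in the high-expression group.
#' @param event_rate_high,event_rate_low Event probabilities per group.
#' @param seed Integer seed.
#' @param scale_event,scale_censor Exponential means (months).
#' @return `data.frame`: sample_id, group, event (0/1), time (months > 0).
#' @export
generate_clinical <- function(samples, high_group_ids, event_rate_high,
                              event_rate_low, seed,
                              scale_event = 36, scale_censor = 60) {
  check_fraction(event_rate_high, "event_rate_high")
  check_fraction(event_rate_low, "event_rate_low")
  unknown <- setdiff(high_group_ids, samples)
  if (length(unknown))
    abort_input(paste0("unknown sample id(s): ",
                       paste(utils::head(unknown, 5), collapse = ", ")))
  set.seed(split_seed(seed, 7))
  high <- samples %in% high_group_ids
  rate <- ifelse(high, event_rate_high, event_rate_low)
  event <- as.integer(stats::runif(length(samples)) < rate)
  time <- ifelse(event == 1,
                 stats::rexp(length(samples), 1 / scale_event),
                 stats::rexp(length(samples), 1 / scale_censor))
  data.frame(sample_id = samples, group = ifelse(high, "high", "low"),
             event = event, time = pmax(time, 0.01), stringsAsFactors = FALSE)
}

#' Generate ChIP-seq-like peaks around loci
#'
#' Loci in `hit_ids` receive one peak inside their span (hence inside the
#' flanked window); the others receive a peak well outside
#' `locus +/- flank_bp`.
#'
#' @param loci Locus table (`locus_id`/`name`, `chrom`, `start`, `end`).
#' @param hit_ids Locus ids that must be supported by a peak.
#' @param flank_bp Flank used downstream by [peak_overlap()] (default 50000).
#' @param seed Integer seed.
#' @param peak_width Width of each generated peak (default 500).
#' @return BED-like `data.frame`: chrom, start, end, name.
#' @export
generate_peaks <- function(loci, hit_ids, flank_bp = 50000, seed = 1,
                           peak_width = 500) {
  ids <- loci$locus_id %||% loci$name
  unknown <- setdiff(hit_ids, ids)
  if (length(unknown))
    abort_input(paste0("hit_ids not in loci: ", paste(unknown, collapse = ", ")))
  set.seed(split_seed(seed, 11))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    if (ids[i] %in% hit_ids) {
      s <- round(stats::runif(1, loci$start[i],
                              max(loci$start[i], loci$end[i] - peak_width)))
    } else {
      s <- loci$end[i] + flank_bp + 100000 + round(stats::runif(1, 0, 10000))
    }
    data.frame(chrom = loci$chrom[i], start = s, end = s + peak_width,
               name = sprintf("peak_%s", ids[i]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a per-base conservation track
#'
#' Scores are Gaussian noise around `baseline`; intervals listed in
#' `elevated` have their mean raised to `elevated_value`, emulating
#' conserved elements inside otherwise neutral sequence.
#'
#' @param intervals Interval table (`chrom`, `start`, `end`) to cover.
#' @param baseline Mean background score (default 0).
#' @param sd Per-base score SD (default 0.3).
#' @param elevated Optional interval table of conserved windows.
#' @param elevated_value Mean score inside elevated windows (default 2).
#' @param seed Integer seed.
#' @return A `conservation_track` (see [conservation_track()]), one row per
#'   base.
#' @export
generate_conservation <- function(intervals, baseline = 0, sd = 0.3,
                                  elevated = NULL, elevated_value = 2,
                                  seed = 1) {
  set.seed(split_seed(seed, 13))
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    pos <- seq(intervals$start[i], intervals$end[i] - 1)
    mu <- rep(baseline, length(pos))
    if (!is.null(elevated)) {
      for (j in seq_len(nrow(elevated))) {
        if (elevated$chrom[j] != intervals$chrom[i]) next
        inside <- pos >= elevated$start[j] & pos < elevated$end[j]
        mu[inside] <- elevated_value
      }
    }
    data.frame(chrom = intervals$chrom[i], start = pos, end = pos + 1,
               score = stats::rnorm(length(pos), mu, sd),
               stringsAsFactors = FALSE)
  })
  conservation_track(do.call(rbind, rows))
}
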