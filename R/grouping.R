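#' Group retained transcript clusters into candidate loci
#'
#' Within one dataset, two transcript clusters are linked when they lie on
#' the same chromosome and strand, the gap between their intervals is below
#' `max_gap_bp`, and the Spearman correlation of their COPA score vectors
#' across all samples is at least `min_rho`. Candidate loci are the
#' connected components of this graph (single linkage; singletons allowed).
#'
#' @param tcs Transcript-cluster table restricted to the retained TCs of one
#'   dataset (needs `tc_id`, `chrom`, `start`, `end`, `strand`,
#'   `probe_count`).
#' @param copa_scores Numeric matrix of COPA scores, rows = TC ids (must
#'   cover `tcs$tc_id`), columns = samples.
#' @param max_gap_bp Maximum interval gap in bp (default 250000).
#' @param min_rho Minimum Spearman correlation of outlier profiles
#'   (default 0.5).
#' @param dataset_id Cohort identifier stored on each locus.
#' @return List of `candidate_locus` objects: `dataset_id`, `tc_ids`,
#'   `chrom`, `strand`, `start`, `end`, `probe_total`.
#' @export
group_tcs <- function(tcs, copa_scores, max_gap_bp = 250000, min_rho = 0.5,
                      dataset_id = NA_character_) {
  if (nrow(tcs) == 0L) return(list())
  if (any(is.na(tcs$start)) || any(is.na(tcs$end)))
    abort_input("group_tcs(): missing coordinates")
  missing <- setdiff(tcs$tc_id, rownames(copa_scores))
  if (length(missing))
    abort_input(paste0("group_tcs(): missing COPA scores for ",
                       paste(utils::head(missing, 5), collapse = ", ")))
  check_positive(max_gap_bp, "max_gap_bp")
  n <- nrow(tcs)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1L) {
    # candidate pairs restricted by (chrom, strand) before computing rho
    key <- paste(tcs$chrom, tcs$strand)
    pair_list <- list()
    for (k in unique(key)) {
      idx <- which(key == k)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      gaps <- interval_gap(tcs$start[cmb[1, ]], tcs$end[cmb[1, ]],
                           tcs$start[cmb[2, ]], tcs$end[cmb[2, ]])
      near <- gaps < max_gap_bp
      if (!any(near)) next
      cmb <- cmb[, near, drop = FALSE]
      rho <- vapply(seq_len(ncol(cmb)), function(j) {
        suppressWarnings(stats::cor(copa_scores[tcs$tc_id[cmb[1, j]], ],
                                    copa_scores[tcs$tc_id[cmb[2, j]], ],
                                    method = "spearman"))
      }, numeric(1))
      ok <- !is.na(rho) & rho >= min_rho
      if (any(ok)) pair_list[[length(pair_list) + 1L]] <- t(cmb[, ok, drop = FALSE])
    }
    if (length(pair_list)) edges <- do.call(rbind, pair_list)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(cid) {
    i <- which(comp == cid)
    structure(
      list(dataset_id = dataset_id,
           tc_ids = sort(tcs$tc_id[i]),
           chrom = tcs$chrom[i[1]], strand = tcs$strand[i[1]],
           start = min(tcs$start[i]), end = max(tcs$end[i]),
           probe_total = sum(tcs$probe_count[i])),
      class = "candidate_locus"
    )
  })
}

#' Reconcile candidate loci across datasets into EPCATs
#'
#' Loci from different datasets are linked when their spans overlap by at
#' least 1 bp on the same chromosome and strand. Each connected component
#' detected in at least `min_datasets` distinct datasets becomes one
#' candidate locus (EPCAT) whose member TC set is the union over datasets
#' and whose span is the union span; candidates whose unique member TCs
#' carry fewer than `min_probes` probes in total are removed.
#'
#' @param loci_by_dataset Named list (dataset id -> list of
#'   `candidate_locus` from [group_tcs()]).
#' @param tcs Transcript-cluster table covering all member TCs (used for
#'   probe totals of the union set).
#' @param min_datasets Minimum number of datasets a locus must appear in
#'   (default 2).
#' @param min_probes Minimum total probe count of the merged TC set
#'   (default 12).
#' @return List of `epcat` objects: `name` (unset until [name_epcats()]),
#'   `chrom`, `strand`, `start`, `end`, `tc_ids` (union),
#'   `tc_ids_by_dataset`, `datasets_detected`, `probe_total`.
#' @export
reconcile_datasets <- function(loci_by_dataset, tcs, min_datasets = 2,
                               min_probes = 12) {
  if (length(loci_by_dataset) < 2L)
    abort_input("reconcile_datasets() needs loci from >= 2 datasets")
  for (ds in names(loci_by_dataset)) {
    ids <- unlist(lapply(loci_by_dataset[[ds]], `[[`, "tc_ids"))
    if (anyDuplicated(ids))
      abort_input(sprintf("duplicate tc ids within dataset '%s'", ds))
  }
  flat <- do.call(rbind, lapply(names(loci_by_dataset), function(ds) {
    ll <- loci_by_dataset[[ds]]
    if (!length(ll)) return(NULL)
    data.frame(dataset = ds,
               idx = seq_along(ll),
               chrom = vapply(ll, `[[`, "", "chrom"),
               strand = vapply(ll, `[[`, "", "strand"),
               start = vapply(ll, `[[`, 0, "start"),
               end = vapply(ll, `[[`, 0, "end"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(flat) || nrow(flat) == 0L) return(list())
  n <- nrow(flat)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  key <- paste(flat$chrom, flat$strand)
  edges <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    ov <- intervals_overlap(flat$start[cmb[1, ]], flat$end[cmb[1, ]],
                            flat$start[cmb[2, ]], flat$end[cmb[2, ]])
    if (any(ov)) edges[[length(edges) + 1L]] <- t(cmb[, ov, drop = FALSE])
  }
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  probes <- stats::setNames(tcs$probe_count, tcs$tc_id)
  out <- list()
  for (cid in sort(unique(comp))) {
    i <- which(comp == cid)
    ds_set <- sort(unique(flat$dataset[i]))
    if (length(ds_set) < min_datasets) next
    members_by_ds <- lapply(stats::setNames(ds_set, ds_set), function(ds) {
      sort(unique(unlist(lapply(i[flat$dataset[i] == ds], function(j) {
        loci_by_dataset[[ds]][[flat$idx[j]]]$tc_ids
      }))))
    })
    union_tcs <- sort(unique(unlist(members_by_ds)))
    unknown <- setdiff(union_tcs, names(probes))
    if (length(unknown))
      abort_input(paste0("member TC(s) absent from tc table: ",
                         paste(utils::head(unknown, 5), collapse = ", ")))
    probe_total <- sum(probes[union_tcs])
    if (probe_total < min_probes) next
    out[[length(out) + 1L]] <- structure(
      list(name = NA_character_,
           chrom = flat$chrom[i[1]], strand = flat$strand[i[1]],
           start = min(flat$start[i]), end = max(flat$end[i]),
           tc_ids = union_tcs, tc_ids_by_dataset = members_by_ds,
           datasets_detected = ds_set, probe_total = probe_total,
           positional_class = NA_character_),
      class = "epcat"
    )
  }
  out
}

#' Assign names to candidate loci
#'
#' Names encode chromosome, strand and an ordinal:
#' `EPCAT<chrom><F|R><ordinal>` where `F` marks the forward (+) and `R` the
#' reverse (-) strand, and the ordinal is the zero-padded rank by genomic
#' start within each (chromosome, strand). Deterministic for a given set.
#'
#' @param epcats List of `epcat` objects from [reconcile_datasets()].
#' @param pad Width of the zero-padded ordinal (default 3).
#' @return The same list with `name` fields set, sorted by
#'   (chrom, strand, start).
#' @export
name_epcats <- function(epcats, pad = 3) {
  if (!length(epcats)) return(epcats)
  chrom <- vapply(epcats, `[[`, "", "chrom")
  strand <- vapply(epcats, `[[`, "", "strand")
  start <- vapply(epcats, `[[`, 0, "start")
  ord <- order(chrom, strand, start)
  epcats <- epcats[ord]
  chrom <- chrom[ord]; strand <- strand[ord]; start <- start[ord]
  key <- paste(chrom, strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    lab <- sub("^chr", "", chrom[idx[1]])
    sletter <- if (strand[idx[1]] == "+") "F" else "R"
    for (j in seq_along(idx)) {
      epcats[[idx[j]]]$name <-
        sprintf("EPCAT%s%s%0*d", lab, sletter, as.integer(pad), j)
    }
  }
  epcats
}

#' @export
print.epcat <- function(x, ...) {
  cat(sprintf("<epcat> %s %s:%d-%d(%s) %d TCs, %d probes, datasets: %s%s\n",
              x$name %||% "<unnamed>", x$chrom, x$start, x$end, x$strand,
              length(x$tc_ids), x$probe_total,
              paste(x$datasets_detected, collapse = ","),
              if (is.na(x$positional_class)) "" else paste0(", ", x$positional_class)))
  invisible(x)
}

#' Classify a candidate locus against known-gene annotation
#'
#' Positional classes follow a fixed precedence:
#' 1. `overlap_5prime` — the locus overlaps a same-strand gene and contains
#'    that gene's 5' end (transcription start);
#' 2. `overlap_3prime` — likewise for the 3' end;
#' 3. `intronic` — the locus lies fully inside a same-strand gene body
#'    (the canonical case is residence within a single intron);
#' 4. `antisense` — the locus overlaps only opposite-strand genes;
#' 5. `intergenic` — no gene overlap at all.
#'
#' @param epcat An `epcat` object (or any list with `chrom`, `strand`,
#'   `start`, `end`).
#' @param genes Gene table: `data.frame` with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return One of `"intergenic"`, `"antisense"`, `"overlap_5prime"`,
#'   `"overlap_3prime"`, `"intronic"`.
#' @export
classify_epcat <- function(epcat, genes) {
  if (is.null(genes) || nrow(genes) == 0L) return("intergenic")
  ov <- genes$chrom == epcat$chrom &
    intervals_overlap(genes$start, genes$end, epcat$start, epcat$end)
  if (!any(ov)) return("intergenic")
  hit <- genes[ov, , drop = FALSE]
  same <- hit[hit$strand == epcat$strand, , drop = FALSE]
  if (nrow(same) == 0L) return("antisense")
  # 5' end of a + gene is its start; of a - gene its end (last base end-1).
  p5 <- ifelse(same$strand == "+", same$start, same$end - 1)
  p3 <- ifelse(same$strand == "+", same$end - 1, same$start)
  contains <- function(p) p >= epcat$start & p < epcat$end
  if (any(contains(p5))) return("overlap_5prime")
  if (any(contains(p3))) return("overlap_3prime")
  "intronic"
}

#' Tabulate a list of EPCATs
#'
#' @param epcats List of `epcat` objects.
#' @return `data.frame` with one row per EPCAT (name, chrom, strand, start,
#'   end, n_tcs, n_probes, n_datasets, datasets, class).
#' @export
epcat_table <- function(epcats) {
  if (!length(epcats))
    return(data.frame(name = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), n_tcs = integer(),
                      n_probes = integer(), n_datasets = integer(),
                      datasets = character(), class = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    name = vapply(epcats, `[[`, "", "name"),
    chrom = vapply(epcats, `[[`, "", "chrom"),
    strand = vapply(epcats, `[[`, "", "strand"),
    start = vapply(epcats, `[[`, 0, "start"),
    end = vapply(epcats, `[[`, 0, "end"),
    n_tcs = vapply(epcats, function(e) length(e$tc_ids), 0L),
    n_probes = vapply(epcats, function(e) as.integer(e$probe_total), 0L),
    n_datasets = vapply(epcats, function(e) length(e$datasets_detected), 0L),
    datasets = vapply(epcats, function(e) paste(e$datasets_detected, collapse = ","), ""),
    class = vapply(epcats, function(e) e$positional_class %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
}
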