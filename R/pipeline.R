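#' Discovery driver: from expression datasets to named, classified loci
#'
#' Runs, per dataset: COPA transform, outlier calling, the three TC
#' filters; then grouping into candidate loci, cross-dataset
#' reconciliation, naming, and (when annotation is given) positional
#' classification.
#'
#' @param datasets List of [expression_dataset()] (>= 2).
#' @param tcs Shared [tc_table()].
#' @param genes Optional gene annotation table for classification.
#' @param params Parameter list; defaults are the method's canonical
#'   constants: `min_cancer_outlier_fraction = 0.05`,
#'   `max_gap_bp = 250000`, `min_rho = 0.5`, `min_datasets = 2`,
#'   `min_probes = 12`.
#' @return List: `epcats` (list of `epcat`), `table`
#'   ([epcat_table()] `data.frame`), `retained_by_dataset`,
#'   `loci_by_dataset`.
#' @export
discover_epcats <- function(datasets, tcs, genes = NULL, params = list()) {
  p <- utils::modifyList(list(min_cancer_outlier_fraction = 0.05,
                              max_gap_bp = 250000, min_rho = 0.5,
                              min_datasets = 2, min_probes = 12), params)
  if (length(datasets) < 2L)
    abort_input("discover_epcats() needs >= 2 datasets")
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, "", "dataset_id")
  loci_by_dataset <- list()
  retained_by_dataset <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    calls <- call_outliers(ds)
    retained <- filter_transcript_clusters(
      ds, tcs, calls,
      min_cancer_outlier_fraction = p$min_cancer_outlier_fraction)
    retained_by_dataset[[ds_name]] <- retained
    sub <- tcs[tcs$tc_id %in% retained, , drop = FALSE]
    score_mat <- do.call(rbind, lapply(calls[retained],
                                       function(cl) cl$copa_scores))
    rownames(score_mat) <- retained
    loci_by_dataset[[ds_name]] <- group_tcs(
      sub, score_mat, max_gap_bp = p$max_gap_bp, min_rho = p$min_rho,
      dataset_id = ds_name)
  }
  epcats <- reconcile_datasets(loci_by_dataset, tcs,
                               min_datasets = p$min_datasets,
                               min_probes = p$min_probes)
  epcats <- name_epcats(epcats)
  if (!is.null(genes)) {
    for (i in seq_along(epcats))
      epcats[[i]]$positional_class <- classify_epcat(epcats[[i]], genes)
  }
  list(epcats = epcats, table = epcat_table(epcats),
       retained_by_dataset = retained_by_dataset,
       loci_by_dataset = loci_by_dataset)
}

#' Pipeline configuration
#'
#' A single structured object holding input paths, stage parameters (with
#' the method's canonical defaults baked in) and the root seed. Can be
#' read from / written to JSON.
#'
#' @param expression Named list of per-dataset lists with `matrix` and
#'   `metadata` paths.
#' @param tc_bed Path to the transcript-cluster BED table.
#' @param annotation_bed Optional known-gene BED path.
#' @param peaks_bed Optional ChIP-seq peak BED path.
#' @param conservation_bedgraph Optional bedGraph path.
#' @param clinical_tsv Optional clinical TSV path.
#' @param out_dir Output directory.
#' @param params Stage parameter overrides; defaults:
#'   `max_gap_bp = 250000`, `min_rho = 0.5`,
#'   `min_cancer_outlier_fraction = 0.05`, `min_datasets = 2`,
#'   `min_probes = 12`, `flank_bp = 50000`, `window_bp = 50`,
#'   `n_iter = 10000`, `alpha = 0.05`.
#' @param seed Root seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, tc_bed, annotation_bed = NULL,
                            peaks_bed = NULL, conservation_bedgraph = NULL,
                            clinical_tsv = NULL, out_dir = ".",
                            params = list(), seed = 1) {
  defaults <- list(max_gap_bp = 250000, min_rho = 0.5,
                   min_cancer_outlier_fraction = 0.05, min_datasets = 2,
                   min_probes = 12, flank_bp = 50000, window_bp = 50,
                   n_iter = 10000, alpha = 0.05)
  p <- utils::modifyList(defaults, params)
  for (nm in setdiff(names(defaults), "alpha"))
    check_positive(p[[nm]], nm)
  check_fraction(p$alpha, "alpha", lo_open = TRUE)
  if (length(expression) < 2L)
    abort_config("pipeline needs >= 2 expression datasets")
  structure(
    list(expression = expression, tc_bed = tc_bed,
         annotation_bed = annotation_bed, peaks_bed = peaks_bed,
         conservation_bedgraph = conservation_bedgraph,
         clinical_tsv = clinical_tsv, out_dir = out_dir, params = p,
         seed = check_count(seed, "seed", min = 0L)),
    class = "pipeline_config"
  )
}

#' Run the full pipeline from files
#'
#' Executes discovery (always) and, when the corresponding inputs are
#' configured, regulation peak support, prognosis and conservation stages,
#' writing one TSV/BED per result table plus a log of every stage and
#' parameter. Identical config and seed yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Result bundle: `epcats`, `epcat_table`, optional
#'   `regulation_table`, `prognostic_table`, `conservation_table`, and
#'   `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  # fail before any computation if a configured input is missing
  paths <- c(unlist(config$expression), config$tc_bed, config$annotation_bed,
             config$peaks_bed, config$conservation_bedgraph,
             config$clinical_tsv)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort_input(paste0("missing input file(s): ",
                       paste(missing, collapse = ", ")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  note("seed=%d params: %s", config$seed,
       paste(sprintf("%s=%g", names(p), unlist(p)), collapse = " "))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  tcs <- run_stage("read", read_tc_bed(config$tc_bed))
  datasets <- run_stage("read", {
    out <- lapply(names(config$expression), function(nm) {
      e <- config$expression[[nm]]
      read_matrix(e$matrix, e$metadata, dataset_id = nm)
    })
    stats::setNames(out, names(config$expression))
  })
  genes <- if (!is.null(config$annotation_bed)) {
    g <- read_bed(config$annotation_bed)
    data.frame(gene_id = g$name %||% sprintf("gene%d", seq_len(nrow(g))),
               chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE)
  } else NULL

  disc <- run_stage("discover",
                    discover_epcats(datasets, tcs, genes = genes, params = p))
  note("discover: %d candidate loci", length(disc$epcats))
  write_tsv(disc$table, file.path(config$out_dir, "epcats.tsv"))
  if (nrow(disc$table)) {
    bed <- data.frame(chrom = disc$table$chrom, start = disc$table$start,
                      end = disc$table$end, name = disc$table$name,
                      score = disc$table$n_probes, strand = disc$table$strand)
    write_bed(bed, file.path(config$out_dir, "epcats.bed"))
  }
  result <- list(epcats = disc$epcats, epcat_table = disc$table)

  if (!is.null(config$peaks_bed) && length(disc$epcats)) {
    peaks <- run_stage("regulate", read_bed(config$peaks_bed))
    reg <- data.frame(
      name = disc$table$name,
      peak_support = vapply(disc$epcats, function(e)
        peak_overlap(e, peaks, flank_bp = p$flank_bp), logical(1)))
    write_tsv(reg, file.path(config$out_dir, "regulation.tsv"))
    note("regulate: %d/%d loci with peak support", sum(reg$peak_support),
         nrow(reg))
    result$regulation_table <- reg
  }

  if (!is.null(config$clinical_tsv) && length(disc$epcats)) {
    clin <- run_stage("prognose", read_clinical(config$clinical_tsv))
    ds1 <- datasets[[1]]
    expr <- do.call(rbind, lapply(disc$epcats, function(e)
      epcat_expression(ds1, intersect(e$tc_ids, rownames(ds1$matrix)))))
    rownames(expr) <- disc$table$name
    endpoints <- sub("_event$", "",
                     grep("_event$", names(clin), value = TRUE))
    if (!length(endpoints)) endpoints <- "event"
    prog <- run_stage("prognose",
                      prognostic_screen(expr, clin, endpoints = endpoints,
                                        n_iter = p$n_iter, seed = config$seed))
    write_tsv(prog, file.path(config$out_dir, "prognosis.tsv"))
    note("prognose: %d tests", nrow(prog))
    result$prognostic_table <- prog
  }

  if (!is.null(config$conservation_bedgraph) && length(disc$epcats)) {
    track <- run_stage("conserve", read_bedgraph(config$conservation_bedgraph))
    cons <- data.frame(
      name = disc$table$name,
      score = vapply(disc$epcats, function(e) {
        locus_conservation_score(
          data.frame(chrom = e$chrom, start = e$start, end = e$end),
          track, window_bp = p$window_bp)
      }, numeric(1)))
    write_tsv(cons, file.path(config$out_dir, "conservation.tsv"))
    note("conserve: %d loci scored", nrow(cons))
    result$conservation_table <- cons
  }

  result$log <- log
  writeLines(log, file.path(config$out_dir, "pipeline.log"))
  result
}
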