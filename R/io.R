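# File formats: TSV matrices and metadata, BED (0-based half-open, strand
# honored), bedGraph. Coordinates are kept in the BED convention
# internally, so disk round-trips involve no shifting.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write records as TSV
#'
#' @param records `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' Accepts 3-6 columns (chrom, start, end, name, score, strand); start and
#' end are 0-based half-open. Malformed lines are reported with their line
#' number.
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  ncols <- lengths(rows)
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  if (any(ncols < 3L))
    abort_input(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                        lineno[which(ncols < 3L)[1]], path))
  n <- min(ncols)
  get <- function(i) vapply(rows, `[[`, "", i)
  df <- data.frame(chrom = get(1), start = suppressWarnings(as.numeric(get(2))),
                   end = suppressWarnings(as.numeric(get(3))),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    abort_input(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                        lineno[bad[1]], path))
  bad <- which(df$start >= df$end)
  if (length(bad))
    abort_input(sprintf("BED line %d in %s: start >= end",
                        lineno[bad[1]], path))
  if (n >= 4L) df$name <- get(4)
  if (n >= 5L) df$score <- suppressWarnings(as.numeric(get(5)))
  if (n >= 6L) {
    df$strand <- get(6)
    if (!all(df$strand %in% c("+", "-", ".")))
      abort_input(sprintf("invalid strand in %s", path))
  }
  df
}

#' Write intervals as BED
#'
#' @param df `data.frame` with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(df)) cols <- c(cols, "name")
  if ("score" %in% names(df) && "name" %in% names(df)) cols <- c(cols, "score")
  if ("strand" %in% names(df) && all(c("name", "score") %in% cols))
    cols <- c(cols, "strand")
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph conservation track
#'
#' @param path bedGraph path (chrom, start, end, score; 0-based half-open).
#' @return A [conservation_track()].
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path)
  if (!"name" %in% names(df))
    abort_input(sprintf("bedGraph %s needs 4 columns", path))
  df$score <- suppressWarnings(as.numeric(df$name))
  if (any(is.na(df$score)))
    abort_input(sprintf("non-numeric score in bedGraph %s", path))
  conservation_track(df[, c("chrom", "start", "end", "score")])
}

#' Write a conservation track as bedGraph
#'
#' @param track A [conservation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- as.data.frame(track)
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its sample metadata
#'
#' The matrix TSV has TC ids in the first column and sample ids as header;
#' the metadata TSV maps `sample_id` to `group` and `class`
#' (`control`/`cancer`). Every matrix column must appear in the metadata.
#'
#' @param matrix_path,metadata_path File paths.
#' @param dataset_id Cohort identifier (default: matrix file name).
#' @return An [expression_dataset()].
#' @export
read_matrix <- function(matrix_path, metadata_path,
                        dataset_id = basename(matrix_path)) {
  raw <- read_tsv_checked(matrix_path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  meta <- read_tsv_checked(metadata_path)
  need <- c("sample_id", "group", "class")
  if (!all(need %in% names(meta)))
    abort_input(sprintf("metadata %s needs columns %s", metadata_path,
                        paste(need, collapse = ", ")))
  groups <- stats::setNames(meta$group, meta$sample_id)
  classes <- stats::setNames(meta$class, meta$group)
  classes <- classes[!duplicated(names(classes))]
  expression_dataset(dataset_id, m, groups, classes)
}

#' Write an expression dataset to TSV (matrix + metadata)
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_matrix <- function(dataset, matrix_path, metadata_path) {
  df <- data.frame(tc_id = rownames(dataset$matrix), dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  meta <- data.frame(sample_id = names(dataset$sample_groups),
                     group = unname(dataset$sample_groups),
                     class = unname(dataset$group_classes[dataset$sample_groups]),
                     stringsAsFactors = FALSE)
  write_tsv(meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Read a clinical follow-up table
#'
#' Requires `sample_id` plus, per endpoint, `<endpoint>_event` (0/1) and
#' `<endpoint>_time` (> 0), or a single `event`/`time` pair.
#'
#' @param path TSV path.
#' @return Validated `data.frame`.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path)
  if (!"sample_id" %in% names(df))
    abort_input(sprintf("clinical table %s needs a sample_id column", path))
  ev_cols <- grep("(^|_)event$", names(df), value = TRUE)
  if (!length(ev_cols))
    abort_input(sprintf("clinical table %s has no event column", path))
  for (ec in ev_cols) {
    if (!all(df[[ec]] %in% c(0, 1)))
      abort_input(sprintf("column %s must be 0/1 in %s", ec, path))
    tc <- sub("event$", "time", ec)
    if (tc %in% names(df) && any(df[[tc]] <= 0))
      abort_input(sprintf("column %s must be > 0 in %s", tc, path))
  }
  df
}

#' Write transcript-cluster coordinates as a BED-like table
#'
#' Six BED columns (name = tc_id, score = probe_count) plus an `annotated`
#' 7th column; [read_tc_bed()] reads it back losslessly.
#'
#' @param tcs A [tc_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tc_bed <- function(tcs, path) {
  out <- data.frame(chrom = tcs$chrom,
                    start = format(tcs$start, scientific = FALSE, trim = TRUE),
                    end = format(tcs$end, scientific = FALSE, trim = TRUE),
                    name = tcs$tc_id, score = tcs$probe_count,
                    strand = tcs$strand,
                    annotated = as.integer(tcs$annotated))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript clusters written by [write_tc_bed()]
#'
#' @param path File path.
#' @return A [tc_table()].
#' @export
read_tc_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 7L)
    abort_input(sprintf("TC BED %s needs 7 columns", path))
  names(df)[1:7] <- c("chrom", "start", "end", "name", "score", "strand",
                      "annotated")
  tc_table(df$name, df$chrom, df$start, df$end, df$strand, df$score,
           df$annotated == 1)
}
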