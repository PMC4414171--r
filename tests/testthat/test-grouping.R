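score_rows <- function(tcs, rho_perfect = TRUE, n = 20, seed = 1) {
  set.seed(seed)
  base <- rnorm(n)
  m <- t(vapply(seq_len(nrow(tcs)), function(i) {
    if (rho_perfect) base + i else rnorm(n)
  }, numeric(n)))
  rownames(m) <- tcs$tc_id
  m
}

test_that("group_tcs applies gap and strand rules (hand example)", {
  tcs <- data.frame(tc_id = c("a", "b", "c"), chrom = "chr2",
                    start = c(1000, 100000, 400000),
                    end = c(2000, 101000, 401000),
                    strand = "+", probe_count = 5, annotated = FALSE,
                    stringsAsFactors = FALSE)
  loci <- group_tcs(tcs, score_rows(tcs), max_gap_bp = 250000, min_rho = 0.5)
  expect_length(loci, 2L)
  expect_identical(
    sort(vapply(loci, function(l) paste(l$tc_ids, collapse = ","), "")),
    c("a,b", "c"))

  # opposite strands never share a locus even at zero gap
  tcs$strand <- c("+", "-", "+")
  loci2 <- group_tcs(tcs[1:2, ], score_rows(tcs[1:2, ]))
  expect_length(loci2, 2L)
})

test_that("grouping equals the union-find oracle on random instances", {
  set.seed(21)
  for (rep in 1:30) {
    tcs <- random_tcs(sample(10:40, 1))
    scores <- score_rows(tcs, rho_perfect = FALSE, seed = rep)
    gap <- sample(c(5e4, 2e5, 5e5), 1)
    rho <- sample(c(-0.2, 0.2, 0.5), 1)
    loci <- group_tcs(tcs, scores, max_gap_bp = gap, min_rho = rho)
    comp <- oracle_group(tcs, scores, gap, rho)
    impl_parts <- sort(vapply(loci, function(l) paste(l$tc_ids, collapse = ","), ""))
    orc_parts <- sort(vapply(split(tcs$tc_id, comp),
                             function(ids) paste(sort(ids), collapse = ","), ""))
    expect_identical(impl_parts, unname(orc_parts))
  }
})

test_that("grouping is a partition, order-invariant, and monotone in its thresholds", {
  set.seed(22)
  tcs <- random_tcs(25)
  scores <- score_rows(tcs, rho_perfect = FALSE, seed = 99)
  loci <- group_tcs(tcs, scores)
  expect_setequal(unlist(lapply(loci, `[[`, "tc_ids")), tcs$tc_id)

  perm <- sample(nrow(tcs))
  loci_p <- group_tcs(tcs[perm, ], scores)
  expect_setequal(
    vapply(loci, function(l) paste(l$tc_ids, collapse = ","), ""),
    vapply(loci_p, function(l) paste(l$tc_ids, collapse = ","), ""))

  sizes <- function(ll) sort(lengths(lapply(ll, `[[`, "tc_ids")))
  loose <- group_tcs(tcs, scores, max_gap_bp = 1e6, min_rho = -1)
  expect_true(length(loose) <= length(loci))
})

test_that("reconcile_datasets merges overlapping spans and enforces both minimums", {
  tcs <- tc_table(c("x1", "x2", "y1"), "chr2", c(1.0e6, 1.15e6, 1.1e6),
                  c(1.2e6, 1.25e6, 1.3e6), "+", c(6, 6, 6), FALSE)
  lc <- function(ds, ids, s, e) structure(
    list(dataset_id = ds, tc_ids = ids, chrom = "chr2", strand = "+",
         start = s, end = e, probe_total = 6 * length(ids)),
    class = "candidate_locus")
  eps <- reconcile_datasets(
    list(A = list(lc("A", c("x1", "x2"), 1.0e6, 1.25e6)),
         B = list(lc("B", "y1", 1.1e6, 1.3e6))), tcs)
  expect_length(eps, 1L)
  expect_equal(eps[[1]]$start, 1.0e6)
  expect_equal(eps[[1]]$end, 1.3e6)
  expect_setequal(eps[[1]]$tc_ids, c("x1", "x2", "y1"))
  expect_equal(eps[[1]]$probe_total, 18)

  # single-dataset locus never becomes an EPCAT
  eps1 <- reconcile_datasets(
    list(A = list(lc("A", "x1", 1.0e6, 1.2e6)), B = list()), tcs)
  expect_length(eps1, 0L)

  # probe boundary: 11 removed, 12 kept
  tcs11 <- tc_table(c("x1", "y1"), "chr2", c(1.0e6, 1.1e6),
                    c(1.2e6, 1.3e6), "+", c(5, 6), FALSE)
  both <- list(A = list(lc("A", "x1", 1.0e6, 1.2e6)),
               B = list(lc("B", "y1", 1.1e6, 1.3e6)))
  expect_length(reconcile_datasets(both, tcs11), 0L)
  tcs12 <- tc_table(c("x1", "y1"), "chr2", c(1.0e6, 1.1e6),
                    c(1.2e6, 1.3e6), "+", c(6, 6), FALSE)
  expect_length(reconcile_datasets(both, tcs12), 1L)

  # min_datasets = 1 yields a superset of spans
  eps_all <- reconcile_datasets(both, tcs12, min_datasets = 1)
  expect_true(length(eps_all) >= length(reconcile_datasets(both, tcs12)))

  dup <- list(A = list(lc("A", c("x1", "x1"), 1.0e6, 1.2e6)),
              B = list(lc("B", "y1", 1.1e6, 1.3e6)))
  expect_error(reconcile_datasets(dup, tcs12), "duplicate")
})

test_that("name_epcats encodes chromosome and strand and is deterministic", {
  ep <- function(chrom, strand, start) structure(
    list(name = NA, chrom = chrom, strand = strand, start = start,
         end = start + 1000, tc_ids = "t", tc_ids_by_dataset = list(),
         datasets_detected = c("A", "B"), probe_total = 12,
         positional_class = NA_character_), class = "epcat")
  eps <- list(ep("chr2", "+", 5e6), ep("chr2", "+", 1e6),
              ep("chrX", "-", 2e6))
  named <- name_epcats(eps)
  nm <- vapply(named, `[[`, "", "name")
  expect_identical(nm, c("EPCAT2F001", "EPCAT2F002", "EPCATXR001"))
  expect_true(startsWith(nm[3], "EPCATXR"))
  # naming the same set twice gives identical names
  expect_identical(vapply(name_epcats(eps), `[[`, "", "name"), nm)
  # ordinal follows genomic start
  expect_equal(named[[1]]$start, 1e6)
})

test_that("classify_epcat matches definitions and the interval-logic oracle", {
  ep <- list(chrom = "chr1", strand = "+", start = 5000, end = 6000)
  intron_gene <- data.frame(gene_id = "g", chrom = "chr1", start = 1000,
                            end = 20000, strand = "+", stringsAsFactors = FALSE)
  expect_identical(classify_epcat(ep, intron_gene), "intronic")
  anti <- transform(intron_gene, strand = "-")
  expect_identical(classify_epcat(ep, anti), "antisense")
  expect_identical(classify_epcat(ep, intron_gene[0, ]), "intergenic")

  set.seed(23)
  for (i in 1:120) {
    ep <- list(chrom = "chr1", strand = sample(c("+", "-"), 1),
               start = s <- sample.int(1e5, 1), end = s + sample.int(5e4, 1))
    ng <- sample(0:4, 1)
    genes <- data.frame(
      gene_id = sprintf("g%d", seq_len(ng)),
      chrom = sample(c("chr1", "chr2"), max(ng, 1), replace = TRUE)[seq_len(ng)],
      start = gs <- sample.int(1.5e5, ng), end = gs + sample.int(8e4, ng),
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
    expect_identical(classify_epcat(ep, genes), oracle_classify(ep, genes))
  }
})

test_that("annotation generator places genes yielding the requested classes", {
  cfg <- simulation_config(seed = 5, n_true_loci = 5, n_background_tcs = 0)
  classes <- c("intergenic", "antisense", "overlap_5prime", "overlap_3prime",
               "intronic")
  ann <- generate_annotation(cfg, classes = classes)
  layout <- ann$requested
  sim <- generate_expression_datasets(cfg)
  got <- vapply(seq_len(nrow(sim$truth$loci)), function(i) {
    L <- sim$truth$loci[i, ]
    classify_epcat(list(chrom = L$chrom, strand = L$strand,
                        start = L$start, end = L$end), ann$genes)
  }, character(1))
  expect_identical(unname(got), unname(layout))
  # no genes -> everything intergenic
  ann0 <- generate_annotation(cfg, classes = "intergenic")
  expect_equal(nrow(ann0$genes), 0L)
})
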