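# Independent brute-force oracles. These re-derive each quantity from its
# definition by a different route than the implementation and are kept
# deliberately naive.

# COPA transform + outlier mask from the literal formulas.
oracle_copa <- function(x) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  dev <- abs(x - med)
  sdev <- sort(dev)
  m <- if (length(x) %% 2 == 0) {
    (sdev[length(x) / 2] + sdev[length(x) / 2 + 1]) / 2
  } else sdev[ceiling(length(x) / 2)]
  if (m == 0) return(list(scores = rep(0, length(x)), mask = rep(FALSE, length(x))))
  scores <- (x - med) / m
  dev2 <- abs(scores - median(scores))
  m2 <- median(dev2)
  thr <- 2 * m2 / 0.6745
  list(scores = scores, mask = scores > thr, threshold = thr)
}

# Union-find over the all-pairs edge predicate.
oracle_group <- function(tcs, scores, max_gap, min_rho) {
  n <- nrow(tcs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (tcs$chrom[i] != tcs$chrom[j] || tcs$strand[i] != tcs$strand[j]) next
    gap <- max(0, max(tcs$start[i], tcs$start[j]) - min(tcs$end[i], tcs$end[j]))
    if (gap >= max_gap) next
    rho <- suppressWarnings(cor(scores[tcs$tc_id[i], ], scores[tcs$tc_id[j], ],
                                method = "spearman"))
    if (is.na(rho) || rho < min_rho) next
    parent[find(i)] <- find(j)
  }
  vapply(seq_len(n), find, integer(1))
}

# Positional classification from first principles interval logic.
oracle_classify <- function(ep, genes) {
  if (nrow(genes) == 0) return("intergenic")
  ov <- which(genes$chrom == ep$chrom &
                genes$start < ep$end & ep$start < genes$end)
  if (!length(ov)) return("intergenic")
  same <- ov[genes$strand[ov] == ep$strand]
  if (!length(same)) return("antisense")
  for (g in same) {
    p5 <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g] - 1
    if (p5 >= ep$start && p5 < ep$end) return("overlap_5prime")
  }
  for (g in same) {
    p3 <- if (genes$strand[g] == "+") genes$end[g] - 1 else genes$start[g]
    if (p3 >= ep$start && p3 < ep$end) return("overlap_3prime")
  }
  "intronic"
}

# AUC by explicit counting over all (case, control) pairs.
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Textbook BH step-up: q_i = min over j >= i of p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  q[order(o)]
}

# Max 50 bp window mean with explicit loops (concatenated exon bases).
oracle_conservation <- function(scores, window, min_tail) {
  n <- length(scores)
  bounds <- list()
  k <- n %/% window
  if (k == 0) {
    bounds[[1]] <- c(1, n)
  } else {
    for (i in seq_len(k)) bounds[[i]] <- c((i - 1) * window + 1, i * window)
    tail_len <- n - k * window
    if (tail_len >= min_tail) {
      bounds[[k + 1]] <- c(k * window + 1, n)
    } else if (tail_len > 0) {
      bounds[[k]][2] <- n
    }
  }
  means <- vapply(bounds, function(b) {
    v <- scores[b[1]:b[2]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(means))) NA_real_ else max(means, na.rm = TRUE)
}

# Small random TC table on a handful of chromosomes.
random_tcs <- function(n, n_chrom = 2) {
  start <- sample.int(2e6, n)
  data.frame(
    tc_id = sprintf("tc%03d", seq_len(n)),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    start = start, end = start + sample.int(5e4, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    probe_count = sample(4:10, n, replace = TRUE),
    annotated = FALSE, stringsAsFactors = FALSE)
}

# Minimal two-dataset world for grouping/reconciliation tests.
tiny_simulation <- function(seed = 1, ...) {
  cfg <- simulation_config(seed = seed, n_background_tcs = 60,
                           n_true_loci = 3, ...)
  generate_expression_datasets(cfg)
}
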