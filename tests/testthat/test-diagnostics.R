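test_that("empirical_auc matches the all-pairs oracle and its invariants", {
  expect_equal(empirical_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_equal(empirical_auc(rep(5, 8), rep(c(F, T), 4)), 0.5)
  expect_error(empirical_auc(1:3, rep(TRUE, 3)), "both classes")

  set.seed(51)
  for (i in 1:120) {
    n <- sample(6:40, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
    s <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    auc <- empirical_auc(s, pos)
    expect_equal(auc, oracle_auc(s, pos), tolerance = 1e-12)
    # complement and monotone-transform invariance
    expect_equal(empirical_auc(-s, pos) + auc, 1, tolerance = 1e-12)
    expect_equal(empirical_auc(exp(s), pos), auc, tolerance = 1e-12)
  }
})

test_that("optimize_panel_weights never loses to the best single marker", {
  set.seed(52)
  for (i in 1:8) {
    n <- 40; p <- sample(2:4, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
    pos <- rep(c(TRUE, FALSE), each = n / 2)
    x[pos, 1] <- x[pos, 1] + runif(1, 0, 2)  # one informative marker
    w <- optimize_panel_weights(x, pos, seed = i)
    single <- max(vapply(seq_len(p), function(j)
      max(empirical_auc(x[, j], pos), empirical_auc(-x[, j], pos)),
      numeric(1)))
    single_raw <- max(vapply(seq_len(p), function(j)
      empirical_auc(x[, j], pos), numeric(1)))
    expect_gte(attr(w, "train_auc"), single_raw - 1e-9)
  }
})

test_that("panel weights are deterministic and beat complementary singles", {
  set.seed(53)
  n <- 60
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  # two markers, individually weak, complementary in combination
  z <- rnorm(n)
  m1 <- z + ifelse(pos, 0.9, 0) + rnorm(n, 0, 0.4)
  m2 <- -z + ifelse(pos, 0.9, 0) + rnorm(n, 0, 0.4)
  x <- cbind(m1 = m1, m2 = m2)
  w1 <- optimize_panel_weights(x, pos, seed = 4)
  w2 <- optimize_panel_weights(x, pos, seed = 4)
  expect_identical(w1, w2)
  singles <- c(empirical_auc(m1, pos), empirical_auc(m2, pos))
  expect_gt(attr(w1, "train_auc"), max(singles))
  # grid-search oracle over 2-D directions confirms near-optimality
  grid <- seq(0, pi, length.out = 721)
  grid_best <- max(vapply(grid, function(a)
    empirical_auc(x %*% c(cos(a), sin(a)), pos), numeric(1)))
  expect_gte(attr(w1, "train_auc"), grid_best - 0.02)
})

test_that("apply_panel reproduces training AUC on the training set and checks names", {
  set.seed(54)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  pos <- rep(c(TRUE, FALSE), 20)
  x[pos, 1] <- x[pos, 1] + 1.5
  w <- optimize_panel_weights(x, pos, seed = 1)
  expect_equal(apply_panel(w, x, pos), attr(w, "train_auc"), tolerance = 1e-12)
  colnames(x) <- c("a", "zz")
  expect_error(apply_panel(w, x, pos), "match")
})

test_that("validation AUC is ~0.5 under shuffled labels", {
  set.seed(55)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  pos <- rep(c(TRUE, FALSE), 50)
  x[pos, ] <- x[pos, ] + 1
  w <- optimize_panel_weights(x[1:50, ], pos[1:50], seed = 2)
  aucs <- replicate(50, apply_panel(w, x[51:100, ], sample(pos[51:100])))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("binary_panel_metrics counts positives per the score > 0 rule", {
  tab <- data.frame(
    tissue = c(rep("PCa", 4), rep("normal", 4)),
    A = c(1, 2, 0, 0, 0, 0, 0, 0),
    B = c(0, 3, 1, 0, 0, 0, 0, 0))
  res <- binary_panel_metrics(tab, c("A", "B"), "PCa", "normal")
  expect_equal(unname(res$per_marker_sensitivity), c(0.5, 0.5))
  expect_equal(res$combined_sensitivity, 3 / 4)  # union of {1,2} and {2,3}
  expect_equal(res$specificity, 1)
  expect_equal(res$auc, (3 / 4 + 1) / 2)  # binary AUC = (sens + spec) / 2

  expect_error(binary_panel_metrics(tab, "A", character(0), "normal"),
               "non-empty")
  set.seed(56)
  for (i in 1:30) {
    tab <- data.frame(
      tissue = sample(c("PCa", "NAP"), 30, replace = TRUE),
      A = rpois(30, 0.5), B = rpois(30, 0.5))
    if (!any(tab$tissue == "PCa") || !any(tab$tissue == "NAP")) next
    res <- binary_panel_metrics(tab, c("A", "B"), "PCa", "NAP")
    cases <- tab[tab$tissue == "PCa", ]; ctrl <- tab[tab$tissue == "NAP", ]
    sens <- mean(cases$A > 0 | cases$B > 0)
    spec <- mean(!(ctrl$A > 0 | ctrl$B > 0))
    expect_equal(res$combined_sensitivity, sens)
    expect_equal(res$specificity, spec)
    expect_gte(res$combined_sensitivity,
               max(res$per_marker_sensitivity) - 1e-12)
    expect_equal(res$auc, (sens + spec) / 2, tolerance = 1e-12)
  }
})

test_that("fisher_exact equals full enumeration and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")

  set.seed(57)
  for (i in 1:120) {
    tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("positivity_rate reproduces printed staining percentages", {
  expect_equal(positivity_rate(46, 73, 1), 63.0)
  expect_equal(positivity_rate(16, 71, 1), 22.5)
  expect_equal(positivity_rate(12, 113, 2), 10.62)
  expect_equal(positivity_rate(0, 50, 1), 0)
  expect_error(positivity_rate(1, 0), "n_total")
  expect_error(positivity_rate(5, 3), "n_positive")
})

test_that("roc_points trace the empirical ROC", {
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  pts <- roc_points(s, pos)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
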