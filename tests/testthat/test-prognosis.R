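test_that("pam_two_groups separates clusters and matches the exhaustive optimum", {
  v <- setNames(c(0, 0.1, 0.2, 10, 10.1), paste0("s", 1:5))
  lab <- pam_two_groups(v)
  expect_identical(unname(lab), c("low", "low", "low", "high", "high"))

  expect_error(pam_two_groups(rep(2, 6)), "all values equal")
  expect_error(pam_two_groups(c(1, 2, 3)), "4 samples")

  # implementation cost equals the brute-force optimum over all medoid pairs
  set.seed(41)
  for (i in 1:25) {
    x <- c(rnorm(sample(3:10, 1), 0, 1), rnorm(sample(3:10, 1), 6, 1))
    lab <- pam_two_groups(setNames(x, seq_along(x)))
    medoid_cost <- function(m) sum(pmin(abs(x - m[1]), abs(x - m[2])))
    # optimal cost by full enumeration
    best <- Inf
    for (a in seq_along(x)) for (b in seq_along(x)) {
      if (a >= b || x[a] == x[b]) next
      best <- min(best, medoid_cost(sort(c(x[a], x[b]))))
    }
    # recompute the implementation's achieved cost from its labels
    cost_of_split <- function(lab) {
      lo <- x[lab == "low"]; hi <- x[lab == "high"]
      best_med <- function(v) min(vapply(v, function(m) sum(abs(v - m)), 1))
      best_med(lo) + best_med(hi)
    }
    expect_equal(cost_of_split(lab), best, tolerance = 1e-9)
  }
})

test_that("pam_two_groups agrees with cluster::pam on separated data", {
  skip_if_not_installed("cluster")
  set.seed(42)
  for (i in 1:10) {
    x <- setNames(c(rnorm(8, 0, 0.5), rnorm(7, 5, 0.5)), 1:15)
    lab <- pam_two_groups(x)
    ref <- cluster::pam(x, k = 2, metric = "manhattan")$clustering
    # align cluster ids by mean value
    hi_ref <- names(ref)[ref == ref[which.max(x)]]
    expect_setequal(names(lab)[lab == "high"], hi_ref)
  }
})

test_that("duplicated values partition consistently by value", {
  v <- setNames(c(0, 0.1, 5, 5.1), paste0("a", 1:4))
  v2 <- setNames(rep(c(0, 0.1, 5, 5.1), 2), paste0("b", 1:8))
  l1 <- pam_two_groups(v); l2 <- pam_two_groups(v2)
  expect_identical(unname(l2[1:4]), unname(l1))
  expect_identical(unname(l2[5:8]), unname(l1))
})

test_that("bootstrap_association matches the exact hypergeometric tail", {
  labels <- rep(c("high", "low"), each = 5)
  events <- c(rep(1, 5), rep(0, 5))
  res <- bootstrap_association(labels, events, n_iter = 20000, seed = 2)
  exact <- phyper(4, 5, 5, 5, lower.tail = FALSE)  # P(X >= 5) = 1/C(10,5)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_equal(res$observed, 5)
  expect_lt(abs(res$p - exact), 3 * se + 1e-6)

  # zero events: every permutation ties the observed 0 -> p = 1
  none <- bootstrap_association(labels, rep(0, 10), n_iter = 500, seed = 3)
  expect_equal(none$p, 1)

  expect_error(bootstrap_association(labels, events, n_iter = 0), "n_iter")
  expect_error(bootstrap_association(labels[1:3], events), "aligned")
})

test_that("bootstrap_association is invariant to sample relabeling and seeded", {
  set.seed(43)
  labels <- sample(rep(c("high", "low"), c(20, 34)))
  events <- rbinom(54, 1, 0.3)
  a <- bootstrap_association(labels, events, n_iter = 2000, seed = 9)
  b <- bootstrap_association(labels, events, n_iter = 2000, seed = 9)
  expect_identical(a, b)
  # permuting patient order together leaves the distribution unchanged
  perm <- sample(54)
  c_ <- bootstrap_association(labels[perm], events[perm], n_iter = 2000, seed = 9)
  expect_equal(c_$observed, a$observed)
})

test_that("fdr_bh reproduces the step-up procedure", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")

  set.seed(44)
  for (i in 1:60) {
    p <- runif(sample(1:40, 1))
    q <- fdr_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("km_logrank matches a hand-computed product-limit table", {
  # high: times 1,2,3,4,5 events 1,0,1,1,0; low: 2,4,6,8,10 events 1,1,0,1,0
  times <- c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10)
  events <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 0)
  groups <- rep(c("high", "low"), each = 5)
  res <- km_logrank(times, events, groups)
  hi <- res$curves[res$curves$group == "high" & res$curves$n_event > 0, ]
  expect_equal(hi$survival, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  lo <- res$curves[res$curves$group == "low" & res$curves$n_event > 0, ]
  expect_equal(lo$survival, c(4 / 5, 4 / 5 * 3 / 4, 4 / 5 * 3 / 4 * 1 / 2),
               tolerance = 1e-12)
  expect_true(res$p >= 0 && res$p <= 1)
  # curves are nonincreasing step functions starting at 1
  for (g in c("high", "low")) {
    s <- res$curves$survival[res$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
})

test_that("km_logrank degenerate conventions", {
  times <- c(1, 2, 3, 4, 5, 6)
  groups <- rep(c("high", "low"), each = 3)
  expect_warning(res <- km_logrank(times, rep(0, 6), groups), "no events")
  expect_equal(res$p, 1)
  expect_true(all(res$curves$survival == 1))

  # identical groups duplicated: statistic 0, p = 1
  same <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1), groups)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  expect_error(km_logrank(c(0, 1, 2), c(1, 0, 1), c("high", "low", "low")),
               "> 0")
  expect_error(km_logrank(c(1, 2), c(1, 0), c("high", "high")), "non-empty")
})

test_that("prognostic_screen ties the pieces together on simulated truth", {
  set.seed(45)
  n <- 54
  samples <- sprintf("p%02d", 1:n)
  expr <- rbind(
    marker = c(rnorm(18, 8, 0.3), rnorm(n - 18, 4, 0.3)),
    noise = rnorm(n, 6, 0.3))
  colnames(expr) <- samples
  high_ids <- samples[1:18]
  clin <- generate_clinical(samples, high_ids, 0.9, 0.05, seed = 6)
  clinical <- data.frame(sample_id = samples,
                         PCaD_event = clin$event, PCaD_time = clin$time)
  res <- prognostic_screen(expr, clinical, endpoints = "PCaD",
                           n_iter = 2000, seed = 8)
  expect_lt(res$perm_p[res$name == "marker"], 0.01)
  expect_gt(res$perm_p[res$name == "noise"], 0.05)
  expect_true(all(res$q_value >= res$perm_p - 1e-12))
})
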