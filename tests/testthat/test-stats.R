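# Cohort statistics: Spearman, Bland-Altman, rank tests, the correlation
# table and the median/IQR summary.

test_that("Spearman correlation is +-1 on monotone pairs", {
  x <- c(3, 7, 9, 15, 21)
  y <- exp(x / 5)
  expect_equal(spearman_cor(x, y)$r, 1)
  expect_equal(spearman_cor(x, rev(y))$r, -1)
  expect_error(spearman_cor(x, rep(1, 5)), class = "lungvent_value_error")
})

test_that("ties are handled by midranks", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  # midrank oracle: Pearson correlation on midranks, computed from scratch
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(x, y)$r, oracle)
  expect_equal(oracle, 0.9486833, tolerance = 1e-6)
})

test_that("Bland-Altman closed forms hold", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)  # d = (1, 2, 3), SD = 1
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_bias, 2)
  expect_equal(ba$loa_low, 0.04)
  expect_equal(ba$loa_high, 3.96)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * stats::sd(x - y))
  # identical methods
  same <- bland_altman(y, y)
  expect_equal(same$mean_bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  expect_equal(same$p_paired, 1)
  expect_match(same$note, "zero")
})

test_that("mean bias is the difference of means on random pairs", {
  set.seed(12)
  for (i in 1:10) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    ba <- bland_altman(x, y)
    expect_equal(ba$mean_bias, mean(x) - mean(y))
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * stats::sd(x - y))
  }
})

test_that("rank-sum p matches exhaustive enumeration for small samples", {
  # independent oracle: enumerate all assignments of the pooled sample
  enum_p <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    w_obs <- sum(r[seq_along(a)])
    combs <- utils::combn(length(pooled), length(a))
    ws <- apply(combs, 2, function(ix) sum(r[ix]))
    mu <- mean(ws)
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  expect_equal(wilcoxon_rank_sum(a, b), 0.1)
  expect_equal(enum_p(a, b), 0.1)
  set.seed(3)
  for (i in 1:8) {
    a <- round(stats::rnorm(sample(3:5, 1)), 4)
    b <- round(stats::rnorm(sample(3:6, 1)) + 0.5, 4)
    expect_equal(wilcoxon_rank_sum(a, b), enum_p(a, b))
  }
})

test_that("rank-sum p is 1 for identical multisets and rank-invariant", {
  a <- c(1, 2, 2, 5)
  expect_equal(wilcoxon_rank_sum(a, a), 1)
  x <- c(0.3, 1.2, 2.5); y <- c(0.9, 3.1, 4.4)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(exp(x), exp(y)))
})

test_that("correlation table flags families at their own alpha", {
  set.seed(9)
  n <- 12
  base <- sort(stats::runif(n, 0, 50))
  rec <- data.frame(
    group = rep(c("COPD", "healthy"), each = n / 2),
    vdp_rvent = base + stats::rnorm(n, 0, 2),
    vdp_fvlcm = base + stats::rnorm(n, 0, 2),
    vdp_combined = base,
    vdp_xe = base,
    fev1_pct = 100 - base + stats::rnorm(n, 0, 3))
  tab <- vdp_correlation_table(rec)
  cell <- tab[tab$marker == "vdp_combined" & tab$outcome == "vdp_xe", ]
  expect_equal(cell$r, 1)
  expect_equal(cell$alpha, 0.0167)
  spiro <- tab[tab$outcome == "fev1_pct", ]
  expect_true(all(spiro$alpha == 0.0125))
  expect_true("vdp_xe" %in% spiro$marker)
  # permutation invariance of paired statistics
  tab2 <- vdp_correlation_table(rec[sample(n), ])
  expect_equal(tab$r, tab2$r)
  expect_equal(tab$p, tab2$p)
})

test_that("cells with too few complete cases degrade to NA, not failure", {
  rec <- data.frame(vdp_rvent = c(1, 2, NA, NA), vdp_fvlcm = 1:4,
                    vdp_combined = 1:4, vdp_xe = c(1, 2, NA, NA))
  tab <- vdp_correlation_table(rec)
  cell <- tab[tab$marker == "vdp_rvent" & tab$outcome == "vdp_xe", ]
  expect_true(is.na(cell$r))
  expect_identical(cell$n, 2L)
})

test_that("cohort summary uses the pinned quartile convention", {
  rec <- data.frame(group = rep("COPD", 5), v = c(1, 2, 3, 4, 5))
  s <- cohort_summary(rec)
  expect_equal(s$median, 3)
  expect_equal(s$q1, oracle_percentile(1:5, 0.25))
  expect_equal(s$q3, oracle_percentile(1:5, 0.75))
  expect_true(is.na(s$p_between))  # single group: no test
  flat <- cohort_summary(data.frame(group = c("a", "a", "b", "b"),
                                    v = c(2, 2, 2, 2)))
  expect_true(all(flat$q3 - flat$q1 == 0))
})

test_that("cohort summary is invariant to record order", {
  set.seed(4)
  rec <- data.frame(group = rep(c("COPD", "healthy"), each = 6),
                    v = stats::rnorm(12), w = stats::rnorm(12))
  s1 <- cohort_summary(rec)
  s2 <- cohort_summary(rec[sample(12), ])
  expect_equal(s1, s2)
})

test_that("copula cohorts recover the target rank correlation", {
  rs <- vapply(1:20, function(s) {
    d <- simulate_rank_correlated(40, 0.7, seed = s)
    spearman_cor(d$x, d$y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.15)
  expect_identical(simulate_rank_correlated(10, 0.5, seed = 3),
                   simulate_rank_correlated(10, 0.5, seed = 3))
})
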