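test_that("rank_groups orders by estimate with exact normal CIs", {
  est <- data.frame(group = c("a", "b", "c"), est = c(0, 2, 1),
                    se = c(0.1, 0.1, 0.1))
  rk <- rank_groups(est, ci_level = 0.999)
  expect_equal(rk$group, c("b", "c", "a"))
  expect_equal(rk$rank, 1:3)
  # half-width = 3.2905 SE at the 99.9% level
  expect_equal(rk$upper - rk$est, rep(3.290527 * 0.1, 3), tolerance = 1e-5)

  # ties broken by label, flagged
  est2 <- data.frame(group = c("z", "y"), est = c(1, 1), se = c(0.1, 0.1))
  rk2 <- rank_groups(est2)
  expect_equal(rk2$group, c("y", "z"))
  expect_true(all(rk2$tied))

  # missing SE: excluded with warning
  est3 <- rbind(est, data.frame(group = "d", est = 5, se = NA))
  expect_warning(rk3 <- rank_groups(est3), "excluding")
  expect_equal(nrow(rk3), 3)
})

test_that("CI-overlap clustering matches a brute-force pairwise oracle", {
  # all overlapping -> one cluster; all disjoint -> G clusters
  allov <- rank_groups(data.frame(group = letters[1:4], est = c(1, 1.1, 0.9, 1.05),
                                  se = rep(1, 4)))
  expect_equal(unique(cluster_by_ci_overlap(allov)$cluster), 1L)
  disj <- rank_groups(data.frame(group = letters[1:4], est = c(10, 20, 30, 40),
                                 se = rep(0.1, 4)))
  expect_equal(cluster_by_ci_overlap(disj)$cluster, 1:4)

  # two well-separated triplets: 2 clusters of 3, checked against exhaustive
  # pairwise-overlap enumeration
  est <- data.frame(group = letters[1:6],
                    est = c(10, 10.3, 9.8, 2, 2.2, 1.9), se = rep(0.2, 6))
  rk <- cluster_by_ci_overlap(rank_groups(est, 0.999))
  expect_equal(as.vector(table(rk$cluster)), c(3L, 3L))
  overlap <- outer(seq_len(6), seq_len(6), function(i, j)
    rk$lower[i] <= rk$upper[j] & rk$lower[j] <= rk$upper[i])
  for (cl in unique(rk$cluster)) {
    idx <- which(rk$cluster == cl)
    expect_true(all(overlap[idx, idx]))   # members mutually overlap
  }

  # widening the CIs can only merge clusters
  levels <- c(0.5, 0.9, 0.99, 0.999)
  est_r <- data.frame(group = letters[1:8], est = c(1, 2, 3, 5, 5.2, 8, 9, 12),
                      se = rep(0.5, 8))
  n_cl <- vapply(levels, function(cl)
    max(cluster_by_ci_overlap(rank_groups(est_r, cl))$cluster), integer(1))
  expect_true(all(diff(n_cl) <= 0))
})

test_that("the Wilcoxon signed-rank test matches exact references", {
  # identical vectors: degenerate, p = 1
  w0 <- wilcoxon_signed_rank(1:6, 1:6)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$n_informative, 0L)

  # five all-positive differences: one-sided exact p = 1/32
  a <- c(2, 4, 6, 8, 10); b <- c(1, 2, 3, 4, 5)
  w1 <- wilcoxon_signed_rank(a, b, alternative = "greater")
  expect_equal(w1$statistic, 15)
  expect_equal(w1$p_value, 1 / 32)

  # two-sided p equals stats::wilcox.test on data with distinct |differences|
  set.seed(6)
  for (i in 1:5) {
    d <- sample(c(-1, 1), 8, replace = TRUE) * sample(1:20, 8)
    x <- rnorm(8)
    y <- x - d
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }

  # with ties the exact path matches the independent enumeration oracle
  set.seed(7)
  for (i in 1:5) {
    x <- sample(1:5, 9, replace = TRUE)
    y <- sample(1:5, 9, replace = TRUE)
    got <- wilcoxon_signed_rank(x, y)
    orc <- enum_wilcoxon(x, y)
    if (got$n_informative > 0) {
      expect_equal(got$statistic, orc$statistic)
      expect_equal(got$p_value, orc$p, tolerance = 1e-12)
    }
  }

  # swapping the vectors leaves the two-sided p unchanged
  wab <- wilcoxon_signed_rank(a, b)
  wba <- wilcoxon_signed_rank(b, a)
  expect_equal(wab$p_value, wba$p_value)

  # large-n path: normal approximation with continuity correction
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30)
  wl <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(wl$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(wl$method, "normal")

  expect_error(wilcoxon_signed_rank(c(a = 1, b = 2), c(a = 1, c = 2)),
               "mismatched")
})

test_that("convergent correlations behave like product-moment correlations", {
  fm <- c(A = 0.1, B = 0.5, C = 0.9, D = 1.4)
  prev <- data.frame(group = c("A", "B", "C", "D"),
                     est = 0.1 + 0.3 * c(0.1, 0.5, 0.9, 1.4))
  cc <- convergent_correlations(fm, prev)
  expect_equal(cc["factor_mean", "est"], 1, tolerance = 1e-12)

  # invariant to affine rescaling
  prev2 <- prev; prev2$est <- 5 - 2 * prev2$est
  cc2 <- convergent_correlations(fm, prev2)
  expect_equal(abs(cc2["factor_mean", "est"]), 1, tolerance = 1e-12)

  # independent vectors stay inside the null band +-3/sqrt(G)
  set.seed(9)
  G <- 36
  fm_r <- stats::setNames(rnorm(G), sprintf("G%02d", 1:G))
  prev_r <- data.frame(group = names(fm_r), est = rnorm(G))
  cc3 <- convergent_correlations(fm_r, prev_r)
  expect_lt(abs(cc3["factor_mean", "est"]), 3 / sqrt(G))

  # zero variance is warned about and undefined
  prev0 <- prev; prev0$est <- 0.5
  expect_warning(cc0 <- convergent_correlations(fm, prev0), "zero-variance")
  expect_true(is.na(cc0["factor_mean", "est"]))
  expect_error(convergent_correlations(fm[1:2], prev[1:2, ]), ">= 3")
})
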