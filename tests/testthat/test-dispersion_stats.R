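test_that("MAD and MADn match hand-computed order statistics", {
  expect_equal(mad_raw(c(1, 2, 3, 4, 5)), 1)
  expect_equal(madn(c(1, 2, 3, 4, 5)), 1.4826)
  expect_equal(mad_raw(rep(0.3, 7)), 0)
  # even length: midpoint medians; |dev| = (.45,.15,.05,.05,.35,.45)
  expect_equal(mad_raw(c(0.1, 0.4, 0.5, 0.6, 0.9, 1.0)), 0.25)
  expect_error(madn(numeric(0)), "non-empty")
})

test_that("MADn is consistent for the SD under normality", {
  set.seed(14)
  expect_lt(abs(madn(rnorm(50000)) - 1), 0.02)
})

test_that("compiled MADn agrees with stats::mad on tied and untied samples", {
  set.seed(8)
  for (n in c(2, 5, 6, 41, 300)) {
    x <- sample(seq(-1, 1, by = 0.05), n, replace = TRUE)
    expect_identical(flychoice:::cpp_mad(x, 1.4826), stats::mad(x))
    y <- rnorm(n)
    expect_identical(flychoice:::cpp_mad(y, 1), stats::mad(y, constant = 1))
  }
})

test_that("MADn is scale-equivariant and the index scale is twice the LCP scale", {
  set.seed(3)
  x <- rnorm(31)
  expect_equal(madn(-2.5 * x + 7), 2.5 * madn(x))
  cohort <- cohort_from_lcp(list(A = runif(40), B = runif(35)))
  s_idx <- dispersion_summary(
    list(A = cohort$flies$phototaxis_index[cohort$flies$group_label == "A"],
         B = cohort$flies$phototaxis_index[cohort$flies$group_label == "B"]),
    "phototaxis_index")
  s_lcp <- dispersion_summary(
    list(A = cohort$flies$lcp[cohort$flies$group_label == "A"],
         B = cohort$flies$lcp[cohort$flies$group_label == "B"]), "lcp")
  expect_equal(s_idx$madn, 2 * s_lcp$madn)
  expect_equal(s_idx$madn, 1.4826 * s_idx$mad)
})

test_that("the MADn-range test is exceedance-correct on forced cases", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- global_dispersion_test(g, B = 200, seed = 1)
  expect_equal(res$observed_stat, 0)
  expect_equal(res$p_value, 1)

  g2 <- list(a = c(1, 2, 3, 4, 5), b = c(10, 20, 30, 40, 50))
  res2 <- global_dispersion_test(g2, B = 50, seed = 1)
  expect_equal(res2$observed_stat, 1.4826 * 9)

  expect_error(global_dispersion_test(list(a = 1:3, b = 2)), "at least 2")
  expect_error(global_dispersion_test(list(a = 1:3)), "2 groups")
})

test_that("compiled and reference permutation engines agree", {
  set.seed(6)
  g <- list(a = rnorm(12), b = rnorm(12, sd = 2), c = rnorm(12))
  pc <- global_dispersion_test(g, B = 4000, seed = 2, engine = "cpp")
  pr <- global_dispersion_test(g, B = 4000, seed = 2, engine = "r")
  expect_equal(pc$observed_stat, pr$observed_stat)
  # same null distribution up to Monte-Carlo noise
  expect_lt(abs(pc$p_value - pr$p_value),
            3 * sqrt(0.25 / 4000) * 2)
})

test_that("pairwise |dMADn| tests report signed effects and Holm-adjusted p", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
            c = c(10, 20, 30, 40, 50))
  res <- pairwise_dispersion_tests(g, B = 400, seed = 3)
  expect_equal(nrow(res), 3L)
  ab <- res[res$group_a == "a" & res$group_b == "b", ]
  expect_equal(ab$effect, 0)
  expect_equal(ab$p_raw, 1)
  ac <- res[res$group_a == "a" & res$group_b == "c", ]
  expect_equal(ac$statistic, 1.4826 * 9)
  expect_lt(ac$effect, 0)
  expect_true(all(res$p_holm >= res$p_raw))
  expect_equal(res$p_holm, holm_by_hand(res$p_raw))
})

test_that("BCa intervals handle degeneracy and reduce to percentile when z0 = a = 0", {
  const <- bca_ci(rep(0.4, 30), "madn", n_boot = 500, seed = 1)
  expect_true(const$degenerate)
  expect_equal(c(const$point, const$lower, const$upper), c(0, 0, 0))

  theta_star <- rnorm(2000)
  expect_identical(
    flychoice:::bca_endpoints(theta_star, z0 = 0, accel = 0, level = 0.95),
    unname(quantile(theta_star, c((1 - 0.95) / 2, 1 - (1 - 0.95) / 2),
                    type = 7, names = FALSE)))
})

test_that("BCa interval brackets the point estimate and matches boot's BCa closely", {
  skip_if_not_installed("boot")
  set.seed(12)
  x <- rnorm(60, 5, 2)
  ours <- bca_ci(x, "mean", n_boot = 9999, seed = 4)
  expect_lte(ours$lower, ours$point)
  expect_gte(ours$upper, ours$point)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 9999)
  bci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # independent implementation; residual gap is quantile-rule noise
  expect_lt(abs(ours$lower - bci[1]), 0.06)
  expect_lt(abs(ours$upper - bci[2]), 0.06)
})

test_that("custom statistic functions run through the generic bootstrap path", {
  set.seed(5)
  x <- rexp(40)
  ci <- bca_ci(x, function(v) median(v), n_boot = 800, seed = 9,
               statistic_name = "median")
  expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
  expect_equal(ci$point, median(x))
})
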