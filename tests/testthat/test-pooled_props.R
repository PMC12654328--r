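test_that("Wilson interval matches the closed form and its boundary behavior", {
  ci <- wilson_ci(5, 10)
  expect_equal(unname(ci), c(0.2366, 0.7634), tolerance = 1e-4)
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
  expect_gt(wilson_ci(0, 10)[["upper"]], 0)
  expect_equal(wilson_ci(10, 10)[["upper"]], 1)
  # contains p-hat; width shrinks with n at fixed p-hat
  for (x in c(1, 7, 13)) {
    ci20 <- wilson_ci(x, 20)
    expect_true(ci20[["lower"]] <= x / 20 && x / 20 <= ci20[["upper"]])
    ci200 <- wilson_ci(10 * x, 200)
    expect_lt(diff(ci200), diff(ci20))
  }
})

test_that("pooled counts are trial-weighted and equal the plain mean when complete", {
  cohort <- cohort_from_lcp(list(A = c(0.75, 0.25), B = c(0.5, 0.5, 0.8)))
  pc <- pool_counts(cohort)
  expect_equal(pc$n_trials_total, c(80L, 120L))
  expect_equal(pc$p_hat[1], 0.5)
  expect_equal(pc$p_hat,
               vapply(split(cohort$flies$lcp, cohort$flies$group_label)[
                 cohort$group_labels], mean, numeric(1)),
               ignore_attr = TRUE)
  expect_true(all(pc$wilson_lower <= pc$p_hat & pc$p_hat <= pc$wilson_upper))
  expect_true(all(pc$descriptive))
})

test_that("the groups-by-choice chi-square matches hand margins", {
  expect_equal(chisq_groups_by_choice(rbind(c(30, 10), c(30, 10)))$statistic,
               0)
  sub <- chisq_groups_by_choice(rbind(c(10, 0), c(0, 10)))
  expect_equal(sub$statistic, 20)
  expect_equal(sub$df, 1)
  tab <- rbind(c(20, 10), c(5, 25), c(17, 13), c(9, 21))
  expect_equal(chisq_groups_by_choice(tab)$statistic,
               chisq_groups_by_choice(tab[c(3, 1, 4, 2), ])$statistic)
  expect_error(chisq_groups_by_choice(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("two-proportion z matches hand arithmetic and the 2x2 chi-square", {
  eq <- two_prop_z(5, 10, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  zt <- two_prop_z(8, 10, 2, 10)
  expect_equal(zt$z, 0.6 / sqrt(0.25 * 0.2), tolerance = 1e-9)
  expect_equal(zt$z, 2.683, tolerance = 1e-3)
  # classical identity: z^2 equals the uncorrected 2x2 Pearson statistic
  x2 <- chisq_groups_by_choice(rbind(c(8, 2), c(2, 8)))$statistic
  expect_equal(zt$z^2, x2, tolerance = 1e-9)
  # degenerate pooled proportion is flagged, not an error
  und <- two_prop_z(0, 10, 0, 12)
  expect_true(und$undefined)
  expect_equal(und$p_value, 1)
})

test_that("MOVER-W interval recombines the Wilson limits", {
  # oracle: plug wilson_ci(5,10) into the closed form
  half <- 0.5 - wilson_ci(5, 10)[["lower"]]
  mw <- mover_w_ci(5, 10, 5, 10)
  expect_equal(unname(mw), c(-1, 1) * sqrt(2) * half, tolerance = 1e-9)
  expect_equal(unname(mw), c(-0.3725, 0.3725), tolerance = 1e-4)
  # always contains the point difference; symmetric for identical counts
  set.seed(2)
  for (i in 1:10) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    x1 <- rbinom(1, n1, 0.6); x2 <- rbinom(1, n2, 0.4)
    d <- x1 / n1 - x2 / n2
    ci <- mover_w_ci(x1, n1, x2, n2)
    expect_true(ci[["lower"]] <= d && d <= ci[["upper"]])
  }
  # interval width shrinks toward 0 with matched large samples
  expect_lt(diff(mover_w_ci(600, 1000, 600, 1000)),
            diff(mover_w_ci(6, 10, 6, 10)))
})

test_that("pooled contrasts cover all pairs, Holm-adjusted and flagged descriptive", {
  cohort <- cohort_from_lcp(list(
    A = rep(c(0.7, 0.75), 10), B = rep(c(0.7, 0.8), 10),
    C = rep(c(0.5, 0.55), 10), D = rep(c(0.45, 0.5), 10)))
  out <- pooled_contrasts(cohort)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$mover_lower <= out$delta & out$delta <= out$mover_upper))
  expect_equal(out$p_holm, holm_by_hand(out$p_raw))
  expect_true(all(out$descriptive))
  # delta follows the (group_a minus group_b) ordering
  ad <- out[out$group_a == "A" & out$group_b == "D", ]
  expect_gt(ad$delta, 0)
  rep <- pooled_report(cohort)
  expect_named(rep, c("proportions", "chisq", "contrasts", "note"))
  expect_match(rep$note, "descriptive")
})
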