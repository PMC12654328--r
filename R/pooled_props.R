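# Descriptive pooled-trial proportions: Wilson intervals, the
# groups-by-choice chi-square, pairwise two-proportion z-tests and MOVER-W
# difference intervals. These pool trials as if independent and are
# descriptive only; confirmatory inference is per fly.

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' wilson_ci(5, 10) # c(0.2366, 0.7634)
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Pooled within-group choice proportions with Wilson intervals
#'
#' Sums trials and toward-light choices over the retained flies of each
#' group; the pooled proportion equals the trial-weighted mean of per-fly
#' LCPs (the plain mean when all flies are complete).
#'
#' @param cohort A `fly_cohort`.
#' @param level Confidence level for the Wilson intervals.
#' @return Data.frame: group, total trials, toward count, `p_hat`, Wilson
#'   bounds, and a `descriptive` flag.
#' @export
pool_counts <- function(cohort, level = 0.95) {
  flies <- cohort$flies
  rows <- lapply(cohort$group_labels, function(g) {
    sub <- flies[flies$group_label == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group: ", g)
    n <- sum(sub$n_trials); x <- sum(sub$n_toward)
    ci <- wilson_ci(x, n, level)
    data.frame(group_label = g, n_trials_total = n, n_toward = x,
               p_hat = x / n, wilson_lower = ci[["lower"]],
               wilson_upper = ci[["upper"]], level = level,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$descriptive <- TRUE
  rownames(out) <- NULL
  out
}

#' Chi-square test of choice counts across groups
#'
#' Pearson chi-square (no continuity correction) on the groups x
#' \{toward, away\} contingency table; df = groups - 1.
#'
#' @param counts Matrix with one row per group and columns
#'   `c(toward, away)`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_groups_by_choice <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2L, nrow(counts) >= 2L)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contract error: zero row or column margin")
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-proportion z-test
#'
#' Pooled-variance z statistic
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` without
#' continuity correction (unpooled variance available by switch), with a
#' two-sided normal p-value. When the pooled proportion is 0 or 1 the
#' statistic is undefined; `z = NA`, `p = 1` is returned with a flag.
#'
#' @param x1,n1,x2,n2 Success and trial counts of the two samples.
#' @param pooled Use the pooled variance (default TRUE).
#' @return List with `z`, `p_value`, `undefined`.
#' @examples
#' two_prop_z(8, 10, 2, 10) # z = 2.683
#' @export
two_prop_z <- function(x1, n1, x2, n2, pooled = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  se <- if (pooled) sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
        else sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (!is.finite(se) || se == 0) {
    if (p1 == p2) return(list(z = 0, p_value = 1, undefined = pbar %in% c(0, 1)))
    return(list(z = NA_real_, p_value = 1, undefined = TRUE))
  }
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), undefined = FALSE)
}

#' MOVER-W interval for a difference of proportions
#'
#' Method-of-variance-estimates-recovery interval built from the two
#' Wilson intervals `(l1, u1)` and `(l2, u2)`:
#' `lower = (p1 - p2) - sqrt((p1 - l1)^2 + (u2 - p2)^2)`,
#' `upper = (p1 - p2) + sqrt((u1 - p1)^2 + (p2 - l2)^2)`.
#'
#' @inheritParams two_prop_z
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` for `p1 - p2`.
#' @export
mover_w_ci <- function(x1, n1, x2, n2, level = 0.95) {
  p1 <- x1 / n1; p2 <- x2 / n2
  w1 <- wilson_ci(x1, n1, level); w2 <- wilson_ci(x2, n2, level)
  d <- p1 - p2
  c(lower = d - sqrt((p1 - w1[["lower"]])^2 + (w2[["upper"]] - p2)^2),
    upper = d + sqrt((w1[["upper"]] - p1)^2 + (p2 - w2[["lower"]])^2))
}

#' Pairwise pooled-trial contrasts
#'
#' All unordered group pairs, each with the difference of pooled
#' proportions (`delta = p_a - p_b`, pairs ordered as in the cohort's
#' label order), its MOVER-W interval, the two-proportion z-test and Holm
#' step-down adjusted p-values. Descriptive only.
#'
#' @param cohort A `fly_cohort`.
#' @param level Confidence level.
#' @param pooled_variance Use pooled-variance z (default TRUE).
#' @return Data.frame with one row per pair.
#' @export
pooled_contrasts <- function(cohort, level = 0.95, pooled_variance = TRUE) {
  counts <- pool_counts(cohort, level)
  pairs <- utils::combn(counts$group_label, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- counts[counts$group_label == pr[1], ]
    b <- counts[counts$group_label == pr[2], ]
    zt <- two_prop_z(a$n_toward, a$n_trials_total, b$n_toward,
                     b$n_trials_total, pooled = pooled_variance)
    mw <- mover_w_ci(a$n_toward, a$n_trials_total, b$n_toward,
                     b$n_trials_total, level)
    data.frame(group_a = pr[1], group_b = pr[2],
               delta = a$p_hat - b$p_hat,
               mover_lower = mw[["lower"]], mover_upper = mw[["upper"]],
               z = zt$z, p_raw = zt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out$descriptive <- TRUE
  rownames(out) <- NULL
  out
}

#' Pooled-proportion report for a cohort
#'
#' @param cohort A `fly_cohort`.
#' @param level Confidence level.
#' @return List with `proportions`, `chisq` and `contrasts`; every table
#'   is flagged descriptive (trials pooled as if independent).
#' @export
pooled_report <- function(cohort, level = 0.95) {
  counts <- pool_counts(cohort, level)
  tab <- cbind(toward = counts$n_toward,
               away = counts$n_trials_total - counts$n_toward)
  rownames(tab) <- counts$group_label
  list(proportions = counts,
       chisq = chisq_groups_by_choice(tab),
       contrasts = pooled_contrasts(cohort, level),
       note = "descriptive: trials pooled as if independent")
}
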