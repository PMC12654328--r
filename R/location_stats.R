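# Per-fly location analysis of light-choice probability: group summaries,
# permutation Kruskal-Wallis, and pairwise permutation mean contrasts.

#' Per-group location summaries
#'
#' Median with IQR (linear interpolation between order statistics,
#' [stats::quantile()] type 7) and mean with SEM (sample SD, n - 1
#' denominator, over the square root of n; `NA` for singleton groups).
#'
#' @param cohort A `fly_cohort`, or a named list of numeric vectors.
#' @param var Per-fly variable to summarize when a cohort is given.
#' @return Data.frame with one row per group.
#' @export
summarize_groups <- function(cohort, var = c("lcp", "phototaxis_index")) {
  groups <- if (inherits(cohort, "fly_cohort")) {
    var <- match.arg(var)
    split_by_group(cohort, var)
  } else cohort
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("each group must be non-empty")
  data.frame(
    group_label = names(groups),
    n_flies = vapply(groups, length, integer(1)),
    median = vapply(groups, stats::median, numeric(1)),
    q1 = vapply(groups, function(v)
      unname(stats::quantile(v, 0.25, type = 7)), numeric(1)),
    q3 = vapply(groups, function(v)
      unname(stats::quantile(v, 0.75, type = 7)), numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Kruskal-Wallis H with tie correction
#'
#' Rank-based location statistic: with pooled midranks,
#' `H = 12 / (N (N + 1)) * sum(n_g * Rbar_g^2) - 3 (N + 1)`, divided by
#' the tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)` over tie
#' groups of size t. Ties are pervasive here (a 40-trial choice proportion
#' takes only 41 values), so the correction is applied by default; it can
#' be switched off for sensitivity analysis. If all pooled values are
#' identical the statistic is degenerate and 0 is returned.
#'
#' @param values Pooled numeric vector.
#' @param labels Group labels, same length as `values`.
#' @param tie_correct Apply the tie correction (default TRUE).
#' @return The H statistic (scalar).
#' @export
kruskal_H <- function(values, labels, tie_correct = TRUE) {
  stopifnot(length(values) == length(labels), length(values) >= 3L)
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)               # midranks for ties
  rbar_sq <- tapply(r, labels, function(x) sum(x)^2 / length(x))
  H <- 12 / (N * (N + 1)) * sum(rbar_sq) - 3 * (N + 1)
  if (!tie_correct) return(H)
  tie_sizes <- table(values)
  tie_factor <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  if (tie_factor <= 0) return(0)  # all values identical: degenerate
  H / tie_factor
}

#' Permutation Kruskal-Wallis test
#'
#' Observed tie-corrected H, with a null built by permuting group labels
#' across all individuals (sizes preserved). Pooled ranks are invariant
#' under relabelling, so the null recomputes only group rank sums.
#'
#' @param groups Named list of per-fly numeric vectors.
#' @param B Number of permutations.
#' @param seed Master seed; stream label `"location-kw"`.
#' @param convention See [perm_pvalue()].
#' @param engine `"cpp"` (default) or `"r"` reference path.
#' @return A `perm_result`.
#' @export
perm_kw_test <- function(groups, B = 10000L, seed = 1L,
                         convention = c("proportion_ge", "plus_one"),
                         engine = c("cpp", "r")) {
  convention <- match.arg(convention)
  engine <- match.arg(engine)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop("each group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), sizes)
  N <- length(pooled)
  if (length(unique(pooled)) == 1L) {
    return(new_perm_result("Kruskal-Wallis H (tie-corrected)", 0,
                           numeric(B), 1, seed, convention,
                           degenerate = TRUE))
  }
  obs <- kruskal_H(pooled, labels)
  r <- rank(pooled)
  tie_sizes <- table(pooled)
  tie_factor <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  set.seed(stream_seed(seed, "location-kw"))
  null <- if (engine == "cpp") {
    cpp_perm_null_kw(r, sizes, tie_factor, as.integer(B))
  } else {
    replicate(B, {
      shuffled <- permute_labels(r, sizes)
      acc <- sum(vapply(shuffled, function(x) sum(x)^2 / length(x),
                        numeric(1)))
      (12 / (N * (N + 1)) * acc - 3 * (N + 1)) / tie_factor
    })
  }
  new_perm_result("Kruskal-Wallis H (tie-corrected)", obs, null,
                  perm_pvalue(obs, null, convention), seed, convention)
}

#' Pairwise permutation tests on group mean differences
#'
#' For each unordered pair the reported effect is the signed difference of
#' group means `mean_a - mean_b`; the test statistic is its absolute
#' value, with a two-group relabelling null and Holm step-down correction
#' across the pairs.
#'
#' @inheritParams perm_kw_test
#' @return Data.frame, one row per pair (signed effect, `p_raw`,
#'   `p_holm`).
#' @export
pairwise_mean_tests <- function(groups, B = 10000L, seed = 1L,
                                convention = c("proportion_ge",
                                               "plus_one")) {
  convention <- match.arg(convention)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("each group must be non-empty")
  pairwise_perm(groups, B, seed, convention, "location-pair",
                stat_fun = function(a, b) mean(a) - mean(b),
                null_fun = function(pooled, n1, B)
                  cpp_perm_null_mean_diff(pooled, n1, as.integer(B)))
}

#' Location report for a cohort
#'
#' Group summaries of per-fly LCP, the global permutation Kruskal-Wallis
#' test and pairwise permutation mean contrasts with Holm correction.
#'
#' @param cohort A `fly_cohort`.
#' @param B Number of permutations for both tests.
#' @inheritParams perm_kw_test
#' @return List with `summary`, `global` and `pairwise`.
#' @export
location_report <- function(cohort, B = 10000L, seed = 1L,
                            convention = c("proportion_ge", "plus_one")) {
  convention <- match.arg(convention)
  groups <- split_by_group(cohort, "lcp")
  list(summary = summarize_groups(groups),
       global = perm_kw_test(groups, B = B, seed = seed,
                             convention = convention),
       pairwise = pairwise_mean_tests(groups, B = B, seed = seed,
                                      convention = convention))
}
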