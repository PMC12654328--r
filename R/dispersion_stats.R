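# Between-fly dispersion: MAD / MADn of per-fly phototaxis indices,
# permutation inference on the range of group MADn and on pairwise
# |dMADn|, and BCa bootstrap intervals for MADn.

# Consistency constant making MADn comparable to the SD under normality.
MADN_CONSTANT <- 1.4826

#' Median absolute deviation (raw and normalized)
#'
#' `mad_raw()` is the median of absolute deviations from the median
#' (midpoint rule for even-length medians); `madn()` scales it by 1.4826,
#' making it directly comparable to a standard deviation under normality
#' while staying robust to heavy tails. Both delegate to [stats::mad()].
#'
#' @param values Non-empty numeric vector.
#' @return A non-negative scalar.
#' @examples
#' mad_raw(c(1, 2, 3, 4, 5)) # 1
#' madn(c(1, 2, 3, 4, 5))    # 1.4826
#' @export
mad_raw <- function(values) {
  if (length(values) == 0L) stop("values must be non-empty")
  stats::mad(values, constant = 1)
}

#' @rdname mad_raw
#' @export
madn <- function(values) {
  if (length(values) == 0L) stop("values must be non-empty")
  stats::mad(values, constant = MADN_CONSTANT)
}

#' Per-group dispersion summary
#'
#' @param groups Named list of per-fly numeric vectors (one per group),
#'   e.g. phototaxis indices.
#' @param scale Label recording which per-fly scale the values are on.
#' @return Data.frame with group, n, MAD and MADn.
#' @export
dispersion_summary <- function(groups,
                               scale = c("phototaxis_index", "lcp")) {
  scale <- match.arg(scale)
  data.frame(group_label = names(groups),
             n_flies = vapply(groups, length, integer(1)),
             mad = vapply(groups, mad_raw, numeric(1)),
             madn = vapply(groups, madn, numeric(1)),
             scale = scale,
             stringsAsFactors = FALSE, row.names = NULL)
}

check_dispersion_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values (dispersion undefined)")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
}

#' Global permutation test on the range of group MADn
#'
#' The observed statistic is `max_g MADn_g - min_g MADn_g` over the
#' groups. Group labels are permuted across all individuals (group sizes
#' preserved) and the range recomputed for each shuffle; the p-value is
#' the exceedance proportion under the chosen convention.
#'
#' @param groups Named list of per-fly numeric vectors.
#' @param B Number of permutations (default 10000).
#' @param seed Master seed; the test draws from its own stream
#'   `"dispersion-global"`.
#' @param convention P-value convention, see [perm_pvalue()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference path).
#' @return A `perm_result`.
#' @export
global_dispersion_test <- function(groups, B = 10000L, seed = 1L,
                                   convention = c("proportion_ge",
                                                  "plus_one"),
                                   engine = c("cpp", "r")) {
  convention <- match.arg(convention)
  engine <- match.arg(engine)
  check_dispersion_groups(groups)
  stopifnot(B >= 1L)
  obs <- diff(range(vapply(groups, madn, numeric(1))))
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  set.seed(stream_seed(seed, "dispersion-global"))
  null <- if (engine == "cpp") {
    cpp_perm_null_madn_range(pooled, sizes, as.integer(B), MADN_CONSTANT)
  } else {
    replicate(B, {
      shuffled <- permute_labels(pooled, sizes)
      diff(range(vapply(shuffled, madn, numeric(1))))
    })
  }
  new_perm_result("range of group MADn", obs, null,
                  perm_pvalue(obs, null, convention), seed, convention)
}

#' Pairwise permutation tests on |dMADn| with Holm correction
#'
#' For each unordered pair of groups the effect is the signed difference
#' `MADn_a - MADn_b`; the test statistic is its absolute value, with a
#' two-group relabelling null (only the two groups in the contrast are
#' reshuffled). Raw p-values are Holm step-down adjusted across all pairs.
#'
#' @inheritParams global_dispersion_test
#' @return Data.frame with one row per pair: effect (signed), statistic,
#'   `p_raw`, `p_holm`, B, seed, convention.
#' @export
pairwise_dispersion_tests <- function(groups, B = 10000L, seed = 1L,
                                      convention = c("proportion_ge",
                                                     "plus_one")) {
  convention <- match.arg(convention)
  check_dispersion_groups(groups)
  pairwise_perm(groups, B, seed, convention, "dispersion-pair",
                stat_fun = function(a, b) madn(a) - madn(b),
                null_fun = function(pooled, n1, B)
                  cpp_perm_null_madn_diff(pooled, n1, as.integer(B),
                                          MADN_CONSTANT))
}

# BCa endpoints from a bootstrap sample: adjusted quantile levels
# Phi(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha))). With z0 = 0 and
# a = 0 this is exactly the percentile interval (same quantile rule).
bca_endpoints <- function(theta_star, z0, accel, level) {
  base_probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  probs <- if (z0 == 0 && accel == 0) {
    base_probs  # transform is the identity: plain percentile interval
  } else {
    z <- stats::qnorm(base_probs)
    adj <- z0 + (z0 + z) / (1 - accel * (z0 + z))
    stats::pnorm(adj)
  }
  unname(stats::quantile(theta_star, probs, type = 7, names = FALSE))
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for a statistic of one sample.
#' The bias-correction term is
#' `z0 = qnorm((#\{theta* < theta_hat\} + 0.5 * #\{theta* = theta_hat\}) / n_boot)`
#' (ties get half weight: resampled MADn values of 40-trial proportions
#' are heavily tied and a strictly-less rule would bias z0), clamped into
#' `(0, 1)` by `1/(n_boot + 1)` when all resamples fall on one side. The
#' acceleration comes from the jackknife:
#' `a = sum(d^3) / (6 * sum(d^2)^1.5)` with `d = mean(loo) - loo`, set to
#' 0 when the leave-one-out values are constant.
#'
#' @param values Numeric sample (length >= 2).
#' @param statistic `"madn"`, `"mean"` (compiled fast paths) or an R
#'   function of a numeric vector.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Master seed; stream label `"bca-<statistic-label>"`.
#' @param statistic_name Label used for the stream and the report.
#' @return An object of class `bca_ci`: point estimate, lower, upper,
#'   `z0`, `accel`, flags `degenerate` and `z0_clamped`.
#' @export
bca_ci <- function(values, statistic = "madn", n_boot = 10000L,
                   level = 0.95, seed = 1L,
                   statistic_name = NULL) {
  stopifnot(length(values) >= 2L, n_boot >= 1L, level > 0, level < 1)
  if (is.character(statistic)) {
    statistic <- match.arg(statistic, c("madn", "mean"))
    stat_id <- match(statistic, c("madn", "mean")) - 1L
    if (is.null(statistic_name)) statistic_name <- statistic
    stat_fun <- if (statistic == "madn") madn else mean
  } else {
    stopifnot(is.function(statistic))
    stat_id <- NA_integer_
    if (is.null(statistic_name)) statistic_name <- "custom"
    stat_fun <- statistic
  }
  set.seed(stream_seed(seed, paste0("bca-", statistic_name)))

  n <- length(values)
  if (is.na(stat_id)) {
    theta_hat <- stat_fun(values)
    theta_star <- vapply(seq_len(n_boot), function(b)
      stat_fun(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    loo <- vapply(seq_len(n), function(i) stat_fun(values[-i]), numeric(1))
  } else {
    # compiled paths compute theta_hat with the same code as theta_star so
    # tie counting is exact
    theta_hat <- if (stat_id == 0L) cpp_mad(values, MADN_CONSTANT)
                 else mean(values)
    theta_star <- cpp_boot_stat(values, as.integer(n_boot), stat_id,
                                MADN_CONSTANT)
    loo <- cpp_jack_stat(values, stat_id, MADN_CONSTANT)
  }

  degenerate <- length(unique(theta_star)) == 1L
  z0_clamped <- FALSE
  if (degenerate && theta_star[1] == theta_hat) {
    lo <- hi <- theta_hat
    z0 <- 0; accel <- 0
  } else {
    prop <- (sum(theta_star < theta_hat) +
               0.5 * sum(theta_star == theta_hat)) / n_boot
    if (prop <= 0 || prop >= 1) {
      prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
      z0_clamped <- TRUE
    }
    z0 <- stats::qnorm(prop)
    d <- mean(loo) - loo
    denom <- sum(d^2)
    accel <- if (denom > 0) sum(d^3) / (6 * denom^1.5) else 0
    ends <- bca_endpoints(theta_star, z0, accel, level)
    lo <- ends[1]; hi <- ends[2]
  }
  structure(list(statistic_name = statistic_name, point = theta_hat,
                 lower = lo, upper = hi, level = level,
                 n_boot = as.integer(n_boot), z0 = z0, accel = accel,
                 seed = seed, degenerate = degenerate,
                 z0_clamped = z0_clamped),
            class = "bca_ci")
}

#' @export
print.bca_ci <- function(x, ...) {
  cat(sprintf("BCa %.0f%% CI for %s: %.5g [%.5g, %.5g] (B = %d)\n",
              100 * x$level, x$statistic_name, x$point, x$lower, x$upper,
              x$n_boot))
  if (x$degenerate) cat("  [degenerate bootstrap distribution]\n")
  invisible(x)
}

#' Dispersion report for a cohort
#'
#' Runs the full between-fly dispersion suite on a cohort's phototaxis
#' indices: per-group MAD/MADn with BCa intervals, the global MADn-range
#' permutation test, and pairwise |dMADn| tests with Holm correction.
#'
#' @param cohort A `fly_cohort` from [filter_complete()].
#' @param B_perm,B_boot Permutation / bootstrap iterations.
#' @param level Confidence level for the BCa intervals.
#' @inheritParams global_dispersion_test
#' @return List with `summary` (per-group table including BCa bounds),
#'   `global` (`perm_result`) and `pairwise` (data.frame).
#' @export
dispersion_report <- function(cohort, B_perm = 10000L, B_boot = 10000L,
                              level = 0.95, seed = 1L,
                              convention = c("proportion_ge", "plus_one")) {
  convention <- match.arg(convention)
  groups <- split_by_group(cohort, "phototaxis_index")
  summ <- dispersion_summary(groups, "phototaxis_index")
  cis <- lapply(names(groups), function(g)
    bca_ci(groups[[g]], "madn", n_boot = B_boot, level = level, seed = seed,
           statistic_name = paste0("madn-", g)))
  summ$bca_lower <- vapply(cis, function(ci) ci$lower, numeric(1))
  summ$bca_upper <- vapply(cis, function(ci) ci$upper, numeric(1))
  list(summary = summ,
       global = global_dispersion_test(groups, B = B_perm, seed = seed,
                                       convention = convention),
       pairwise = pairwise_dispersion_tests(groups, B = B_perm, seed = seed,
                                            convention = convention))
}
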