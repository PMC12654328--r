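# Shared permutation machinery: label shuffles, p-value conventions, Holm
# step-down, and the seed-stream contract used by every resampling test.

#' Derive a reproducible sub-seed for a named random stream
#'
#' Every stochastic procedure in the pipeline draws from its own stream,
#' identified by a text label, derived deterministically from one master
#' seed. Adding a new test to an analysis therefore never perturbs the
#' draws of an existing one.
#'
#' @param seed Master integer seed.
#' @param stream_label Character label naming the consumer (e.g.
#'   `"dispersion-global"`).
#' @return A single integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' stream_seed(7, "dispersion-global")
#' @export
stream_seed <- function(seed, stream_label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream_label), length(stream_label) == 1L)
  # FNV-1a style fold of the label bytes, kept in exact double arithmetic
  h <- 2166136261
  for (b in utf8ToInt(stream_label)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  mixed <- (abs(seed) * 2654435761 + h * 97 + sign(seed) * 11) %% (2^31 - 2)
  as.integer(mixed) + 1L
}

#' Shuffle values into groups of fixed sizes
#'
#' One label permutation: partitions `values` uniformly at random into
#' groups of exactly the given sizes (group sizes are preserved, as in a
#' permutation test that relabels individuals).
#'
#' @param values Numeric vector of pooled per-individual values.
#' @param group_sizes Integer vector; must sum to `length(values)`.
#' @return A list of numeric vectors, one per group size.
#' @export
permute_labels <- function(values, group_sizes) {
  group_sizes <- as.integer(group_sizes)
  if (sum(group_sizes) != length(values))
    stop("group_sizes must sum to length(values)")
  idx <- sample.int(length(values))
  ends <- cumsum(group_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(group_sizes),
         function(g) values[idx[starts[g]:ends[g]]])
}

#' Permutation p-value from a null sample
#'
#' Counts null statistics at least as large as the observed one. All
#' statistics in this pipeline are oriented as non-negative departures
#' (ranges, absolute differences, H on ranks), so the exceedance
#' proportion is the two-sided p-value. Two conventions are supported:
#' `proportion_ge` is the plain proportion `#\{null >= obs\}/B`;
#' `plus_one` adds the observed statistic to its own null,
#' `(1 + #\{null >= obs\})/(1 + B)`, which is never anti-conservative and
#' is bounded below by `1/(B+1)`.
#'
#' @param observed Observed statistic (non-negative departure).
#' @param null_stats Numeric vector of permutation statistics.
#' @param convention `"proportion_ge"` (default) or `"plus_one"`.
#' @return A p-value in `[0, 1]`.
#' @export
perm_pvalue <- function(observed, null_stats,
                        convention = c("proportion_ge", "plus_one")) {
  convention <- match.arg(convention)
  if (length(null_stats) == 0L) stop("null_stats must be non-empty")
  stopifnot(is.finite(observed))
  # guard against last-ulp differences between the observed statistic and
  # null replicates recomputed by a different (compiled) code path
  eps <- 1e-12 * max(1, abs(observed))
  n_ge <- sum(null_stats >= observed - eps)
  B <- length(null_stats)
  if (convention == "proportion_ge") n_ge / B else (1 + n_ge) / (1 + B)
}

#' Holm step-down adjustment
#'
#' Step-down family-wise error control: sort p-values ascending, multiply
#' the i-th smallest by (m - i + 1), enforce monotonicity and cap at 1.
#' Backed by [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p_values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

# Container for one permutation test result.
new_perm_result <- function(statistic_name, observed, null_stats, p_value,
                            seed, convention, degenerate = FALSE) {
  structure(
    list(statistic_name = statistic_name,
         observed_stat = observed,
         n_permutations = length(null_stats),
         null_stats = null_stats,
         p_value = p_value,
         seed = seed,
         convention = convention,
         degenerate = degenerate),
    class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %.6g, B = %d, p = %.4g (%s)\n",
              x$observed_stat, x$n_permutations, x$p_value, x$convention))
  if (isTRUE(x$degenerate)) cat("  [degenerate statistic]\n")
  invisible(x)
}

# Shared driver for pairwise two-group permutation tests. `groups` is a
# named list of numeric vectors; stat_fun(a, b) returns the signed effect;
# null_fun(pooled, n1, B) returns the two-group null of |effect|.
pairwise_perm <- function(groups, B, seed, convention, stream_prefix,
                          stat_fun, null_fun) {
  labs <- names(groups)
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    eff <- stat_fun(a, b)
    set.seed(stream_seed(seed, paste(stream_prefix, pr[1], pr[2], sep = "-")))
    null <- null_fun(c(a, b), length(a), B)
    data.frame(group_a = pr[1], group_b = pr[2],
               effect = eff,
               statistic = abs(eff),
               p_raw = perm_pvalue(abs(eff), null, convention),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out$B <- B
  out$seed <- seed
  out$convention <- convention
  out
}
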