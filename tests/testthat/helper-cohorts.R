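# Shared fixtures: all built in code at test time.

# A per-fly table with given per-group LCP vectors (all flies complete).
flies_from_lcp <- function(lcp_by_group, n_trials = 40L) {
  rows <- lapply(names(lcp_by_group), function(g) {
    lcp <- lcp_by_group[[g]]
    data.frame(fly_id = paste0(g, "_", seq_along(lcp)),
               group_label = g, lane_id = NA_character_,
               n_trials = n_trials,
               n_toward = as.integer(round(lcp * n_trials)),
               lcp = lcp, phototaxis_index = 2 * lcp - 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cohort_from_lcp <- function(lcp_by_group, n_trials = 40L) {
  filter_complete(flies_from_lcp(lcp_by_group, n_trials), n_trials)
}

# A minimal per-trial table for one fly.
trials_for_fly <- function(id, group, scores, lane = "lane01") {
  data.frame(fly_id = id, group_label = group, lane_id = lane,
             trial_index = seq_along(scores),
             lit_side = rep_len(c("left", "right"), length(scores)),
             score = as.integer(scores), stringsAsFactors = FALSE)
}

# Exact two-group permutation null: every assignment of the pooled values
# to a first group of size n1 (complement is group 2), via combn.
exact_two_group_null <- function(pooled, n1, stat) {
  idx <- utils::combn(length(pooled), n1, simplify = FALSE)
  vapply(idx, function(i) stat(pooled[i], pooled[-i]), numeric(1))
}

# Independent hand implementation of Holm step-down (oracle for
# holm_adjust): sort, scale by (m - i + 1), running max, cap at 1.
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Beta-binomial pmf over k = 0..m successes (oracle for generator and
# population MADn calculations).
betabinom_pmf <- function(m, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  k <- 0:m
  p <- exp(lchoose(m, k) + lbeta(k + a, m - k + b) - lbeta(a, b))
  p / sum(p)
}

# Discrete population quantile: smallest value with CDF >= q.
discrete_quantile <- function(values, probs, q) {
  o <- order(values)
  values[o][which(cumsum(probs[o]) >= q)[1]]
}
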