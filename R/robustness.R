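# Pre-specified robustness screens: the 3-MAD extreme-value rule on
# per-fly LCP and lane/side balance diagnostics.

#' Screen per-fly LCP values for extreme observations
#'
#' Single-pass screen: within each group, a fly is flagged when its LCP
#' lies more than `k` median absolute deviations from the group median.
#' The threshold uses raw MAD units by default (the literal reading of a
#' "three MAD" rule); normalized MADn units widen it by 1.4826x and are
#' available by switch. When the group MAD is zero the criterion is
#' degenerate and no fly is flagged.
#'
#' @param cohort A `fly_cohort`.
#' @param k Threshold multiplier (default 3).
#' @param scale `"raw_mad"` (default) or `"madn"`.
#' @return Data.frame: per group, number checked, number flagged, the
#'   flagged fly ids (comma-separated), scale value used and a
#'   `degenerate` flag. Attribute `"flagged_ids"` holds the ids as a list.
#' @export
screen_outliers <- function(cohort, k = 3, scale = c("raw_mad", "madn")) {
  scale <- match.arg(scale)
  stopifnot(k >= 0)
  groups <- split(cohort$flies, cohort$flies$group_label)
  groups <- groups[cohort$group_labels]
  rows <- lapply(cohort$group_labels, function(g) {
    sub <- groups[[g]]
    med <- stats::median(sub$lcp)
    s <- if (scale == "raw_mad") mad_raw(sub$lcp) else madn(sub$lcp)
    degen <- s == 0
    flagged <- if (degen) character(0)
               else sub$fly_id[abs(sub$lcp - med) > k * s]
    list(row = data.frame(group_label = g, n_checked = nrow(sub),
                          n_flagged = length(flagged),
                          flagged_fly_ids = paste(flagged, collapse = ","),
                          threshold_k = k, scale_used = scale,
                          scale_value = s, degenerate = degen,
                          stringsAsFactors = FALSE),
         ids = flagged)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "flagged_ids") <- setNames(lapply(rows, `[[`, "ids"),
                                       cohort$group_labels)
  out
}

#' Lane/side balance diagnostics
#'
#' Descriptive checks that treatment groups were balanced across the
#' apparatus: a group-by-lane contingency chi-square on retained flies,
#' and the toward-light rate split by which side was illuminated (two
#' estimates of the same quantity under fair-coin side randomization),
#' each with a Wilson interval. Skipped with a notice when lane or side
#' information is absent.
#'
#' @param trials Per-trial data.frame (canonical layout).
#' @param cohort A `fly_cohort` (defines the retained flies).
#' @param alpha Flagging level for the balance chi-square (default 0.05).
#' @return List with `lane_table`, `lane_chisq`, `side_rates`, `flagged`,
#'   and `skipped` notices.
#' @export
lane_side_balance <- function(trials, cohort, alpha = 0.05) {
  skipped <- character(0)
  retained_ids <- cohort$flies$fly_id
  out <- list(lane_table = NULL, lane_chisq = NULL, side_rates = NULL,
              flagged = FALSE, skipped = skipped)

  if (all(is.na(cohort$flies$lane_id))) {
    out$skipped <- c(out$skipped, "lane_id absent: lane balance skipped")
  } else {
    tab <- table(group = cohort$flies$group_label,
                 lane = cohort$flies$lane_id)
    out$lane_table <- tab
    if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
      ht <- suppressWarnings(stats::chisq.test(tab))
      out$lane_chisq <- list(statistic = unname(ht$statistic),
                             df = unname(ht$parameter),
                             p_value = unname(ht$p.value))
      out$flagged <- is.finite(ht$p.value) && ht$p.value < alpha
    }
  }

  tr <- trials[trials$fly_id %in% retained_ids, , drop = FALSE]
  if (all(is.na(tr$lit_side))) {
    out$skipped <- c(out$skipped, "lit_side absent: side rates skipped")
  } else {
    rows <- lapply(c("left", "right"), function(s) {
      sub <- tr[tr$lit_side == s, , drop = FALSE]
      n <- nrow(sub); x <- sum(sub$score == 1L)
      ci <- if (n > 0) wilson_ci(x, n) else c(lower = NA_real_,
                                              upper = NA_real_)
      data.frame(lit_side = s, n_trials = n, n_toward = x,
                 toward_rate = if (n > 0) x / n else NA_real_,
                 wilson_lower = ci[["lower"]], wilson_upper = ci[["upper"]],
                 stringsAsFactors = FALSE)
    })
    out$side_rates <- do.call(rbind, rows)
  }
  out
}
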