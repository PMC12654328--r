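# Synthetic choice-data generator: beta-binomial cohorts with tunable
# between-fly overdispersion, emulating a parallel single-fly T-maze assay.

#' Specify one treatment group for the generator
#'
#' Each fly in a group carries a latent probability `p_i` of choosing the
#' illuminated arm. With intraclass correlation `icc = 0`, every fly shares
#' `p_i = mean_lcp` (pure binomial); with `icc > 0`, `p_i` is drawn from a
#' Beta distribution with mean `mean_lcp` and
#' `alpha = mean_lcp * (1 - icc) / icc`,
#' `beta = (1 - mean_lcp) * (1 - icc) / icc`, so that the variance of the
#' per-fly choice proportion over `m` trials is
#' `mean_lcp * (1 - mean_lcp) * (icc + (1 - icc) / m)`.
#'
#' @param label Group label.
#' @param n_flies Number of flies (>= 1).
#' @param mean_lcp Mean light-choice probability in `[0, 1]` (must be in
#'   the open interval when `icc > 0`).
#' @param icc Between-fly overdispersion (intraclass correlation) in
#'   `[0, 1)`.
#' @param dropout_prob Probability a fly fails to complete the schedule, in
#'   `[0, 1)`; such a fly completes `U` trials, `U` uniform on
#'   `{1, ..., m - 1}`.
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n_flies, mean_lcp, icc = 0,
                       dropout_prob = 0) {
  if (!is.finite(icc) || icc < 0 || icc >= 1)
    stop("parameter error: icc must lie in [0, 1)")
  if (!is.finite(mean_lcp) || mean_lcp < 0 || mean_lcp > 1)
    stop("parameter error: mean_lcp must lie in [0, 1]")
  if (icc > 0 && (mean_lcp <= 0 || mean_lcp >= 1))
    stop("parameter error: mean_lcp must be in (0, 1) when icc > 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("parameter error: dropout_prob must lie in [0, 1)")
  stopifnot(n_flies >= 1)
  structure(list(label = as.character(label), n_flies = as.integer(n_flies),
                 mean_lcp = mean_lcp, icc = icc,
                 dropout_prob = dropout_prob),
            class = "group_spec")
}

#' Specify a synthetic cohort
#'
#' @param groups List of [group_spec()] objects with unique labels.
#' @param trials_per_fly Scheduled trials per fly (default 40).
#' @param seed Integer seed; identical specs reproduce identical cohorts
#'   bit-for-bit.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, trials_per_fly = 40L, seed = 1L) {
  stopifnot(trials_per_fly >= 1L, length(groups) >= 1L)
  labs <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labs)) stop("group labels must be unique")
  structure(list(groups = groups,
                 trials_per_fly = as.integer(trials_per_fly),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reference four-group cohort specification
#'
#' A ready-made specification emulating a four-arm larval serotonergic
#' manipulation study run on a 40-lane FlyVac rig: groups Control, aMW
#' (serotonin-synthesis inhibitor), 5-HTP (serotonin precursor) and
#' Escitalopram (SSRI), 40 trials per fly, with group mean light-choice
#' probabilities 0.73 / 0.73 / 0.65 / 0.52. Overdispersion defaults
#' (icc 0.09 / 0.09 / 0.08 / 0.12) are calibrated so that group MADn of
#' the phototaxis index sits near 0.30 for Control, aMW and 5-HTP and
#' near 0.37 for Escitalopram (an elevated-dispersion group), and dropout
#' is calibrated so that the completion filter excludes roughly 6-9 flies
#' per group, leaving about 301 / 310 / 301 / 321 retained.
#'
#' @param seed Integer master seed for the generated cohort.
#' @return A `cohort_spec`.
#' @examples
#' spec <- flyvac_cohort_spec(1)
#' @export
flyvac_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    groups = list(
      group_spec("Control",      309L, 0.73, icc = 0.09, dropout_prob = 0.025),
      group_spec("aMW",          318L, 0.73, icc = 0.09, dropout_prob = 0.025),
      group_spec("5-HTP",        309L, 0.65, icc = 0.08, dropout_prob = 0.025),
      group_spec("Escitalopram", 329L, 0.52, icc = 0.12, dropout_prob = 0.025)),
    trials_per_fly = 40L,
    seed = seed)
}

#' Sample a synthetic per-trial cohort
#'
#' Draws one cohort from a [cohort_spec()]: per fly a latent `p_i`
#' (degenerate at the group mean when `icc = 0`), per trial an
#' independently fair-coin lit side and a ±1 score that is +1 with
#' probability `p_i`. With probability `dropout_prob` a fly completes only
#' `U ~ Uniform{1, ..., m - 1}` trials, exercising the completion filter.
#' Flies are assigned to lanes cyclically (1..40).
#'
#' @param spec A `cohort_spec`.
#' @return A list with `trials` (a per-trial data.frame in the canonical
#'   layout of [read_trials()]) and `truth` (per-fly ground-truth latent
#'   `p_i`, for recovery tests).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  m <- spec$trials_per_fly
  trial_rows <- list()
  truth_rows <- list()
  fly_counter <- 0L
  for (g in spec$groups) {
    p_i <- if (g$icc > 0) {
      a <- g$mean_lcp * (1 - g$icc) / g$icc
      b <- (1 - g$mean_lcp) * (1 - g$icc) / g$icc
      stats::rbeta(g$n_flies, a, b)
    } else rep(g$mean_lcp, g$n_flies)
    drop <- stats::runif(g$n_flies) < g$dropout_prob
    n_done <- as.integer(ifelse(drop & m > 1L,
                                1L + floor(stats::runif(g$n_flies) * (m - 1L)),
                                m))
    ids <- sprintf("fly%05d", fly_counter + seq_len(g$n_flies))
    lanes <- sprintf("lane%02d", ((fly_counter + seq_len(g$n_flies) - 1L)
                                  %% 40L) + 1L)
    fly_counter <- fly_counter + g$n_flies
    total <- sum(n_done)
    trial_rows[[length(trial_rows) + 1L]] <- data.frame(
      fly_id = rep(ids, n_done),
      group_label = g$label,
      lane_id = rep(lanes, n_done),
      trial_index = sequence(n_done),
      lit_side = ifelse(stats::runif(total) < 0.5, "left", "right"),
      score = ifelse(stats::runif(total) < rep(p_i, n_done), 1L, -1L),
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      fly_id = ids, group_label = g$label, p_i = p_i,
      n_trials = as.integer(n_done), stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, trial_rows),
       truth = do.call(rbind, truth_rows))
}

#' Write a synthetic cohort to disk
#'
#' Writes the per-trial table in the delimited layout [read_trials()]
#' accepts, and optionally the ground-truth latent probabilities.
#'
#' @param cohort Result of [sample_cohort()].
#' @param path Output TSV path for the trial table.
#' @param truth_path Optional output TSV path for the ground truth.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  utils::write.table(cohort$trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(truth_path))
    utils::write.table(cohort$truth, truth_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}
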