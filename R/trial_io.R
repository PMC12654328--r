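# Reading, validating and aggregating per-trial T-maze choice logs.

default_column_map <- function() {
  list(fly_id = "fly_id", group_label = "group_label", lane_id = "lane_id",
       trial_index = "trial_index", lit_side = "lit_side", score = "score",
       chosen_side = "chosen_side")
}

default_encoding_map <- function() {
  c("1" = 1, "+1" = 1, "-1" = -1, "toward" = 1, "away" = -1)
}

#' Read a per-trial choice log
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) of single-fly T-maze trials and validates it into a canonical
#' trial table: one row per trial with a ±1 score (+1 = chose the
#' illuminated arm, -1 = chose the dark arm). The file's column dialect is
#' supplied through `column_map`; the choice may arrive either as a
#' pre-computed score column (decoded through `encoding_map`) or as a
#' `(lit_side, chosen_side)` pair, in which case the score is +1 exactly
#' when the chosen side equals the lit side.
#'
#' @param path Path to the delimited file (header required).
#' @param column_map Named list mapping logical fields (`fly_id`,
#'   `group_label`, `trial_index`, `score` or `chosen_side`, optionally
#'   `lane_id`, `lit_side`) to column names in the file.
#' @param encoding_map Named vector mapping raw score values to +1/-1.
#' @return A data.frame of validated trials with columns `fly_id`,
#'   `group_label`, `lane_id`, `trial_index`, `lit_side`, `score`.
#' @export
read_trials <- function(path, column_map = default_column_map(),
                        encoding_map = default_encoding_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  cm <- utils::modifyList(default_column_map(), as.list(column_map))

  need <- c("fly_id", "group_label", "trial_index")
  has_score <- !is.null(cm$score) && cm$score %in% names(raw)
  has_sides <- !is.null(cm$chosen_side) && cm$chosen_side %in% names(raw) &&
    !is.null(cm$lit_side) && cm$lit_side %in% names(raw)
  for (f in need) {
    if (is.null(cm[[f]]) || !cm[[f]] %in% names(raw))
      stop("configuration error: mapped column for '", f,
           "' not found in file")
  }
  if (!has_score && !has_sides)
    stop("configuration error: need either a score column or a ",
         "(lit_side, chosen_side) pair")

  out <- data.frame(
    fly_id = as.character(raw[[cm$fly_id]]),
    group_label = as.character(raw[[cm$group_label]]),
    lane_id = if (!is.null(cm$lane_id) && cm$lane_id %in% names(raw))
      as.character(raw[[cm$lane_id]]) else NA_character_,
    trial_index = as.integer(raw[[cm$trial_index]]),
    lit_side = if (!is.null(cm$lit_side) && cm$lit_side %in% names(raw))
      as.character(raw[[cm$lit_side]]) else NA_character_,
    stringsAsFactors = FALSE)

  if (has_score) {
    vals <- as.character(raw[[cm$score]])
    unknown <- setdiff(unique(vals), names(encoding_map))
    if (length(unknown) > 0) {
      row1 <- which(vals == unknown[1])[1]
      stop("data error: unmappable choice value \"", unknown[1],
           "\" (first at row ", row1, ")")
    }
    out$score <- as.integer(unname(encoding_map[vals]))
  } else {
    out$score <- ifelse(as.character(raw[[cm$chosen_side]]) == out$lit_side,
                        1L, -1L)
  }

  if (anyNA(out$score) || !all(out$score %in% c(-1L, 1L)))
    stop("data error: scores must decode to +1 or -1")
  if (anyNA(out$trial_index) || any(out$trial_index < 1L))
    stop("data error: trial_index must be an integer >= 1")
  key <- paste(out$fly_id, out$trial_index, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    stop("data error: duplicate (fly_id, trial_index) = (",
         out$fly_id[i], ", ", out$trial_index[i], ") at row ", i)
  }
  out
}

#' Aggregate trials to per-fly records
#'
#' Collapses a validated trial table to one row per fly with the trial
#' count, number of toward-light choices, light-choice probability
#' (LCP = proportion of +1 scores) and phototaxis index (mean of the ±1
#' scores). The index is computed as `2 * lcp - 1`, so the identity between
#' the two scales holds to full precision.
#'
#' @param trials Data.frame from [read_trials()] (or [sample_cohort()]).
#' @return A data.frame with one row per fly: `fly_id`, `group_label`,
#'   `lane_id`, `n_trials`, `n_toward`, `lcp`, `phototaxis_index`.
#' @export
aggregate_flies <- function(trials) {
  if (nrow(trials) == 0L) {
    return(data.frame(fly_id = character(), group_label = character(),
                      lane_id = character(), n_trials = integer(),
                      n_toward = integer(), lcp = numeric(),
                      phototaxis_index = numeric(),
                      stringsAsFactors = FALSE))
  }
  grp <- vapply(split(trials$group_label, trials$fly_id),
                function(g) g[1], character(1))
  lane <- vapply(split(trials$lane_id, trials$fly_id),
                 function(l) l[1], character(1))
  n <- vapply(split(trials$score, trials$fly_id), length, integer(1))
  tw <- vapply(split(trials$score, trials$fly_id),
               function(s) sum(s == 1L), integer(1))
  lcp <- tw / n
  out <- data.frame(fly_id = names(n), group_label = unname(grp),
                    lane_id = unname(lane), n_trials = unname(n),
                    n_toward = unname(tw), lcp = unname(lcp),
                    phototaxis_index = unname(2 * lcp - 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the completion filter and assemble a cohort
#'
#' Flies are scheduled for a fixed number of trials; those that did not
#' complete the full schedule are excluded from analysis. Partitions the
#' per-fly table into retained flies (exactly `required_trials` trials) and
#' excluded flies (fewer), and records per-group exclusion counts. A fly
#' with more trials than the schedule indicates a corrupt log and is an
#' error, not a truncation.
#'
#' @param flies Per-fly data.frame from [aggregate_flies()].
#' @param required_trials Scheduled trials per fly (default 40).
#' @param group_labels Optional ordered character vector of expected group
#'   labels; defaults to order of first appearance.
#' @return An object of class `fly_cohort`: list with `flies` (retained),
#'   `excluded`, `group_labels`, `required_trials`, `exclusion_counts`.
#' @export
filter_complete <- function(flies, required_trials = 40L,
                            group_labels = NULL) {
  stopifnot(required_trials >= 1L)
  over <- flies$n_trials > required_trials
  if (any(over))
    stop("data error: fly ", flies$fly_id[which(over)[1]], " has ",
         flies$n_trials[which(over)[1]], " trials, more than the schedule (",
         required_trials, ")")
  if (is.null(group_labels)) group_labels <- unique(flies$group_label)
  keep <- flies$n_trials == required_trials
  retained <- flies[keep, , drop = FALSE]
  excluded <- flies[!keep, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  counts <- data.frame(
    group_label = group_labels,
    n_retained = vapply(group_labels,
                        function(g) sum(retained$group_label == g),
                        integer(1)),
    n_excluded = vapply(group_labels,
                        function(g) sum(excluded$group_label == g),
                        integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  structure(list(flies = retained, excluded = excluded,
                 group_labels = group_labels,
                 required_trials = as.integer(required_trials),
                 exclusion_counts = counts),
            class = "fly_cohort")
}

#' @export
print.fly_cohort <- function(x, ...) {
  cat(sprintf("Fly cohort: %d retained, %d excluded (schedule: %d trials)\n",
              nrow(x$flies), nrow(x$excluded), x$required_trials))
  print(x$exclusion_counts, row.names = FALSE)
  invisible(x)
}

#' Write the per-fly table (and exclusion report) as TSV
#'
#' @param cohort A `fly_cohort`.
#' @param path Output path for the retained per-fly table.
#' @param exclusion_path Optional path for the excluded-fly table.
#' @return `path`, invisibly.
#' @export
write_fly_table <- function(cohort, path, exclusion_path = NULL) {
  utils::write.table(cohort$flies, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(exclusion_path))
    utils::write.table(cohort$excluded, exclusion_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a cohort's per-fly values by group, in group_labels order.
split_by_group <- function(cohort, var = c("phototaxis_index", "lcp")) {
  var <- match.arg(var)
  out <- lapply(cohort$group_labels,
                function(g) cohort$flies[[var]][cohort$flies$group_label == g])
  names(out) <- cohort$group_labels
  out
}
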