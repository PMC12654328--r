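test_that("read_trials decodes scores, applies the encoding map, and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fly,diet,trial,choice",
               "A,Control,1,toward",
               "A,Control,2,away",
               "B,Control,1,toward"), path)
  cm <- list(fly_id = "fly", group_label = "diet", trial_index = "trial",
             score = "choice")
  tr <- read_trials(path, cm)
  expect_equal(tr$score, c(1L, -1L, 1L))
  expect_equal(tr$fly_id, c("A", "A", "B"))

  # unmapped value is named, with its row
  writeLines(c("fly,diet,trial,choice", "A,Control,1,T"), path)
  expect_error(read_trials(path, cm), "\"T\"")

  # duplicated (fly, trial) is a data error
  writeLines(c("fly,diet,trial,choice",
               "A,Control,1,toward",
               "A,Control,2,toward",
               "A,Control,2,away"), path)
  expect_error(read_trials(path, cm), "duplicate")

  # missing mapped column is a configuration error
  writeLines(c("fly,diet,trial,choice", "A,Control,1,toward"), path)
  expect_error(read_trials(path, list(fly_id = "nope")), "configuration")
})

test_that("read_trials derives the score from a (lit_side, chosen_side) pair", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fly_id\tgroup_label\ttrial_index\tlit_side\tchosen_side",
               "A\tControl\t1\tleft\tleft",
               "A\tControl\t2\tright\tleft"), path)
  tr <- read_trials(path)
  expect_equal(tr$score, c(1L, -1L))
})

test_that("aggregate_flies computes LCP and phototaxis index from trial scores", {
  tr <- rbind(trials_for_fly("A", "Control", c(rep(1, 30), rep(-1, 10))),
              trials_for_fly("B", "Control", rep(-1, 40)),
              trials_for_fly("C", "Control", rep(c(1, -1), 5)))
  flies <- aggregate_flies(tr)
  flies <- flies[order(flies$fly_id), ]
  expect_equal(flies$lcp, c(0.75, 0, 0.5))
  expect_equal(flies$phototaxis_index, c(0.5, -1, 0))
  expect_equal(flies$n_trials, c(40L, 40L, 10L))
  # empty input is an empty table, not an error
  expect_equal(nrow(aggregate_flies(tr[0, ])), 0L)
  # the two per-fly scales are linked exactly
  expect_identical(flies$phototaxis_index, 2 * flies$lcp - 1)
  # the index equals the mean of the +-1 scores
  expect_equal(flies$phototaxis_index[1], mean(tr$score[tr$fly_id == "A"]))
})

test_that("filter_complete partitions by the completion schedule", {
  counts <- c(40L, 40L, 39L, 40L, 12L)
  tr <- do.call(rbind, lapply(seq_along(counts), function(i)
    trials_for_fly(paste0("f", i), "Control", rep(1, counts[i]))))
  cohort <- filter_complete(aggregate_flies(tr), 40L)
  expect_s3_class(cohort, "fly_cohort")
  expect_equal(nrow(cohort$flies), 3L)
  expect_equal(nrow(cohort$excluded), 2L)
  expect_setequal(cohort$excluded$n_trials, c(39L, 12L))
  expect_equal(cohort$exclusion_counts$n_excluded, 2L)
  # retained + excluded covers every distinct fly
  expect_equal(nrow(cohort$flies) + nrow(cohort$excluded),
               length(unique(tr$fly_id)))

  # all complete: nothing excluded
  all40 <- filter_complete(aggregate_flies(
    rbind(trials_for_fly("a", "g", rep(1, 40)),
          trials_for_fly("b", "g", rep(-1, 40)))))
  expect_equal(nrow(all40$excluded), 0L)

  # more trials than the schedule is corrupt data, not a truncation
  expect_error(filter_complete(aggregate_flies(
    trials_for_fly("x", "g", rep(1, 41)))), "more than the schedule")
})

test_that("per-fly tables round-trip through disk unchanged", {
  spec <- cohort_spec(list(group_spec("A", 25, 0.7, icc = 0.1),
                           group_spec("B", 25, 0.5, icc = 0.2)),
                      seed = 5)
  cohort <- filter_complete(aggregate_flies(sample_cohort(spec)$trials))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fly_table(cohort, path)
  back <- utils::read.delim(path)
  expect_equal(back$lcp, cohort$flies$lcp)
  expect_equal(back$phototaxis_index, cohort$flies$phototaxis_index)
})
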