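# Phono-lexical scoring, error taxonomy and accuracy summaries.

test_that("score_production applies the category rules", {
  inv <- c("non", "jar")
  labels <- rbind(
    naming_row("non", "rise", "non", "mid"),    # tone-only: rise-to-mid
    naming_row("non", "mid", "jar", "low"),     # segment error
    naming_row("non", "mid", "non", "mid"),     # correct
    naming_row("non", "fall", "wer", "fall"),   # deviant -> non_target
    naming_row("non", "fall", NON_TARGET, "fall"),
    naming_row("non", "low", "non", UNCATEGORIZABLE),  # excluded
    naming_row("non", "low", "", "low"),        # non-response -> excluded
    naming_row("non", "low", "non", "low", quality_flag = TRUE))
  out <- score_production(labels, segment_inventory = inv)
  expect_identical(as.character(out$category),
                   c("tone_only_error", "segment_error", "correct",
                     "non_target", "non_target", "excluded", "excluded",
                     "excluded"))
  expect_identical(out$error_type[1], "rise-to-mid")
  expect_true(all(is.na(out$error_type[-1])))

  bad <- naming_row("non", "rise", "non", "tone4")
  expect_error(score_production(bad), class = "tonetrace_validation_error")
})

test_that("every production falls in exactly one category", {
  tg <- make_target_stimuli()
  model <- speaker_model("S01", "english", 100, 220,
                         confusion = english_confusion())
  led <- simulate_naming_ledger(model, tg, days = 2,
                                p_segment_correct = 0.6, seed = 9)
  out <- score_production(led)
  expect_false(anyNA(out$category))
  expect_identical(sum(table(out$category)), nrow(led))
  # tone-only errors require matching segments by construction
  sub <- out[out$category == "tone_only_error", ]
  expect_identical(sub$produced_segments, sub$target_segments)
  expect_true(all(sub$produced_tone != sub$target_tone))
})

test_that("error tables count tone-only types with zero cells retained", {
  labels <- rbind(
    naming_row("non", "rise", "non", "fall"),
    naming_row("non", "rise", "non", "fall", speaker = "S02"),
    naming_row("non", "rise", "non", "fall", speaker = "S03"),
    naming_row("non", "low", "non", "mid"),
    naming_row("non", "rise", "non", "rise"))
  out <- score_production(labels)
  tab <- tabulate_errors(out, by = character(0))
  m <- tab[["all"]]
  expect_identical(m["rise", "fall"], 3L)
  expect_identical(m["low", "mid"], 1L)
  expect_identical(m["rise", "rise"], 1L)         # diagonal = tone correct
  expect_identical(sum(m) - sum(diag(m)), 4L)     # off-diagonal = errors
  expect_identical(dim(m), c(4L, 4L))

  none <- score_production(naming_row("non", "rise", "non", "rise"))
  m0 <- tabulate_errors(none, by = character(0))[["all"]]
  expect_identical(sum(m0) - sum(diag(m0)), 0L)
  expect_identical(dim(m0), c(4L, 4L))

  # only segment-correct items enter the tone table
  mixed <- score_production(rbind(
    naming_row("non", "rise", "jar", "fall"),
    naming_row("non", "rise", "non", "fall")),
    segment_inventory = c("non", "jar"))
  mm <- tabulate_errors(mixed, by = character(0))[["all"]]
  expect_identical(sum(mm), 1L)
})

test_that("the 12 error types come out in canonical order", {
  lv <- error_type_levels()
  expect_length(lv, 12)
  expect_identical(lv[1:3], c("rise-to-fall", "rise-to-mid", "rise-to-low"))
  expect_identical(lv[10:12], c("low-to-rise", "low-to-fall", "low-to-mid"))
  labels <- score_production(naming_row("non", "low", "non", "mid"))
  cnt <- error_type_counts(tabulate_errors(labels, by = character(0)))
  expect_identical(nrow(cnt), 12L)
  expect_identical(cnt$count[cnt$error_type == "low-to-mid"], 1L)
  expect_identical(sum(cnt$count), 1L)
})

test_that("accuracy summaries use attempted denominators and speaker means", {
  rows <- list()
  # speaker A: 16 items, 11 correct, 4 tone-only, 1 segment error
  for (i in 1:11) rows[[length(rows) + 1]] <-
    naming_row("non", "rise", "non", "rise", speaker = "A")
  for (i in 1:4) rows[[length(rows) + 1]] <-
    naming_row("non", "rise", "non", "mid", speaker = "A")
  rows[[length(rows) + 1]] <- naming_row("non", "rise", "jar", "rise",
                                         speaker = "A")
  # speaker B: 4 attempted (1 excluded), all correct -> no errors
  for (i in 1:4) rows[[length(rows) + 1]] <-
    naming_row("non", "fall", "non", "fall", speaker = "B")
  rows[[length(rows) + 1]] <- naming_row("non", "fall", "non", "fall",
                                         speaker = "B",
                                         quality_flag = TRUE)
  out <- score_production(do.call(rbind, rows),
                          segment_inventory = c("non", "jar"))
  s <- summarize_accuracy(out)
  a <- s$speakers[s$speakers$speaker == "A", ]
  expect_equal(a$pct_correct, 100 * 11 / 16)
  expect_equal(a$pct_correct, 68.75)
  expect_equal(a$pct_tone_only, 100 * 4 / 5)
  b <- s$speakers[s$speakers$speaker == "B", ]
  expect_identical(b$attempted, 4L)          # excluded trial not attempted
  expect_true(is.na(b$pct_tone_only))        # zero errors -> undefined
  g <- s$groups
  expect_identical(g$n_zero_error, 1L)
  expect_equal(g$mean_pct_correct, mean(c(68.75, 100)))
  expect_equal(g$mean_pct_tone_only, 80)     # B excluded from that mean
})

test_that("half tone-only errors give a 50% share", {
  rows <- rbind(naming_row("non", "rise", "non", "mid"),
                naming_row("non", "rise", "non", "low"),
                naming_row("non", "rise", "jar", "rise"),
                naming_row("non", "rise", "jar", "rise"))
  out <- score_production(rows, segment_inventory = c("non", "jar"))
  s <- summarize_accuracy(out)
  expect_equal(s$speakers$pct_tone_only, 50)
})

test_that("naming ledgers round-trip through TSV", {
  tg <- make_target_stimuli()
  model <- speaker_model("S01", "mandarin", 100, 220,
                         confusion = mandarin_confusion())
  led <- simulate_naming_ledger(model, tg, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(led, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_naming_ledger(path)
  expect_equal(as.data.frame(back), as.data.frame(led))
})
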