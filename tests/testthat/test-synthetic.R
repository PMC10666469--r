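# Target stimulus generation, imitation distortions, naming simulation,
# cohort bookkeeping and ground-truth parameter recovery.

test_that("Chao digits map linearly onto the T scale", {
  expect_equal(chao_to_t(1), 0)
  expect_equal(chao_to_t(5), 5)
  expect_equal(chao_to_t(c(2, 3, 4)), c(1.25, 2.5, 3.75))
  expect_error(chao_to_t(6), class = "tonetrace_validation_error")
  expect_error(tone_specs(chao_onset = c(0, 5, 2, 1)),
               class = "tonetrace_validation_error")
})

test_that("the stimulus crossing yields 16 words with the right shapes", {
  tg <- make_target_stimuli()
  expect_identical(nrow(tg), 16L)
  expect_identical(length(unique(tg$item)), 16L)
  expect_identical(as.integer(table(tg$tone)[c("rise", "fall", "mid",
                                               "low")]),
                   rep(4L, 4))
  tmat <- attr(tg, "t_matrix")
  # level specs are constant contours; 15 rises 0 -> 5; 51 falls 5 -> 0
  expect_true(all(abs(tmat[tg$tone == "mid", ] - 1.25) < 1e-12))
  expect_true(all(abs(tmat[tg$tone == "low", ] - 0) < 1e-12))
  expect_equal(unname(tmat[tg$tone == "rise", 1]), rep(0, 4))
  expect_equal(unname(tmat[tg$tone == "rise", 20]), rep(5, 4))
  expect_equal(unname(tmat[tg$tone == "fall", 1]), rep(5, 4))
  expect_equal(unname(tmat[tg$tone == "fall", 20]), rep(0, 4))
})

test_that("level targets have zero dct2/dct3 after analysis", {
  tg <- make_target_stimuli()
  rng <- attr(tg, "range")
  tt <- t_normalize(truncate_edges(tg, 2),
                    speaker_range_table("target", rng[["xmin"]],
                                        rng[["xmax"]]))
  ft <- dct_features(tt, duration_stats(tg))
  lev <- ft[ft$tone %in% c("mid", "low"), ]
  expect_true(all(abs(lev$dct2) < 1e-9))
  expect_true(all(abs(lev$dct3) < 1e-9))
})

test_that("zero-curvature rise is linear and survives the Hz round-trip", {
  specs <- tone_specs(curvature_gain = c(0, 0, 0, 0))
  tg <- make_target_stimuli(specs)
  tmat <- attr(tg, "t_matrix")
  rise <- tmat[which(tg$tone == "rise")[1], ]
  expect_equal(rise, seq(0, 5, length.out = 20), tolerance = 1e-12)
  rng <- attr(tg, "range")
  hz <- f0_samples(tg)[which(tg$tone == "rise")[1], ]
  expect_equal(unname(hz_to_t(hz, rng[["xmin"]], rng[["xmax"]])),
               rise, tolerance = 1e-9)
})

test_that("speaker_model validates its invariants", {
  expect_error(speaker_model("s", "english", 200, 100),
               class = "tonetrace_validation_error")
  expect_error(speaker_model("s", "english", slope_gain = 1.2),
               class = "tonetrace_validation_error")
  expect_error(speaker_model("s", "english", noise_sd = -1),
               class = "tonetrace_validation_error")
  bad_cm <- diag(4); bad_cm[1, 1] <- 0.5
  expect_error(speaker_model("s", "english", confusion = bad_cm),
               class = "tonetrace_validation_error")
})

test_that("noiseless faithful imitation reproduces the target in T-space", {
  tg <- make_target_stimuli()
  m <- speaker_model("S01", "english", 110, 240)
  im <- simulate_imitations(tg, m, reps = 1, days = 1, seed = 1)
  expect_identical(nrow(im), 16L)
  tv <- hz_to_t(f0_samples(im), 110, 240)
  expect_equal(unname(tv), unname(attr(tg, "t_matrix")), tolerance = 1e-9)
  expect_equal(im$duration_ms, tg$duration_ms)
})

test_that("slope gain scales dct2 and level raise shifts dct1", {
  tg <- make_target_stimuli()
  rng <- attr(tg, "range")
  tt <- t_normalize(truncate_edges(tg, 2),
                    speaker_range_table("target", rng[["xmin"]],
                                        rng[["xmax"]]))
  ds <- duration_stats(tg)
  ft <- dct_features(tt, ds)

  m <- speaker_model("S01", "english", 110, 240, slope_gain = 0.6,
                     height_offset = 0.8)
  im <- simulate_imitations(tg, m, reps = 1, days = 1, seed = 1)
  ti <- t_normalize(truncate_edges(im, 2),
                    speaker_range_table("S01", 110, 240))
  fi <- dct_features(ti, ds)
  idx <- match(fi$item, ft$item)
  contour <- fi$tone %in% c("rise", "fall")
  expect_equal(fi$dct2[contour] / ft$dct2[idx][contour],
               rep(0.6, sum(contour)), tolerance = 1e-9)
  level <- !contour
  expect_equal(fi$dct1[level] - ft$dct1[idx][level],
               rep(0.8, sum(level)), tolerance = 1e-9)

  # raised level tones sit farther from the low centroid than controls
  cen <- tone_centroids(ft)
  ctrl <- simulate_imitations(tg, speaker_model("S02", "english", 110, 240),
                              reps = 1, days = 1, seed = 1)
  fc <- dct_features(t_normalize(truncate_edges(ctrl, 2),
                                 speaker_range_table("S02", 110, 240)), ds)
  d_raised <- tonal_distance(fi, cen)
  d_ctrl <- tonal_distance(fc, cen)
  expect_gt(mean(d_raised$distance[d_raised$tone == "low"]),
            mean(d_ctrl$distance[d_ctrl$tone == "low"]))
})

test_that("simulators are deterministic given a seed", {
  tg <- make_target_stimuli()
  m <- speaker_model("S01", "mandarin", 100, 220, noise_sd = 0.3,
                     duration_jitter_sd = 0.08,
                     confusion = mandarin_confusion())
  a <- suppressWarnings(simulate_imitations(tg, m, seed = 99))
  b <- suppressWarnings(simulate_imitations(tg, m, seed = 99))
  expect_identical(a, b)
  expect_false(identical(
    f0_samples(a),
    f0_samples(suppressWarnings(simulate_imitations(tg, m, seed = 100)))))
  la <- simulate_naming_ledger(m, tg, seed = 7)
  lb <- simulate_naming_ledger(m, tg, seed = 7)
  expect_identical(la, lb)
  ca <- default_cohort(cohort_config(n_english = 2, n_mandarin = 2),
                       seed = 5)
  cb <- default_cohort(cohort_config(n_english = 2, n_mandarin = 2),
                       seed = 5)
  expect_identical(ca$imitations, cb$imitations)
  expect_identical(ca$naming, cb$naming)
  expect_identical(ca$speakers, cb$speakers)
})

test_that("naming simulation honours its probability structure", {
  tg <- make_target_stimuli()
  ident <- speaker_model("S01", "english", 100, 220)
  led <- simulate_naming_ledger(ident, tg, p_segment_correct = 1, seed = 3)
  out <- score_production(led)
  expect_true(all(out$category == "correct"))

  led0 <- simulate_naming_ledger(ident, tg, p_segment_correct = 0, seed = 3)
  out0 <- score_production(led0)
  expect_identical(sum(out0$category == "tone_only_error"), 0L)
  expect_identical(sum(out0$category == "correct"), 0L)

  # low -> mid dominance: ~90% of low-tone errors go to mid
  cm <- diag(4); cm[4, ] <- c(0, 0, 0.9, 0.1)
  skew <- speaker_model("S02", "mandarin", 100, 220, confusion = cm)
  big_tg <- make_target_stimuli(segments = sprintf("s%02d", 1:50),
                                durations_ms = c(430, 390, 400, 420))
  led_big <- simulate_naming_ledger(skew, big_tg, days = 2,
                                    p_segment_correct = 1, seed = 11)
  low <- led_big[led_big$target_tone == "low", ]
  p_mid <- mean(low$produced_tone == "mid")
  expect_equal(p_mid, 0.9, tolerance = 0.05)
  expect_true(all(low$produced_tone %in% c("mid", "low")))

  expect_error(simulate_naming_ledger(ident, tg, p_segment_correct = 1.2),
               class = "tonetrace_validation_error")
})

test_that("default cohort sizes, groups and ledgers add up", {
  cfg <- cohort_config()
  cohort <- default_cohort(cfg, seed = 2)
  expect_identical(nrow(cohort$speakers), 41L)
  expect_identical(sum(cohort$speakers$group == "english"), 21L)
  expect_identical(sum(cohort$speakers$group == "mandarin"), 20L)
  n <- ledger_counts(attr(cohort$imitations, "ledger"))
  expect_identical(n$planned, 2624L)
  expect_identical(n$retained, nrow(cohort$imitations))
  expect_lte(n$retained, 2624L)
  nn <- ledger_counts(attr(cohort$naming, "ledger"))
  expect_identical(nn$planned, 1312L)
  expect_identical(nn$retained, nrow(cohort$naming))
  # ground-truth sidecar is writable JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(cohort, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(gt$speakers), 41L)
})

test_that("gamma and beta are recoverable from analyzed features", {
  tg <- make_target_stimuli()
  m <- speaker_model("S01", "english", 100, 220, slope_gain = 0.6,
                     height_offset = 0.5, noise_sd = 0.1)
  im <- simulate_imitations(tg, m, reps = 2, days = 2, seed = 31)
  rec <- recover_imitation_params(im, tg,
                                  speaker_range_table("S01", 100, 220))
  expect_equal(rec$gamma_hat, 0.6, tolerance = 0.05)
  expect_equal(rec$beta_hat, 0.5, tolerance = 0.05)
})
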