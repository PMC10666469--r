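# T-value normalization, DCT coefficients, centroids, tonal distance.

make_f0_row <- function(hz, speaker = "S01", tone = "rise", dur = 400,
                        item = "non15") {
  df <- data.frame(speaker = speaker, group = "english", item = item,
                   tone = tone, day = 1L, duration_ms = dur,
                   stringsAsFactors = FALSE)
  df[sprintf("f%02d", seq_along(hz))] <- as.list(hz)
  f0_set(df, length(hz))
}

test_that("speaker_range pools all productions and rejects flat voices", {
  x <- rbind(make_f0_row(seq(100, 150, length.out = 16)),
             make_f0_row(seq(120, 200, length.out = 16)))
  x <- f0_set(x, 16L)
  rng <- speaker_range(x)
  expect_equal(rng$xmin, 100)
  expect_equal(rng$xmax, 200)
  flat <- make_f0_row(rep(100, 16))
  expect_error(speaker_range(flat), class = "tonetrace_degenerate_range")
})

test_that("T-value transform hits its anchor points", {
  # endpoints, log-midpoint, and a directly evaluated interior value
  expect_equal(hz_to_t(100, 100, 200), 0)
  expect_equal(hz_to_t(200, 100, 200), 5)
  expect_equal(hz_to_t(sqrt(100 * 200), 100, 200), 2.5)
  expect_equal(hz_to_t(150, 100, 200), 5 * log10(1.5) / log10(2))
  expect_equal(hz_to_t(150, 100, 200), 2.9248125, tolerance = 1e-7)
  # exact inverse
  tv <- seq(0, 5, by = 0.25)
  expect_equal(hz_to_t(t_to_hz(tv, 90, 180), 90, 180), tv,
               tolerance = 1e-12)
})

test_that("t_normalize bounds, preserves order, clamps or errors", {
  set.seed(7)
  hz <- exp(runif(16, log(95), log(190)))
  x <- make_f0_row(hz)
  rng <- speaker_range(x)
  tv <- as.numeric(t_values(t_normalize(x, rng)))
  expect_true(all(tv >= 0 & tv <= 5))
  expect_equal(min(tv), 0)   # speaker minimum maps to exactly 0
  expect_equal(max(tv), 5)
  expect_identical(order(hz), order(tv))  # strict monotonicity

  narrow <- speaker_range_table("S01", 100, 180)
  expect_warning(t_normalize(x, narrow), "clamped")
  expect_error(t_normalize(x, narrow, strict = TRUE),
               class = "tonetrace_range_violation")
})

test_that("dct_coefs matches the brute-force oracle and its anchors", {
  expect_equal(dct_coefs(rep(3, 16)),
               c(dct1 = 3, dct2 = 0, dct3 = 0), tolerance = 1e-12)
  ramp <- seq(0, 5, length.out = 16)
  expect_lt(dct_coefs(ramp)[["dct2"]], 0)      # rising -> negative DCT2
  expect_gt(dct_coefs(rev(ramp))[["dct2"]], 0) # falling -> positive
  expect_equal(dct_coefs(ramp), oracle_dct3(ramp), tolerance = 1e-9)

  set.seed(11)
  for (i in 1:20) {
    x <- runif(16, 0, 5)
    expect_equal(dct_coefs(x), oracle_dct3(x), tolerance = 1e-9)
    # reversal negates dct2, preserves dct1/dct3
    r <- dct_coefs(rev(x))
    f <- dct_coefs(x)
    expect_equal(r[["dct1"]], f[["dct1"]], tolerance = 1e-10)
    expect_equal(r[["dct2"]], -f[["dct2"]], tolerance = 1e-10)
    expect_equal(r[["dct3"]], f[["dct3"]], tolerance = 1e-10)
    # linearity on the coefficient part
    y <- runif(16, 0, 5)
    expect_equal(dct_coefs(2 * x - 0.5 * y),
                 2 * dct_coefs(x) - 0.5 * dct_coefs(y),
                 tolerance = 1e-10)
    # Parseval under the orthonormal convention
    expect_equal(sum(tonetrace:::dct_ortho(x)^2), sum(x^2),
                 tolerance = 1e-9)
  }
})

test_that("dct1 equals the contour mean in T-value units", {
  set.seed(3)
  x <- runif(16, 0, 5)
  expect_equal(dct_coefs(x)[["dct1"]], mean(x), tolerance = 1e-12)
})

test_that("centroids are arithmetic means and demand all four tones", {
  tg <- make_target_stimuli()
  rng <- attr(tg, "range")
  tt <- t_normalize(truncate_edges(tg, 2),
                    speaker_range_table("target", rng[["xmin"]],
                                        rng[["xmax"]]))
  ft <- dct_features(tt, duration_stats(tg))
  cen <- tone_centroids(ft)
  expect_identical(sort(cen$tone), sort(c("rise", "fall", "mid", "low")))
  expect_identical(cen$n_targets, rep(4L, 4))
  for (tn in cen$tone) {
    sub <- ft[ft$tone == tn, c("dct1", "dct2", "dct3", "dur_z")]
    expect_equal(unlist(cen[cen$tone == tn,
                            c("dct1", "dct2", "dct3", "dur_z")]),
                 colMeans(sub), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(tone_centroids(ft[ft$tone != "low", ]),
               class = "tonetrace_incomplete_reference")

  # two synthetic tokens average to their midpoint
  ft2 <- ft[1:2, ]
  ft2$tone <- "rise"
  ft2[1, c("dct1", "dct2", "dct3", "dur_z")] <- c(1, 0, 0, 0)
  ft2[2, c("dct1", "dct2", "dct3", "dur_z")] <- c(3, 0, 0, 0)
  ft3 <- rbind(ft2, ft[ft$tone != "rise", ])
  class(ft3) <- class(ft)
  cen2 <- tone_centroids(ft3)
  expect_equal(unlist(cen2[cen2$tone == "rise",
                           c("dct1", "dct2", "dct3", "dur_z")]),
               c(dct1 = 2, dct2 = 0, dct3 = 0, dur_z = 0))
})

test_that("tonal distance is a Euclidean metric on feature space", {
  expect_equal(feature_distance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(feature_distance(c(3, 4, 0, 0), c(0, 0, 0, 0)), 5)
  expect_error(feature_distance(c(1, NA, 0, 0), rep(0, 4)),
               class = "tonetrace_invalid_argument")
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4); c <- rnorm(4)
    expect_equal(feature_distance(a, b), sqrt(sum((a - b)^2)))
    expect_equal(feature_distance(a, b), feature_distance(b, a))
    expect_lte(feature_distance(a, c),
               feature_distance(a, b) + feature_distance(b, c) + 1e-12)
    expect_identical(feature_distance(a, a), 0)
  }
})

test_that("per-production distances match the component-wise oracle", {
  tg <- make_target_stimuli()
  rng <- attr(tg, "range")
  tt <- t_normalize(truncate_edges(tg, 2),
                    speaker_range_table("target", rng[["xmin"]],
                                        rng[["xmax"]]))
  ft <- dct_features(tt, duration_stats(tg))
  cen <- tone_centroids(ft)
  scored <- tonal_distance(ft, cen)
  for (i in seq_len(nrow(scored))) {
    cvec <- unlist(cen[cen$tone == scored$tone[i],
                       c("dct1", "dct2", "dct3", "dur_z")])
    fvec <- unlist(scored[i, c("dct1", "dct2", "dct3", "dur_z")])
    expect_equal(scored$distance[i], sqrt(sum((fvec - cvec)^2)))
  }
  # a target set member is at most the within-tone spread from its centroid
  expect_true(all(scored$distance < 1e-9))  # members identical per tone
})

test_that("centroid JSON round-trips", {
  tg <- make_target_stimuli()
  rng <- attr(tg, "range")
  tt <- t_normalize(truncate_edges(tg, 2),
                    speaker_range_table("target", rng[["xmin"]],
                                        rng[["xmax"]]))
  ds <- duration_stats(tg)
  cen <- tone_centroids(dct_features(tt, ds))
  path <- withr::local_tempfile(fileext = ".json")
  write_centroids(cen, path, ds)
  back <- read_centroids(path)
  expect_equal(as.data.frame(back$centroids), as.data.frame(cen))
  expect_equal(back$dur_stats$mean, ds$mean)
})
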