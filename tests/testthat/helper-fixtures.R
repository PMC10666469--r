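# Shared fixtures and independent oracles, all built in code.

# Independent brute-force oracle for the reported DCT coefficients:
# double cosine-sum loop, same scaling convention as dct_coefs().
oracle_dct3 <- function(x) {
  n <- length(x)
  cc <- numeric(3)
  for (k in 0:2) {
    s <- 0
    for (m in 0:(n - 1)) s <- s + x[m + 1] * cos(pi * k * (m + 0.5) / n)
    cc[k + 1] <- s
  }
  c(dct1 = cc[1] / n, dct2 = 2 * cc[2] / n, dct3 = 2 * cc[3] / n)
}

# Minimal well-formed normtime TSV with n 20-sample rows.
write_toy_normtime <- function(path, n = 3, missing_at = NULL,
                               base = 120) {
  cols <- c("speaker", "group", "item", "tone", "day", "duration_ms",
            sprintf("f%02d", 1:20))
  rows <- lapply(seq_len(n), function(i) {
    f0 <- round(base + 10 * i + 3 * sin(seq(0, pi, length.out = 20)), 3)
    vals <- as.character(f0)
    if (i == 1 && length(missing_at)) vals[missing_at] <- "--undefined--"
    c(sprintf("S%02d", i), "english", "non15", "rise", "1", "400", vals)
  })
  lines <- c(paste(cols, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

write_short_pitchtier <- function(path, times = c(0, 0.5),
                                  values = c(100, 200)) {
  writeLines(c('File type = "ooTextFile"',
               'Object class = "PitchTier"',
               "",
               as.character(min(times)), as.character(max(times)),
               as.character(length(times)),
               as.character(rbind(times, values))),
             path)
  path
}

write_long_pitchtier <- function(path, times = c(0, 0.5),
                                 values = c(100, 200)) {
  pts <- unlist(lapply(seq_along(times), function(i) {
    c(sprintf("points [%d]:", i),
      sprintf("    number = %s", times[i]),
      sprintf("    value = %s", values[i]))
  }))
  writeLines(c('File type = "ooTextFile"',
               'Object class = "PitchTier"',
               "",
               sprintf("xmin = %s", min(times)),
               sprintf("xmax = %s", max(times)),
               sprintf("points: size = %d", length(times)),
               pts),
             path)
  path
}

# A t_set of flat level contours with the given per-contour mean heights.
make_flat_tset <- function(means, noise_sd = 0, n_points = 16,
                           speaker = "S01", day = 1L,
                           prior = NULL) {
  n <- length(means)
  tv <- t(matrix(rep(means, n_points), ncol = n, byrow = TRUE))
  if (noise_sd > 0) tv <- tv + matrix(rnorm(n * n_points, 0, noise_sd), n)
  tv <- pmin(pmax(tv, 0), 5)
  df <- data.frame(speaker = speaker, group = "english",
                   item = sprintf("w%03d", seq_len(n)),
                   tone = prior %||% ifelse(means >= 2, "mid", "low"),
                   day = day, duration_ms = 400,
                   stringsAsFactors = FALSE)
  df[sprintf("t%02d", seq_len(n_points))] <- as.data.frame(tv)
  structure(df, n_samples = n_points, class = c("t_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One labeled naming row.
naming_row <- function(target_segments, target_tone, produced_segments,
                       produced_tone, speaker = "S01", day = 2L,
                       quality_flag = FALSE) {
  data.frame(speaker = speaker, group = "english", day = day,
             item = paste0(target_segments, "x"),
             target_segments = target_segments, target_tone = target_tone,
             produced_segments = produced_segments,
             produced_tone = produced_tone, quality_flag = quality_flag,
             stringsAsFactors = FALSE)
}
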