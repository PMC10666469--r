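# Speaker-relative T-value normalization, DCT shape coefficients, tonal
# centroids of the target stimulus set, and Euclidean tonal distance.

#' Per-speaker F0 range
#'
#' The minimum and maximum valid F0 over all of a speaker's sampled
#' productions (days pooled by default), used as the anchors of the T-value
#' transform: a speaker's own floor maps to T = 0 and ceiling to T = 5.
#'
#' @param x an [f0_set()].
#' @param per_day compute ranges per speaker-day instead of pooling both
#'   days (the pooled range keeps a speaker's Day-1 and Day-2 coefficients
#'   on one scale and is the default).
#' @return data frame `speaker` (and `day` if `per_day`), `xmin`, `xmax`,
#'   class `speaker_range`.
#' @export
speaker_range <- function(x, per_day = FALSE) {
  stopifnot(inherits(x, "f0_set"))
  sm <- f0_samples(x)
  grp <- if (per_day) paste(x$speaker, x$day, sep = "|") else x$speaker
  sp <- split(seq_len(nrow(x)), grp)
  rows <- lapply(names(sp), function(g) {
    v <- sm[sp[[g]], , drop = FALSE]
    v <- v[!is.na(v) & v > 0]
    if (!length(v))
      stopf("speaker %s has no valid samples", g,
            class = "tonetrace_empty_input")
    rng <- range(v)
    if (rng[1] >= rng[2])
      stopf("degenerate pitch range for speaker %s (xmin = xmax = %g Hz)",
            g, rng[1], class = "tonetrace_degenerate_range")
    first <- sp[[g]][1]
    data.frame(speaker = x$speaker[first],
               day = if (per_day) x$day[first] else NA_integer_,
               xmin = rng[1], xmax = rng[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!per_day) out$day <- NULL
  structure(out, class = c("speaker_range", "data.frame"))
}

#' Build a speaker range table by hand
#' @param speaker speaker ids.
#' @param xmin,xmax F0 floor/ceiling in Hz, `0 < xmin < xmax`.
#' @return `speaker_range` data frame.
#' @export
speaker_range_table <- function(speaker, xmin, xmax) {
  if (any(xmin <= 0) || any(xmin >= xmax))
    stopf("require 0 < xmin < xmax for every speaker",
          class = "tonetrace_degenerate_range")
  structure(data.frame(speaker = as.character(speaker), xmin = xmin,
                       xmax = xmax, stringsAsFactors = FALSE),
            class = c("speaker_range", "data.frame"))
}

#' T-value transform and its inverse
#'
#' Maps F0 in Hz onto the speaker-relative 0--5 T-value scale:
#' `T = 5 * (log10(x) - log10(xmin)) / (log10(xmax) - log10(xmin))`,
#' so the speaker's floor is 0, the ceiling 5, and equal T steps are equal
#' log-frequency steps. `t_to_hz()` is the exact inverse.
#'
#' @param hz,tval numeric vectors.
#' @param xmin,xmax speaker F0 floor and ceiling in Hz.
#' @return numeric vector.
#' @export
hz_to_t <- function(hz, xmin, xmax) {
  # ratio computed first so the anchors map to exactly 0 and 5 in floating
  # point (5 * a / b rounds twice; a / b is exactly 1 at hz = xmax)
  5 * ((log10(hz) - log10(xmin)) / (log10(xmax) - log10(xmin)))
}

#' @rdname hz_to_t
#' @export
t_to_hz <- function(tval, xmin, xmax) {
  10^(log10(xmin) + tval / 5 * (log10(xmax) - log10(xmin)))
}

#' Normalize trajectories to T-values
#'
#' Applies the T-value transform to every sample using each speaker's
#' range. With a speaker-global range all T-values land in `[0, 5]`;
#' resampled or externally supplied ranges can put samples outside the
#' range, in which case the default policy clamps to `[0, 5]` with a
#' warning and `strict = TRUE` raises a range-violation error.
#'
#' @param x an [f0_set()] (repaired: no missing samples).
#' @param ranges a `speaker_range` table covering every speaker in `x`.
#' @param strict error on out-of-range samples instead of clamping.
#' @return a `t_set`: data frame with the metadata of `x` and T-value
#'   columns `t01`..., attribute `clamped` (count of clamped samples).
#' @export
t_normalize <- function(x, ranges, strict = FALSE) {
  stopifnot(inherits(x, "f0_set"))
  n <- n_f0_samples(x)
  sm <- f0_samples(x)
  if (anyNA(sm))
    stopf("missing samples present; run repair_contour() first",
          class = "tonetrace_validation_error")
  idx <- match(x$speaker, ranges$speaker)
  if (anyNA(idx))
    stopf("no range for speaker(s): %s",
          paste(unique(x$speaker[is.na(idx)]), collapse = ", "),
          class = "tonetrace_validation_error")
  xmin <- ranges$xmin[idx]; xmax <- ranges$xmax[idx]
  tv <- hz_to_t(sm, xmin, xmax)
  out_of_range <- tv < 0 | tv > 5
  n_clamped <- sum(out_of_range)
  if (n_clamped > 0) {
    if (strict)
      stopf("%d sample(s) outside the speaker range", n_clamped,
            class = "tonetrace_range_violation")
    warnf("%d sample(s) outside [xmin, xmax]; clamped to [0, 5]", n_clamped)
    tv[tv < 0] <- 0
    tv[tv > 5] <- 5
  }
  meta <- as.data.frame(x)[setdiff(names(x), sample_cols(n))]
  colnames(tv) <- sample_cols(n, "t")
  structure(cbind(meta, as.data.frame(tv)),
            n_samples = n, clamped = n_clamped,
            class = c("t_set", "data.frame"))
}

#' Extract the T-value matrix of a `t_set`
#' @param x a `t_set`.
#' @return numeric matrix, one row per production.
#' @export
t_values <- function(x) {
  as.matrix(x[sample_cols(n_f0_samples(x), "t")])
}

#' @export
print.t_set <- function(x, ...) {
  cat(sprintf("<t_set> %d production(s), %d T-values each\n",
              nrow(x), n_f0_samples(x)))
  NextMethod()
}

# ---------------------------------------------------------------------------
# DCT machinery

# Type-II DCT basis: B[k+1, n+1] = cos(pi * k * (n + 1/2) / N).
dct_basis <- function(n, k_max = n - 1L) {
  k <- 0:k_max
  outer(k, (0:(n - 1)) + 0.5, function(k, m) cos(pi * k * m / n))
}

# Raw type-II coefficients c_k = sum_n x_n cos(pi k (n + 1/2) / N) for a
# matrix of contours (rows).
dct_raw <- function(X, k_max) {
  X %*% t(dct_basis(ncol(X), k_max))
}

# Orthonormal DCT-II of a single contour; satisfies Parseval
# (sum(y^2) == sum(x^2)). Internal sanity anchor for the scaling used in
# dct_coefs().
dct_ortho <- function(x) {
  n <- length(x)
  y <- drop(dct_basis(n) %*% x)
  y * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

#' First three DCT shape coefficients of a contour
#'
#' Type-II DCT `c_k = sum_n x_n cos(pi k (n + 1/2) / N)`, reported as
#' `dct1 = c_0 / N`, `dct2 = 2 c_1 / N`, `dct3 = 2 c_2 / N`. Under this
#' scaling `dct1` equals the arithmetic mean of the contour (T-value
#' units), `dct2` relates *negatively* to slope (rising contours give
#' negative values, falling positive) and `dct3` positively to curvature;
#' reversing a contour in time negates `dct2` and preserves `dct1`/`dct3`.
#'
#' @param x numeric contour (typically 16 T-values).
#' @return named numeric vector `c(dct1, dct2, dct3)`.
#' @export
dct_coefs <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3)
  n <- length(x)
  cc <- drop(dct_basis(n, 2L) %*% x)
  c(dct1 = cc[1] / n, dct2 = 2 * cc[2] / n, dct3 = 2 * cc[3] / n)
}

#' Duration statistics of a reference set
#'
#' Mean and standard deviation used to z-score production durations; by
#' convention computed over the target stimulus set and reused for all
#' productions.
#'
#' @param durations numeric durations in ms, or an [f0_set()].
#' @return list `mean`, `sd`.
#' @export
duration_stats <- function(durations) {
  if (inherits(durations, "f0_set")) durations <- durations$duration_ms
  s <- sd(durations)
  if (!is.finite(s) || s <= 0)
    stopf("reference durations have zero spread; cannot z-score",
          class = "tonetrace_degenerate_range")
  list(mean = mean(durations), sd = s)
}

#' DCT shape features per production
#'
#' Computes the 4-D feature vector used for tonal distances: the first
#' three DCT coefficients of the T-value contour ([dct_coefs()] scaling)
#' plus the z-scored duration.
#'
#' @param x a `t_set` from [t_normalize()].
#' @param dur_stats reference [duration_stats()] (target set).
#' @return data frame with the metadata of `x` plus `dct1`, `dct2`,
#'   `dct3`, `dur_z`; class `dct_features`.
#' @export
dct_features <- function(x, dur_stats) {
  stopifnot(inherits(x, "t_set"))
  n <- n_f0_samples(x)
  tv <- t_values(x)
  cc <- dct_raw(tv, 2L)
  meta <- as.data.frame(x)[setdiff(names(x), sample_cols(n, "t"))]
  meta$dct1 <- cc[, 1] / n
  meta$dct2 <- 2 * cc[, 2] / n
  meta$dct3 <- 2 * cc[, 3] / n
  meta$dur_z <- (x$duration_ms - dur_stats$mean) / dur_stats$sd
  structure(meta, class = c("dct_features", "data.frame"))
}

FEATURE_DIMS <- c("dct1", "dct2", "dct3", "dur_z")

# ---------------------------------------------------------------------------
# Centroids and distances

#' Per-tone centroids of the target feature set
#'
#' Arithmetic mean of the target stimuli's feature vectors per tone; the
#' reference points for [tonal_distance()]. All four tone categories must
#' be present.
#'
#' @param target_features a `dct_features` frame for the target stimuli.
#' @return data frame `tone`, `dct1`, `dct2`, `dct3`, `dur_z`,
#'   `n_targets`; class `tone_centroids`.
#' @export
tone_centroids <- function(target_features) {
  stopifnot(inherits(target_features, "dct_features"))
  missing_tones <- setdiff(TONE_LEVELS, unique(target_features$tone))
  if (length(missing_tones))
    stopf("target set lacks tone categor%s: %s",
          if (length(missing_tones) > 1) "ies" else "y",
          paste(missing_tones, collapse = ", "),
          class = "tonetrace_incomplete_reference")
  sp <- split(target_features[FEATURE_DIMS], target_features$tone)
  rows <- lapply(TONE_LEVELS, function(tn) {
    m <- colMeans(sp[[tn]])
    data.frame(tone = tn, dct1 = m[["dct1"]], dct2 = m[["dct2"]],
               dct3 = m[["dct3"]], dur_z = m[["dur_z"]],
               n_targets = nrow(sp[[tn]]), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("tone_centroids", "data.frame"))
}

#' Euclidean distance between two feature vectors
#' @param a,b numeric vectors of equal length, all components finite.
#' @return nonnegative scalar.
#' @export
feature_distance <- function(a, b) {
  if (length(a) != length(b) || !all(is.finite(c(a, b))))
    stopf("feature vectors must be equal-length and finite",
          class = "tonetrace_invalid_argument")
  sqrt(sum((a - b)^2))
}

#' Tonal distance of each production to its tone centroid
#'
#' Euclidean distance in `(dct1, dct2, dct3, dur_z)` space from each
#' production's feature vector to the centroid of its *target* tone. Larger
#' distance means a less target-like (less phonetically accurate)
#' production. By default the four dimensions are weighted equally on their
#' raw scales; `standardize = TRUE` divides each dimension by its standard
#' deviation over the target feature set first (requires `target_features`).
#'
#' @param features a `dct_features` frame.
#' @param centroids a [tone_centroids()] table.
#' @param standardize standardize dimensions by target-set spread.
#' @param target_features target features, needed when `standardize`.
#' @return `features` with an added `distance` column.
#' @export
tonal_distance <- function(features, centroids, standardize = FALSE,
                           target_features = NULL) {
  stopifnot(inherits(features, "dct_features"),
            inherits(centroids, "tone_centroids"))
  idx <- match(features$tone, centroids$tone)
  if (anyNA(idx))
    stopf("no centroid for tone(s): %s",
          paste(unique(features$tone[is.na(idx)]), collapse = ", "),
          class = "tonetrace_incomplete_reference")
  fm <- as.matrix(features[FEATURE_DIMS])
  cm <- as.matrix(centroids[FEATURE_DIMS])[idx, , drop = FALSE]
  if (!all(is.finite(fm)) || !all(is.finite(cm)))
    stopf("non-finite feature component",
          class = "tonetrace_invalid_argument")
  w <- rep(1, length(FEATURE_DIMS))
  if (standardize) {
    if (is.null(target_features))
      stopf("standardize = TRUE requires target_features",
            class = "tonetrace_invalid_argument")
    w <- 1 / vapply(target_features[FEATURE_DIMS], sd, numeric(1))
  }
  d <- sqrt(rowSums(((fm - cm) %*% diag(w))^2))
  features$distance <- d
  features
}

#' Write / read the centroid reference as JSON
#'
#' @param centroids a [tone_centroids()] table.
#' @param path JSON path.
#' @param dur_stats optional [duration_stats()] to embed alongside.
#' @return `write_centroids()` returns `path` invisibly; `read_centroids()`
#'   returns a list with elements `centroids` and (if present) `dur_stats`.
#' @export
write_centroids <- function(centroids, path, dur_stats = NULL) {
  obj <- list(centroids = lapply(seq_len(nrow(centroids)), function(i) {
    as.list(centroids[i, c("tone", FEATURE_DIMS, "n_targets")])
  }))
  if (!is.null(dur_stats)) obj$dur_stats <- dur_stats
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cen <- as.data.frame(obj$centroids, stringsAsFactors = FALSE)
  cen$n_targets <- as.integer(cen$n_targets)
  out <- list(centroids = structure(cen,
                                    class = c("tone_centroids",
                                              "data.frame")))
  if (!is.null(obj$dur_stats)) out$dur_stats <- as.list(obj$dur_stats)
  out
}
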