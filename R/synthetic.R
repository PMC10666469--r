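# Synthetic experiment generator: target stimuli from Chao tone
# specifications, distorted imitations with known slope-gain / level-raise
# parameters, picture-naming ledgers drawn from configurable confusion
# matrices, and a full two-group cohort with a ground-truth sidecar.

#' Map Chao pitch digits onto the T-value scale
#'
#' `d -> (d - 1) * 5 / 4`, so Chao 1 (lowest) maps to T = 0 and Chao 5
#' (highest) to T = 5, aligning the five-point Chao scale with the
#' endpoints of the speaker-relative T-value transform.
#'
#' @param d integer digit(s) in 1..5.
#' @return T-value(s) in `[0, 5]`.
#' @export
chao_to_t <- function(d) {
  if (any(d < 1 | d > 5))
    stopf("Chao digits must lie in 1..5",
          class = "tonetrace_validation_error")
  (d - 1) * 5 / 4
}

#' Tone specifications for the four-tone stimulus inventory
#'
#' Chao-digit onset/offset specifications of the four tones -- 15 (rise),
#' 51 (fall), 22 (mid-level), 11 (low-level) -- plus a curvature gain for
#' the raised-cosine bend of the contour family. Defaults give the rise a
#' mild bend and keep the fall a straight line, echoing the asymmetry of
#' natural productions; level tones are flat.
#'
#' @param tone tone names.
#' @param chao_onset,chao_offset Chao digits in 1..5 (equal for level
#'   tones).
#' @param curvature_gain raised-cosine bump amplitude in T-value units
#'   (negative = sagging/delayed contour).
#' @return data frame, class `tone_spec`.
#' @export
tone_specs <- function(tone = TONE_LEVELS,
                       chao_onset = c(1, 5, 2, 1),
                       chao_offset = c(5, 1, 2, 1),
                       curvature_gain = c(-0.3, 0, 0, 0)) {
  if (any(chao_onset < 1 | chao_onset > 5 | chao_offset < 1 |
            chao_offset > 5))
    stopf("Chao digits must lie in 1..5",
          class = "tonetrace_validation_error")
  level <- chao_onset == chao_offset
  structure(data.frame(tone = tone, chao_onset = chao_onset,
                       chao_offset = chao_offset,
                       curvature_gain = curvature_gain, level = level,
                       stringsAsFactors = FALSE),
            class = c("tone_spec", "data.frame"))
}

# T-value contour of one tone spec on normalized time [0, 1]:
# linear onset->offset interpolation plus a raised-cosine bump.
spec_contour <- function(onset_t, offset_t, curvature, n_points) {
  tt <- seq(0, 1, length.out = n_points)
  onset_t + (offset_t - onset_t) * tt + curvature * (1 - cos(2 * pi * tt)) / 2
}

#' Generate the target stimulus trajectories
#'
#' Crosses the tone specifications with the segmental frames (4 x 4 = 16
#' pseudowords with the defaults). Each contour is built in T-space from
#' the Chao onset/offset digits and converted to Hz with the inverse
#' T-value transform using the target speaker's range. Durations vary by
#' *tone* (fixed values, so the reference duration spread is nonzero while
#' all members of a tone category share one feature vector -- a perfect
#' imitation then sits exactly on its tone centroid).
#'
#' @param specs a [tone_specs()] table.
#' @param segments four segment-frame strings.
#' @param range named vector `c(xmin = , xmax = )`: the target speaker's
#'   F0 floor/ceiling in Hz.
#' @param n_points samples per trajectory (default 20).
#' @param durations_ms one duration per tone (row of `specs`), in ms.
#' @return an [f0_set()] with `group = "target"`, attribute `range` and
#'   attribute `t_matrix` (the noise-free T-value contours).
#' @export
make_target_stimuli <- function(specs = tone_specs(),
                                segments = c("non", "lon", "jar", "jur"),
                                range = c(xmin = 90, xmax = 180),
                                n_points = 20L,
                                durations_ms = c(430, 390, 400, 420)) {
  stopifnot(inherits(specs, "tone_spec"), length(segments) >= 1,
            length(durations_ms) == nrow(specs))
  rows <- list(); tmat <- list()
  for (si in seq_along(segments)) {
    for (ti in seq_len(nrow(specs))) {
      tv <- spec_contour(chao_to_t(specs$chao_onset[ti]),
                         chao_to_t(specs$chao_offset[ti]),
                         specs$curvature_gain[ti], n_points)
      hz <- t_to_hz(pmin(pmax(tv, 0), 5), range[["xmin"]], range[["xmax"]])
      chao_tag <- paste0(specs$chao_onset[ti] * 10 + specs$chao_offset[ti])
      row <- data.frame(speaker = "target", group = "target",
                        item = paste0(segments[si], chao_tag),
                        tone = specs$tone[ti], day = 1L,
                        duration_ms = durations_ms[ti],
                        stringsAsFactors = FALSE)
      row[sample_cols(n_points)] <- as.list(hz)
      rows[[length(rows) + 1L]] <- row
      tmat[[length(tmat) + 1L]] <- tv
    }
  }
  out <- f0_set(do.call(rbind, rows), n_points)
  attr(out, "range") <- range
  attr(out, "t_matrix") <- do.call(rbind, tmat)
  out
}

#' Speaker model for the imitation / naming simulators
#'
#' Bundles one simulated participant's voice and distortion parameters:
#'
#' * `f0_floor`, `f0_ceiling`: the speaker's Hz range (T = 0 and T = 5);
#' * `height_offset` (beta): upward T-value shift applied to *level*-tone
#'   imitations (non-native level tones tend to come out too high);
#' * `slope_gain` (gamma, in (0, 1]): compression of the contour's
#'   deviation from its mean (pitch-range compression of rises/falls);
#' * `curvature_gain` (kappa): scaling of the contour's curvature
#'   residual;
#' * `noise_sd` (sigma): white Gaussian noise per sample, T-value units;
#' * `duration_jitter_sd`: sd of multiplicative log-duration jitter;
#' * `confusion`: row-stochastic 4 x 4 matrix of tone-production
#'   probabilities (rows = target tone) used by
#'   [simulate_naming_ledger()].
#'
#' @param speaker_id,group identifiers.
#' @param f0_floor,f0_ceiling Hz, `0 < floor < ceiling`.
#' @param height_offset,slope_gain,curvature_gain,noise_sd,duration_jitter_sd
#'   distortion parameters (see above).
#' @param confusion 4 x 4 row-stochastic matrix in tone order rise, fall,
#'   mid, low; default identity.
#' @return list, class `speaker_model`.
#' @export
speaker_model <- function(speaker_id, group, f0_floor = 100,
                          f0_ceiling = 220, height_offset = 0,
                          slope_gain = 1, curvature_gain = 1,
                          noise_sd = 0, duration_jitter_sd = 0,
                          confusion = diag(4)) {
  if (f0_floor <= 0 || f0_floor >= f0_ceiling)
    stopf("require 0 < f0_floor < f0_ceiling",
          class = "tonetrace_validation_error")
  if (slope_gain <= 0 || slope_gain > 1)
    stopf("slope_gain must lie in (0, 1]",
          class = "tonetrace_validation_error")
  if (noise_sd < 0 || duration_jitter_sd < 0)
    stopf("noise sds must be nonnegative",
          class = "tonetrace_validation_error")
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4, 4)) ||
      any(abs(rowSums(confusion) - 1) > 1e-9) || any(confusion < 0))
    stopf("confusion must be a 4 x 4 row-stochastic matrix",
          class = "tonetrace_validation_error")
  dimnames(confusion) <- list(target = TONE_LEVELS, produced = TONE_LEVELS)
  structure(list(speaker_id = speaker_id, group = group,
                 f0_floor = f0_floor, f0_ceiling = f0_ceiling,
                 height_offset = height_offset, slope_gain = slope_gain,
                 curvature_gain = curvature_gain, noise_sd = noise_sd,
                 duration_jitter_sd = duration_jitter_sd,
                 confusion = confusion),
            class = "speaker_model")
}

#' Simulate imitations of the target stimuli
#'
#' Each imitation contour is built in T-space from the target contour's
#' decomposition into mean + linear part + curvature residual:
#'
#' `imitation = mean + gamma * (linear - mean) + kappa * curvature +
#' beta * 1[level tone] + N(0, sigma^2)` per sample,
#'
#' then converted to Hz with the imitating speaker's own range (values
#' pushed outside (0, 5) by the distortions are clamped with a warning).
#' With `gamma = kappa = 1`, `beta = 0`, `sigma = 0` the imitation equals
#' the target in T-space. Durations are the target durations under
#' multiplicative log-normal jitter.
#'
#' @param targets a [make_target_stimuli()] result.
#' @param model a [speaker_model()].
#' @param reps imitations per word per day.
#' @param days number of days.
#' @param seed optional integer; when given, output is a pure function of
#'   `(targets, model, reps, days, seed)`.
#' @return an [f0_set()] of `reps * days * nrow(targets)` imitations.
#' @export
simulate_imitations <- function(targets, model, reps = 2L, days = 2L,
                                seed = NULL) {
  stopifnot(inherits(targets, "f0_set"), inherits(model, "speaker_model"))
  tmat <- attr(targets, "t_matrix")
  if (is.null(tmat)) {
    rng <- attr(targets, "range") %||%
      stop("targets lack both t_matrix and range attributes")
    tmat <- hz_to_t(f0_samples(targets), rng[["xmin"]], rng[["xmax"]])
  }
  n_points <- ncol(tmat)
  tt <- seq(0, 1, length.out = n_points)
  with_seed(seed, {
    rows <- vector("list", nrow(targets) * days * reps)
    ri <- 0L
    n_clamped <- 0L
    for (i in seq_len(nrow(targets))) {
      tv <- tmat[i, ]
      lin <- tv[1] + (tv[n_points] - tv[1]) * tt
      curv <- tv - lin
      m <- mean(tv)
      is_level <- abs(tv[1] - tv[n_points]) < 1e-12 &&
        targets$tone[i] %in% c("mid", "low")
      base <- m + model$slope_gain * (lin - m) +
        model$curvature_gain * curv +
        if (is_level) model$height_offset else 0
      for (d in seq_len(days)) {
        for (r in seq_len(reps)) {
          sim <- base + rnorm(n_points, 0, model$noise_sd)
          out_of <- sim < 0 | sim > 5
          n_clamped <- n_clamped + sum(out_of)
          sim <- pmin(pmax(sim, 0), 5)
          hz <- t_to_hz(sim, model$f0_floor, model$f0_ceiling)
          dur <- targets$duration_ms[i] *
            exp(rnorm(1, 0, model$duration_jitter_sd))
          row <- data.frame(speaker = model$speaker_id,
                            group = model$group, item = targets$item[i],
                            tone = targets$tone[i], day = d,
                            duration_ms = dur, stringsAsFactors = FALSE)
          row[sample_cols(n_points)] <- as.list(hz)
          ri <- ri + 1L
          rows[[ri]] <- row
        }
      }
    }
    if (n_clamped > 0)
      warnf("%d simulated sample(s) left (0, 5) and were clamped",
            n_clamped)
    f0_set(do.call(rbind, rows), n_points)
  })
}

#' Simulate a picture-naming label ledger
#'
#' Per item and day: segments are produced correctly with probability
#' `p_segment_correct` (incorrect segmental productions draw another
#' inventory frame, or the deviant [NON_TARGET] marker with probability
#' `p_deviant`); the produced tone is drawn from the speaker's confusion
#' row for the target tone.
#'
#' @param model a [speaker_model()].
#' @param targets a [make_target_stimuli()] result (supplies items,
#'   target segments and tones).
#' @param days number of days.
#' @param p_segment_correct probability in `[0, 1]`; may be a vector with
#'   one entry per day (naming accuracy grows with training).
#' @param p_deviant probability that an incorrect segmental production is
#'   deviant rather than another inventory frame.
#' @param seed optional integer seed.
#' @return a production-label data frame for [score_production()].
#' @export
simulate_naming_ledger <- function(model, targets, days = 2L,
                                   p_segment_correct = 0.8,
                                   p_deviant = 0.05, seed = NULL) {
  stopifnot(inherits(model, "speaker_model"), inherits(targets, "f0_set"))
  if (any(p_segment_correct < 0 | p_segment_correct > 1) ||
      p_deviant < 0 || p_deviant > 1)
    stopf("probabilities must lie in [0, 1]",
          class = "tonetrace_validation_error")
  p_seg <- rep_len(p_segment_correct, days)
  seg_of <- sub("[0-9]+$", "", targets$item)
  inventory <- unique(seg_of)
  with_seed(seed, {
    rows <- list()
    for (d in seq_len(days)) {
      for (i in seq_len(nrow(targets))) {
        tgt_seg <- seg_of[i]
        if (runif(1) < p_seg[d]) {
          seg <- tgt_seg
        } else if (runif(1) < p_deviant || length(inventory) < 2) {
          seg <- NON_TARGET
        } else {
          seg <- sample(setdiff(inventory, tgt_seg), 1)
        }
        tone_probs <- model$confusion[targets$tone[i], ]
        produced_tone <- sample(TONE_LEVELS, 1, prob = tone_probs)
        rows[[length(rows) + 1L]] <-
          data.frame(speaker = model$speaker_id, group = model$group,
                     day = d, item = targets$item[i],
                     target_segments = tgt_seg,
                     target_tone = targets$tone[i],
                     produced_segments = seg,
                     produced_tone = produced_tone,
                     quality_flag = FALSE, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# ---------------------------------------------------------------------------
# Cohort-level simulation

#' Cohort configuration for [default_cohort()]
#'
#' Group-level parameter distributions for a two-group imitation +
#' picture-naming experiment. Defaults emulate a 41-speaker cohort
#' (21 English-L1, 20 Mandarin-L1, 2 days): level-tone raising
#' (`height_offset`) is stronger in the Mandarin group, slopes are
#' compressed in both groups, the Mandarin confusion matrix concentrates
#' low-tone errors on the mid category while the English matrix spreads
#' errors across the board, and a small Bernoulli dropout exercises the
#' exclusion ledger.
#'
#' @param n_english,n_mandarin,days,reps design sizes.
#' @param english,mandarin group parameter blocks: lists with means/sds of
#'   the [speaker_model()] parameters and a `confusion` matrix.
#' @param p_dropout per-trial probability of an excluded imitation trial.
#' @param p_naming_dropout per-trial probability of an excluded naming
#'   trial.
#' @param p_segment_correct per-day segmental naming accuracy.
#' @param noise_sd,duration_jitter_sd shared production noise parameters.
#' @return list, class `cohort_config`.
#' @export
cohort_config <- function(n_english = 21L, n_mandarin = 20L, days = 2L,
                          reps = 2L,
                          english = list(beta_mean = 0.2, beta_sd = 0.1,
                                         gamma_mean = 0.7, gamma_sd = 0.08,
                                         kappa_mean = 0.8, kappa_sd = 0.1,
                                         confusion = english_confusion()),
                          mandarin = list(beta_mean = 0.8, beta_sd = 0.15,
                                          gamma_mean = 0.75, gamma_sd = 0.08,
                                          kappa_mean = 0.9, kappa_sd = 0.1,
                                          confusion = mandarin_confusion()),
                          p_dropout = 21 / 2624,
                          p_naming_dropout = 4 / 1312,
                          p_segment_correct = c(0.45, 0.86),
                          noise_sd = 0.3, duration_jitter_sd = 0.08) {
  structure(list(n_english = n_english, n_mandarin = n_mandarin,
                 days = days, reps = reps, english = english,
                 mandarin = mandarin, p_dropout = p_dropout,
                 p_naming_dropout = p_naming_dropout,
                 p_segment_correct = p_segment_correct,
                 noise_sd = noise_sd,
                 duration_jitter_sd = duration_jitter_sd),
            class = "cohort_config")
}

#' Stock confusion matrices for the two L1 groups
#'
#' `mandarin_confusion()` keeps contour tones accurate and concentrates
#' low-tone errors on the mid-level category (low-to-mid dominance);
#' `english_confusion()` spreads errors nearly uniformly off the diagonal.
#' Rows are target tones in the order rise, fall, mid, low and sum to 1.
#'
#' @return 4 x 4 row-stochastic matrix.
#' @export
mandarin_confusion <- function() {
  m <- rbind(c(0.88, 0.06, 0.03, 0.03),
             c(0.06, 0.88, 0.03, 0.03),
             c(0.03, 0.03, 0.82, 0.12),
             c(0.03, 0.03, 0.35, 0.59))
  dimnames(m) <- list(target = TONE_LEVELS, produced = TONE_LEVELS)
  m
}

#' @rdname mandarin_confusion
#' @export
english_confusion <- function() {
  m <- matrix(0.10, 4, 4)
  diag(m) <- 0.70
  dimnames(m) <- list(target = TONE_LEVELS, produced = TONE_LEVELS)
  m
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Simulate a full two-group experiment
#'
#' Draws per-speaker [speaker_model()] parameters from the configured
#' group distributions, simulates imitation trajectories and
#' picture-naming ledgers for every speaker, applies Bernoulli dropout to
#' exercise the exclusion accounting, and returns everything together
#' with a ground-truth sidecar of the drawn parameters.
#'
#' @param config a [cohort_config()].
#' @param seed integer; the whole cohort is a deterministic function of
#'   `(config, seed)`.
#' @return list with elements `targets` ([make_target_stimuli()]),
#'   `imitations` (an [f0_set()] with attached exclusion `ledger`),
#'   `naming` (label ledger with attached `ledger` attribute),
#'   `speakers` (ground-truth parameter data frame) and `config`.
#' @export
default_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  targets <- make_target_stimuli()
  with_seed(seed, {
    ids <- c(sprintf("E%02d", seq_len(config$n_english)),
             sprintf("M%02d", seq_len(config$n_mandarin)))
    groups <- c(rep("english", config$n_english),
                rep("mandarin", config$n_mandarin))
    speakers <- list(); imit <- list(); naming <- list()
    for (i in seq_along(ids)) {
      par <- config[[groups[i]]]
      floor_hz <- rtrunc_norm(1, 120, 25, lo = 70)
      ceiling_hz <- floor_hz * rtrunc_norm(1, 2.0, 0.2, lo = 1.5)
      beta <- rtrunc_norm(1, par$beta_mean, par$beta_sd, lo = 0)
      gamma <- rtrunc_norm(1, par$gamma_mean, par$gamma_sd,
                           lo = 0.05, hi = 1)
      kappa <- rtrunc_norm(1, par$kappa_mean, par$kappa_sd, lo = 0)
      model <- speaker_model(ids[i], groups[i], floor_hz, ceiling_hz,
                             height_offset = beta, slope_gain = gamma,
                             curvature_gain = kappa,
                             noise_sd = config$noise_sd,
                             duration_jitter_sd =
                               config$duration_jitter_sd,
                             confusion = par$confusion)
      speakers[[i]] <- data.frame(speaker = ids[i], group = groups[i],
                                  f0_floor = floor_hz,
                                  f0_ceiling = ceiling_hz,
                                  height_offset = beta, slope_gain = gamma,
                                  curvature_gain = kappa,
                                  noise_sd = config$noise_sd,
                                  stringsAsFactors = FALSE)
      imit[[i]] <- suppressWarnings(
        simulate_imitations(targets, model, reps = config$reps,
                            days = config$days))
      naming[[i]] <- simulate_naming_ledger(
        model, targets, days = config$days,
        p_segment_correct = config$p_segment_correct)
    }
    imitations <- do.call(rbind, imit)
    imitations <- f0_set(imitations, n_f0_samples(imit[[1]]))
    naming_df <- do.call(rbind, naming)

    # imitation dropout + ledger
    keys <- f0_keys(imitations)
    ledger <- exclusion_ledger(keys)
    drop_i <- which(runif(nrow(imitations)) < config$p_dropout)
    if (length(drop_i)) {
      reasons <- sample(c("recording_error", "non_response"),
                        length(drop_i), replace = TRUE)
      ledger <- exclude_trials(ledger, keys[drop_i], reasons)
      imitations <- imitations[-drop_i, , drop = FALSE]
      class(imitations) <- c("f0_set", "data.frame")
      attr(imitations, "n_samples") <- n_f0_samples(targets)
    }
    attr(imitations, "ledger") <- ledger

    # naming dropout + ledger
    nkeys <- trial_key(naming_df$speaker, naming_df$day, naming_df$item)
    nledger <- exclusion_ledger(nkeys)
    drop_n <- which(runif(nrow(naming_df)) < config$p_naming_dropout)
    if (length(drop_n)) {
      nledger <- exclude_trials(nledger, nkeys[drop_n],
                                rep("bad_quality", length(drop_n)))
      naming_df <- naming_df[-drop_n, , drop = FALSE]
    }
    attr(naming_df, "ledger") <- nledger

    list(targets = targets, imitations = imitations, naming = naming_df,
         speakers = do.call(rbind, speakers), config = config)
  })
}

#' Recover distortion parameters from analyzed features
#'
#' Ground-truth recovery harness for the generator: imitations and targets
#' are normalized with their *true* speaker ranges (from the cohort
#' sidecar), DCT features are computed, and per speaker the slope gain
#' gamma is estimated as the mean ratio of imitation to target `dct2` over
#' contour-tone tokens, the level raise beta as the mean `dct1` difference
#' over level-tone tokens. Observed (compressed) ranges cannot be used
#' here: normalizing by the extremes of a compressed contour would rescale
#' away the compression being estimated.
#'
#' @param imitations an [f0_set()] of simulated imitations.
#' @param targets the [make_target_stimuli()] set they imitate.
#' @param ranges a [speaker_range_table()] with the true floors/ceilings.
#' @param n_drop edge truncation applied to both sets (default 2).
#' @return data frame `speaker`, `gamma_hat`, `beta_hat`.
#' @export
recover_imitation_params <- function(imitations, targets, ranges,
                                     n_drop = 2L) {
  tr <- attr(targets, "range")
  t_targets <- t_normalize(truncate_edges(targets, n_drop),
                           speaker_range_table("target", tr[["xmin"]],
                                               tr[["xmax"]]))
  dstats <- duration_stats(targets)
  tf <- dct_features(t_targets, dstats)
  t_imit <- t_normalize(truncate_edges(imitations, n_drop), ranges)
  fi <- dct_features(t_imit, dstats)
  tgt_idx <- match(fi$item, tf$item)
  ratio <- fi$dct2 / tf$dct2[tgt_idx]
  d1diff <- fi$dct1 - tf$dct1[tgt_idx]
  is_level <- fi$tone %in% c("mid", "low")
  sp <- split(seq_len(nrow(fi)), fi$speaker)
  out <- lapply(names(sp), function(s) {
    i <- sp[[s]]
    data.frame(speaker = s,
               gamma_hat = mean(ratio[i][!is_level[i]]),
               beta_hat = mean(d1diff[i][is_level[i]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write the ground-truth sidecar of a simulated cohort
#' @param cohort a [default_cohort()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  jsonlite::write_json(list(speakers = cohort$speakers,
                            noise_sd = cohort$config$noise_sd),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
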