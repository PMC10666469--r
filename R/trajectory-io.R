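# Ingestion, validation, repair and truncation of time-normalized F0
# trajectories (ProsodyPro-style tables and Praat PitchTier files), plus the
# planned-design / exclusion bookkeeping that keeps trial counts honest.

#' Construct a set of F0 trajectories
#'
#' An `f0_set` is a plain data frame with one production per row: metadata
#' columns `speaker`, `group`, `item`, `tone`, `day`, `duration_ms` followed
#' by `n_samples` F0 sample columns (`f01`, `f02`, ...) in Hz. Sample values
#' may be `NA` before repair; non-missing samples must be positive.
#'
#' @param df data frame holding the metadata and sample columns.
#' @param n_samples number of F0 sample columns expected (20 on ingestion,
#'   16 after edge truncation).
#' @return `df` with class `f0_set` and attribute `n_samples`.
#' @seealso [read_normtime_table()], [repair_contour()], [truncate_edges()]
#' @export
f0_set <- function(df, n_samples = 20L) {
  need <- c("speaker", "group", "item", "tone", "day", "duration_ms",
            sample_cols(n_samples))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("f0_set is missing column(s): %s", paste(miss, collapse = ", "),
          class = "tonetrace_format_error")
  assert_tones(df$tone)
  sm <- as.matrix(df[sample_cols(n_samples)])
  if (any(sm <= 0, na.rm = TRUE))
    stopf("non-missing F0 samples must be > 0 Hz",
          class = "tonetrace_validation_error")
  if (any(!is.na(df$duration_ms) & df$duration_ms <= 0))
    stopf("duration_ms must be > 0", class = "tonetrace_validation_error")
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            n_samples = as.integer(n_samples),
            class = c("f0_set", "data.frame"))
}

#' @export
print.f0_set <- function(x, ...) {
  cat(sprintf("<f0_set> %d production(s), %d samples each\n",
              nrow(x), n_f0_samples(x)))
  NextMethod()
}

#' Number of F0 samples per trajectory
#' @param x an `f0_set` or `t_set`.
#' @return integer sample count.
#' @export
n_f0_samples <- function(x) {
  attr(x, "n_samples") %||% sum(grepl("^f[0-9]{2}$", names(x)))
}

#' Extract the sample matrix of an `f0_set`
#' @param x an `f0_set`.
#' @return numeric matrix, one row per production.
#' @export
f0_samples <- function(x) {
  as.matrix(x[sample_cols(n_f0_samples(x))])
}

`f0_samples<-` <- function(x, value) {
  x[sample_cols(n_f0_samples(x))] <- value
  x
}

f0_keys <- function(x) {
  occ <- stats::ave(seq_len(nrow(x)),
                    paste(x$speaker, x$day, x$item, sep = "|"),
                    FUN = seq_along)
  trial_key(x$speaker, x$day, x$item, occ)
}

# ---------------------------------------------------------------------------
# Normtime table I/O

#' Column mapping for time-normalized F0 tables
#'
#' Describes how a tab-separated time-normalized F0 table maps onto the
#' canonical `f0_set` columns, so tables produced by different tools
#' (ProsodyPro exports, custom scripts) can be ingested without editing the
#' file. `missing_tokens` are cell values treated as missing F0
#' (ProsodyPro writes `--undefined--`; other tools write `NA` or leave the
#' cell empty).
#'
#' @param speaker,group,item,tone,day,duration names of the metadata columns
#'   in the file.
#' @param sample_prefix common prefix of the F0 sample columns.
#' @param n_samples number of sample columns (20 for standard exports).
#' @param missing_tokens character vector of cell values parsed as `NA`.
#' @return a named list used by [read_normtime_table()].
#' @export
normtime_dialect <- function(speaker = "speaker", group = "group",
                             item = "item", tone = "tone", day = "day",
                             duration = "duration_ms",
                             sample_prefix = "f", n_samples = 20L,
                             missing_tokens = c("--undefined--", "NA", "NaN",
                                                "")) {
  list(speaker = speaker, group = group, item = item, tone = tone, day = day,
       duration = duration, sample_prefix = sample_prefix,
       n_samples = as.integer(n_samples), missing_tokens = missing_tokens)
}

#' Read a time-normalized F0 table
#'
#' Reads a tab-separated table with one production per row and a fixed
#' number of equidistant F0 samples, as produced by ProsodyPro-style
#' normalized-time analyses. Unparseable or missing-token F0 cells become
#' `NA` samples (to be repaired with [repair_contour()]); the planned design
#' implied by the file's rows is recorded in an [exclusion_ledger()]
#' attached as attribute `"ledger"`.
#'
#' @param path path to the TSV file.
#' @param dialect a [normtime_dialect()] naming the columns.
#' @return an [f0_set()] with attribute `ledger`.
#' @export
read_normtime_table <- function(path, dialect = normtime_dialect()) {
  if (!file.exists(path))
    stopf("file not found: %s", path, class = "tonetrace_io_error")
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  meta_map <- c(speaker = dialect$speaker, group = dialect$group,
                item = dialect$item, tone = dialect$tone, day = dialect$day,
                duration_ms = dialect$duration)
  miss <- setdiff(unname(meta_map), names(raw))
  if (length(miss))
    stopf("mandatory column(s) missing from %s: %s", path,
          paste(miss, collapse = ", "), class = "tonetrace_format_error")
  fcols <- sample_cols(dialect$n_samples, dialect$sample_prefix)
  fmiss <- setdiff(fcols, names(raw))
  if (length(fmiss))
    stopf(paste0("dialect expects %d sample columns ('%s...'); missing: ",
                 "%s"), dialect$n_samples, fcols[1],
          paste(fmiss, collapse = ", "), class = "tonetrace_dialect_error")

  df <- data.frame(
    speaker = raw[[meta_map["speaker"]]],
    group = raw[[meta_map["group"]]],
    item = raw[[meta_map["item"]]],
    tone = raw[[meta_map["tone"]]],
    day = as.integer(raw[[meta_map["day"]]]),
    duration_ms = as.numeric(raw[[meta_map["duration_ms"]]]),
    stringsAsFactors = FALSE)
  sm <- vapply(raw[fcols], parse_f0, numeric(nrow(raw)),
               missing_tokens = dialect$missing_tokens)
  sm <- matrix(sm, nrow = nrow(raw),
               dimnames = list(NULL, sample_cols(dialect$n_samples)))
  df[colnames(sm)] <- as.data.frame(sm)
  x <- f0_set(df, dialect$n_samples)
  attr(x, "ledger") <- exclusion_ledger(f0_keys(x))
  x
}

parse_f0 <- function(v, missing_tokens) {
  v <- trimws(v)
  v[v %in% missing_tokens] <- NA_character_
  out <- suppressWarnings(as.numeric(v))
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Write an `f0_set` as a time-normalized table
#'
#' Inverse of [read_normtime_table()] with the default dialect; round-trips
#' field-for-field (missing samples written as `NA`).
#'
#' @param x an [f0_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_normtime_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Planned designs and exclusion bookkeeping

#' Planned trial designs for imitation and picture-naming tasks
#'
#' `imitation_design()` enumerates the planned imitation trials that enter
#' analysis (`n_reps` analyzed imitations x `n_items` pseudowords x
#' `n_speakers` x `n_days`); with the defaults this is the 2 x 16 x 41 x 2 =
#' 2624-trial design. `naming_design()` enumerates the picture-naming trials
#' (16 x 41 x 2 = 1312 with defaults). `imitation_task_design()` enumerates
#' the trials *presented* in the task, where each word occurs
#' `n_presentations` times per day (64 trials per participant per day with
#' the defaults).
#'
#' @param n_speakers,n_items,n_days,n_reps,n_presentations design sizes.
#' @param speakers,items optional id vectors; generated (`S01`..., `w01`...)
#'   when omitted.
#' @return data frame of planned trial keys with columns `speaker`, `day`,
#'   `item`, (`rep`,) `key`.
#' @export
imitation_design <- function(n_speakers = 41L, n_items = 16L, n_days = 2L,
                             n_reps = 2L, speakers = NULL, items = NULL) {
  speakers <- speakers %||% sprintf("S%02d", seq_len(n_speakers))
  items <- items %||% sprintf("w%02d", seq_len(n_items))
  g <- expand.grid(rep = seq_len(n_reps), item = items,
                   day = seq_len(n_days), speaker = speakers,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[c("speaker", "day", "item", "rep")]
  g$key <- trial_key(g$speaker, g$day, g$item, g$rep)
  g
}

#' @rdname imitation_design
#' @export
imitation_task_design <- function(n_speakers = 41L, n_items = 16L,
                                  n_days = 2L, n_presentations = 4L) {
  imitation_design(n_speakers, n_items, n_days, n_reps = n_presentations)
}

#' @rdname imitation_design
#' @export
naming_design <- function(n_speakers = 41L, n_items = 16L, n_days = 2L,
                          speakers = NULL, items = NULL) {
  speakers <- speakers %||% sprintf("S%02d", seq_len(n_speakers))
  items <- items %||% sprintf("w%02d", seq_len(n_items))
  g <- expand.grid(item = items, day = seq_len(n_days), speaker = speakers,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[c("speaker", "day", "item")]
  g$key <- trial_key(g$speaker, g$day, g$item)
  g
}

#' Exclusion ledger: planned vs retained trial accounting
#'
#' Tracks which planned trials were excluded and why, enforcing the
#' conservation rule `retained = planned - excluded`. Every excluded key
#' must exist in the planned design; excluding the same key twice is an
#' error.
#'
#' @param planned_keys character vector of planned trial keys, or a design
#'   data frame with a `key` column ([imitation_design()]).
#' @param ledger an `exclusion_ledger`.
#' @param keys keys to exclude.
#' @param reason one of `"recording_error"`, `"non_response"`,
#'   `"uncategorizable_tone"`, `"bad_quality"` (recycled over `keys`).
#' @return `exclusion_ledger()` and `exclude_trials()` return an
#'   `exclusion_ledger`; `ledger_counts()` returns a named list
#'   `planned` / `excluded` / `retained`.
#' @export
exclusion_ledger <- function(planned_keys) {
  if (is.data.frame(planned_keys)) planned_keys <- planned_keys$key
  if (anyDuplicated(planned_keys))
    stopf("planned design contains duplicate keys",
          class = "tonetrace_validation_error")
  structure(list(planned = as.character(planned_keys),
                 exclusions = data.frame(key = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE)),
            class = "exclusion_ledger")
}

#' @rdname exclusion_ledger
#' @export
exclude_trials <- function(ledger, keys, reason) {
  stopifnot(inherits(ledger, "exclusion_ledger"))
  if (!length(keys)) return(ledger)
  reason <- rep_len(as.character(reason), length(keys))
  bad_reason <- setdiff(reason, EXCLUSION_REASONS)
  if (length(bad_reason))
    stopf("unknown exclusion reason(s): %s",
          paste(bad_reason, collapse = ", "),
          class = "tonetrace_validation_error")
  orphan <- setdiff(keys, ledger$planned)
  if (length(orphan))
    stopf("excluded key(s) not in the planned design: %s",
          paste(utils::head(orphan, 5), collapse = ", "),
          class = "tonetrace_validation_error")
  dup <- intersect(keys, ledger$exclusions$key)
  if (length(dup))
    stopf("key(s) already excluded: %s", paste(dup, collapse = ", "),
          class = "tonetrace_validation_error")
  ledger$exclusions <- rbind(ledger$exclusions,
                             data.frame(key = as.character(keys),
                                        reason = reason,
                                        stringsAsFactors = FALSE))
  ledger
}

#' @rdname exclusion_ledger
#' @export
ledger_counts <- function(ledger) {
  stopifnot(inherits(ledger, "exclusion_ledger"))
  planned <- length(ledger$planned)
  excluded <- nrow(ledger$exclusions)
  list(planned = planned, excluded = excluded,
       retained = planned - excluded)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  n <- ledger_counts(x)
  cat(sprintf("<exclusion_ledger> planned %d, excluded %d, retained %d\n",
              n$planned, n$excluded, n$retained))
  if (n$excluded) print(table(x$exclusions$reason))
  invisible(x)
}

#' Write the exclusion report
#' @param ledger an [exclusion_ledger()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(ledger, path) {
  write.table(ledger$exclusions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Contour repair and truncation

#' Repair one sampled contour
#'
#' Low-level workhorse behind [repair_contour()]: missing samples and
#' octave-jump spikes are replaced by linear interpolation in log-F0 between
#' the nearest valid neighbours (geometric interpolation in Hz); leading and
#' trailing invalid samples are filled with the nearest valid value.
#'
#' A sample is treated as a spike when the ratio `max(r, 1/r)` to *both* its
#' nearest valid neighbours exceeds `jump_ratio` (for edge samples: the
#' ratio to the single neighbour exceeds it while the next two samples agree
#' with each other). This is an explicit automated stand-in for the manual
#' correction of pitch excursions that a rater would do.
#'
#' @param x numeric vector of F0 samples in Hz (`NA` allowed).
#' @param jump_ratio spike threshold on consecutive-sample ratios;
#'   default 1.8 (just under an octave).
#' @return list with `values` (repaired vector) and `repaired` (integer
#'   positions that were replaced).
#' @export
repair_samples <- function(x, jump_ratio = 1.8) {
  stopifnot(is.numeric(x), jump_ratio > 1)
  bad <- is.na(x) | x <= 0
  n <- length(x)
  if (sum(!bad) < 2)
    stopf("fewer than 2 valid samples: contour is irreparable",
          class = "tonetrace_irreparable_error")
  ratio <- function(a, b) pmax(a / b, b / a)
  valid_idx <- which(!bad)
  spike <- logical(n)
  for (i in valid_idx) {
    left <- valid_idx[valid_idx < i]
    right <- valid_idx[valid_idx > i]
    l <- if (length(left)) max(left) else NA_integer_
    r <- if (length(right)) min(right) else NA_integer_
    if (!is.na(l) && !is.na(r)) {
      spike[i] <- ratio(x[i], x[l]) > jump_ratio &&
        ratio(x[i], x[r]) > jump_ratio
    } else if (is.na(l) && !is.na(r)) {
      r2 <- valid_idx[valid_idx > r]
      r2 <- if (length(r2)) min(r2) else NA_integer_
      spike[i] <- ratio(x[i], x[r]) > jump_ratio &&
        (is.na(r2) || ratio(x[r], x[r2]) <= jump_ratio)
    } else if (!is.na(l) && is.na(r)) {
      l2 <- valid_idx[valid_idx < l]
      l2 <- if (length(l2)) max(l2) else NA_integer_
      spike[i] <- ratio(x[i], x[l]) > jump_ratio &&
        (is.na(l2) || ratio(x[l], x[l2]) <= jump_ratio)
    }
  }
  fix <- bad | spike
  if (!any(fix)) return(list(values = x, repaired = integer()))
  if (sum(!fix) < 2)
    stopf("fewer than 2 valid samples after spike removal: irreparable",
          class = "tonetrace_irreparable_error")
  keep <- which(!fix)
  # log-domain interpolation; rule = 2 extends edges with nearest valid value
  logy <- approx(keep, log(x[keep]), xout = seq_len(n), method = "linear",
                 rule = 2)$y
  out <- x
  out[fix] <- exp(logy[fix])
  list(values = out, repaired = which(fix))
}

#' Repair missing samples and octave-jump spikes in an `f0_set`
#'
#' Applies [repair_samples()] to every trajectory. Contours with fewer than
#' two valid samples are irreparable: they are dropped from the returned set
#' and routed to the ledger with reason `"bad_quality"`.
#'
#' @param x an [f0_set()].
#' @param jump_ratio see [repair_samples()].
#' @return repaired `f0_set` with attributes `repairs` (data frame
#'   `key`/`position`), `excluded` (data frame `key`/`reason`) and, when `x`
#'   carried a ledger, an updated `ledger`.
#' @export
repair_contour <- function(x, jump_ratio = 1.8) {
  stopifnot(inherits(x, "f0_set"))
  sm <- f0_samples(x)
  keys <- f0_keys(x)
  repairs <- list()
  drop <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    res <- tryCatch(repair_samples(sm[i, ], jump_ratio),
                    tonetrace_irreparable_error = function(e) NULL)
    if (is.null(res)) {
      drop[i] <- TRUE
    } else {
      sm[i, ] <- res$values
      if (length(res$repaired))
        repairs[[length(repairs) + 1L]] <-
          data.frame(key = keys[i], position = res$repaired,
                     stringsAsFactors = FALSE)
    }
  }
  out <- x[!drop, , drop = FALSE]
  f0_samples(out) <- sm[!drop, , drop = FALSE]
  attr(out, "n_samples") <- n_f0_samples(x)
  class(out) <- class(x)
  attr(out, "repairs") <- if (length(repairs)) do.call(rbind, repairs)
  else data.frame(key = character(), position = integer())
  excluded <- data.frame(key = keys[drop],
                         reason = rep("bad_quality", sum(drop)),
                         stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  ledger <- attr(x, "ledger")
  if (!is.null(ledger))
    attr(out, "ledger") <- exclude_trials(ledger, excluded$key,
                                          excluded$reason)
  out
}

#' Truncate trajectory edges
#'
#' Drops the first and last `n_drop` samples of every trajectory (edge
#' samples of pitch tracks are excursion-prone); sample columns are
#' renumbered from `f01`. Metadata and attached ledger are preserved.
#'
#' @param x an [f0_set()].
#' @param n_drop samples to drop at each edge (default 2: 20 points
#'   become 16).
#' @return truncated `f0_set`.
#' @export
truncate_edges <- function(x, n_drop = 2L) {
  stopifnot(inherits(x, "f0_set"), n_drop >= 0)
  n <- n_f0_samples(x)
  if (n <= 2L * n_drop)
    stopf("cannot drop %d samples per edge from %d-point trajectories",
          n_drop, n, class = "tonetrace_invalid_argument")
  if (n_drop == 0L) return(x)
  keep <- seq.int(n_drop + 1L, n - n_drop)
  meta <- as.data.frame(x)[setdiff(names(x), sample_cols(n))]
  sm <- f0_samples(x)[, keep, drop = FALSE]
  colnames(sm) <- sample_cols(length(keep))
  out <- cbind(meta, as.data.frame(sm))
  attr_keep <- c("ledger", "repairs", "excluded")
  out <- structure(out, n_samples = length(keep),
                   class = c("f0_set", "data.frame"))
  for (a in attr_keep) attr(out, a) <- attr(x, a)
  out
}

# ---------------------------------------------------------------------------
# Praat PitchTier input

#' Read a Praat PitchTier text file
#'
#' Supports both the "short" and "long" Praat text dialects; both yield the
#' same `(time, f0)` pairs, returned in ascending time.
#'
#' @param path path to the PitchTier file.
#' @return data frame with columns `time` (s) and `f0` (Hz), class
#'   `pitchtier`, attributes `xmin`/`xmax`.
#' @export
read_pitchtier <- function(path) {
  if (!file.exists(path))
    stopf("file not found: %s", path, class = "tonetrace_io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !grepl("ooTextFile", lines[1]) ||
      !grepl("PitchTier", lines[2]))
    stopf("malformed PitchTier header in %s", path,
          class = "tonetrace_format_error")
  body <- lines[-(1:2)]
  num_of <- function(s) suppressWarnings(as.numeric(sub(".*=", "", s)))
  if (any(grepl("number\\s*=", body))) {          # long dialect
    xmin <- num_of(grep("xmin\\s*=", body, value = TRUE)[1])
    xmax <- num_of(grep("xmax\\s*=", body, value = TRUE)[1])
    tt <- num_of(grep("number\\s*=", body, value = TRUE))
    ff <- num_of(grep("value\\s*=", body, value = TRUE))
    if (length(tt) != length(ff))
      stopf("unbalanced number/value lines in %s", path,
            class = "tonetrace_format_error")
  } else {                                        # short dialect
    nums <- suppressWarnings(as.numeric(trimws(body[nzchar(trimws(body))])))
    if (anyNA(nums) || length(nums) < 3)
      stopf("malformed short-format PitchTier body in %s", path,
            class = "tonetrace_format_error")
    xmin <- nums[1]; xmax <- nums[2]; npt <- nums[3]
    if (length(nums) != 3 + 2 * npt)
      stopf("PitchTier declares %d points but body has %d numbers", npt,
            length(nums) - 3, class = "tonetrace_format_error")
    tt <- nums[3 + 2 * seq_len(npt) - 1]
    ff <- nums[3 + 2 * seq_len(npt)]
  }
  if (!length(tt))
    stopf("PitchTier %s contains zero points", path,
          class = "tonetrace_empty_input")
  ord <- order(tt)
  structure(data.frame(time = tt[ord], f0 = ff[ord]),
            xmin = xmin, xmax = xmax,
            class = c("pitchtier", "data.frame"))
}

#' Resample a PitchTier to equidistant points
#'
#' Linear interpolation between the tier's anchor points over its voiced
#' span (first to last point); endpoints are preserved exactly.
#'
#' @param pt a [read_pitchtier()] result.
#' @param n number of equidistant samples (default 20).
#' @return numeric vector of length `n` with attribute `time`.
#' @export
resample_pitchtier <- function(pt, n = 20L) {
  stopifnot(inherits(pt, "pitchtier"), n >= 2)
  if (nrow(pt) < 2)
    stopf("need at least 2 points to resample",
          class = "tonetrace_empty_input")
  tt <- seq(min(pt$time), max(pt$time), length.out = n)
  f0 <- approx(pt$time, pt$f0, xout = tt, method = "linear", ties = mean)$y
  structure(f0, time = tt)
}
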