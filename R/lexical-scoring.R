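# Categorical phono-lexical scoring of picture-naming productions:
# correct / tone-only error / segment error / non-target / excluded, the
# 12-type tone-only error taxonomy, and per-speaker accuracy summaries.

OUTCOME_LEVELS <- c("correct", "tone_only_error", "segment_error",
                    "non_target", "excluded")

#' Marker for segmentally deviant (non-target-like) productions
#' @export
NON_TARGET <- "NON_TARGET"

#' Marker for tone productions not categorizable into the four tones
#' @export
UNCATEGORIZABLE <- "UNCATEGORIZABLE"

#' Score picture-naming productions
#'
#' Classifies each labeled production into exactly one category:
#'
#' * `correct` -- segments and tone both match the target;
#' * `tone_only_error` -- segments match, tone category differs (the
#'   production fails purely on its tonal properties);
#' * `segment_error` -- segments differ from the target but are
#'   target-like (drawn from the experiment's segment inventory);
#' * `non_target` -- segments clearly deviant from any target word
#'   (inventory miss or explicit [NON_TARGET] marker);
#' * `excluded` -- quality-flagged trials, non-responses (empty produced
#'   segments) and productions whose tone is [UNCATEGORIZABLE].
#'
#' For tone-only errors, `error_type` records the ordered pair
#' `"<target>-to-<produced>"` (12 possible types).
#'
#' @param labels data frame with columns `speaker`, `group`, `day`, `item`,
#'   `target_segments`, `target_tone`, `produced_segments`,
#'   `produced_tone`, and optionally `quality_flag` (logical).
#' @param segment_inventory character vector of target-like segment
#'   strings; defaults to the unique `target_segments` in `labels`.
#' @return `labels` with added columns `category` and `error_type`;
#'   class `naming_outcome`.
#' @export
score_production <- function(labels, segment_inventory = NULL) {
  need <- c("speaker", "group", "day", "item", "target_segments",
            "target_tone", "produced_segments", "produced_tone")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    stopf("label ledger is missing column(s): %s",
          paste(miss, collapse = ", "), class = "tonetrace_format_error")
  assert_tones(labels$target_tone)
  assert_tones(labels$produced_tone, allow = c(TONE_LEVELS, UNCATEGORIZABLE),
               what = "produced tone")
  segment_inventory <- segment_inventory %||%
    unique(labels$target_segments)
  quality <- if ("quality_flag" %in% names(labels))
    isTRUE_vec(labels$quality_flag) else rep(FALSE, nrow(labels))
  seg <- as.character(labels$produced_segments)
  non_response <- is.na(seg) | !nzchar(seg)

  excluded <- quality | non_response |
    labels$produced_tone == UNCATEGORIZABLE
  seg_match <- !excluded & seg == labels$target_segments
  tone_match <- labels$produced_tone == labels$target_tone
  category <- rep(NA_character_, nrow(labels))
  category[excluded] <- "excluded"
  category[seg_match & tone_match] <- "correct"
  category[seg_match & !tone_match] <- "tone_only_error"
  deviant <- !excluded & !seg_match &
    (seg == NON_TARGET | !(seg %in% segment_inventory))
  category[deviant] <- "non_target"
  category[is.na(category)] <- "segment_error"

  labels$category <- factor(category, levels = OUTCOME_LEVELS)
  labels$error_type <- ifelse(category == "tone_only_error",
                              paste(labels$target_tone, labels$produced_tone,
                                    sep = "-to-"),
                              NA_character_)
  structure(labels, class = c("naming_outcome", "data.frame"))
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' The 12 tone-only error types in canonical display order
#'
#' Ordered pairs `target-to-produced` over the tone order rise, fall, mid,
#' low, excluding the diagonal.
#'
#' @return character vector of length 12.
#' @export
error_type_levels <- function() {
  g <- expand.grid(produced = TONE_LEVELS, target = TONE_LEVELS,
                   stringsAsFactors = FALSE)
  g <- g[g$target != g$produced, ]
  g <- g[order(match(g$target, TONE_LEVELS), match(g$produced, TONE_LEVELS)), ]
  paste(g$target, g$produced, sep = "-to-")
}

#' Tabulate target x produced tone counts
#'
#' Builds the 4 x 4 tone table per grouping cell from segmentally correct
#' productions: the diagonal counts tone-correct items, the 12 off-diagonal
#' cells count the tone-only error types. Zero cells are retained.
#'
#' @param outcomes a [score_production()] result.
#' @param by character vector of grouping columns (default `"group"`);
#'   `character(0)` pools everything.
#' @return a named list of 4 x 4 integer matrices (rows = target tone,
#'   columns = produced tone), class `error_table`.
#' @export
tabulate_errors <- function(outcomes, by = "group") {
  stopifnot(inherits(outcomes, "naming_outcome"))
  seg_ok <- outcomes$category %in% c("correct", "tone_only_error")
  sub <- outcomes[seg_ok, , drop = FALSE]
  cell <- if (length(by)) {
    interaction(sub[by], drop = FALSE, sep = "|", lex.order = TRUE)
  } else factor(rep("all", nrow(sub)))
  all_cells <- if (length(by) && nrow(outcomes)) {
    levels(interaction(outcomes[by], drop = TRUE, sep = "|",
                       lex.order = TRUE))
  } else "all"
  out <- lapply(all_cells, function(g) {
    s <- sub[as.character(cell) == g, , drop = FALSE]
    tab <- table(factor(s$target_tone, TONE_LEVELS),
                 factor(s$produced_tone, TONE_LEVELS))
    m <- matrix(as.integer(tab), 4, 4,
                dimnames = list(target = TONE_LEVELS,
                                produced = TONE_LEVELS))
    m
  })
  names(out) <- all_cells
  structure(out, by = by, class = "error_table")
}

#' @export
print.error_table <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("-- %s (target x produced) --\n", g))
    print(unclass(x[[g]]))
  }
  invisible(x)
}

#' Tone-only error counts in canonical order
#' @param tab an [tabulate_errors()] result.
#' @return data frame `cell`, `error_type`, `count` (12 rows per cell).
#' @export
error_type_counts <- function(tab) {
  stopifnot(inherits(tab, "error_table"))
  types <- error_type_levels()
  do.call(rbind, lapply(names(tab), function(g) {
    m <- tab[[g]]
    parts <- strsplit(types, "-to-")
    cnt <- vapply(parts, function(p) m[p[1], p[2]], numeric(1))
    data.frame(cell = g, error_type = types, count = as.integer(cnt),
               stringsAsFactors = FALSE)
  }))
}

#' Per-group accuracy summaries (Table-5-style)
#'
#' Per speaker and day: percent correctly named among attempted
#' (non-excluded) items, and the tone-only share -- percent of the
#' speaker's total errors that are tone-only. Speakers with zero errors
#' have an undefined tone-only share; they are excluded from that mean
#' (and counted in `n_zero_error`). Group rows report the mean and
#' standard deviation across speakers.
#'
#' @param outcomes a [score_production()] result.
#' @return list with `speakers` (per speaker-day rows) and `groups`
#'   (per group-day rows: `mean_pct_correct`, `sd_pct_correct`,
#'   `mean_pct_tone_only`, `sd_pct_tone_only`, `n_speakers`,
#'   `n_zero_error`).
#' @export
summarize_accuracy <- function(outcomes) {
  stopifnot(inherits(outcomes, "naming_outcome"))
  keyed <- split(outcomes,
                 list(outcomes$group, outcomes$day, outcomes$speaker),
                 drop = TRUE)
  sp <- do.call(rbind, lapply(keyed, function(s) {
    attempted <- sum(s$category != "excluded")
    correct <- sum(s$category == "correct")
    errors <- attempted - correct
    tone_only <- sum(s$category == "tone_only_error")
    data.frame(speaker = s$speaker[1], group = s$group[1], day = s$day[1],
               attempted = attempted, correct = correct, errors = errors,
               pct_correct = if (attempted) 100 * correct / attempted
               else NA_real_,
               pct_tone_only = if (errors > 0) 100 * tone_only / errors
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  gkey <- paste(sp$group, sp$day, sep = "|")
  groups <- do.call(rbind, lapply(unique(gkey), function(g) {
    s <- sp[gkey == g, , drop = FALSE]
    data.frame(group = s$group[1], day = s$day[1],
               n_speakers = nrow(s),
               mean_pct_correct = mean(s$pct_correct, na.rm = TRUE),
               sd_pct_correct = sd(s$pct_correct, na.rm = TRUE),
               mean_pct_tone_only = mean(s$pct_tone_only, na.rm = TRUE),
               sd_pct_tone_only = sd(s$pct_tone_only, na.rm = TRUE),
               n_zero_error = sum(is.na(s$pct_tone_only)),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(speakers = sp, groups = groups)
}

#' Read a production-label ledger TSV
#'
#' Expected columns: `speaker group day item target_segments target_tone
#' produced_segments produced_tone quality_flag` (the flag column is
#' optional).
#'
#' @param path TSV path.
#' @return data frame ready for [score_production()].
#' @export
read_naming_ledger <- function(path) {
  if (!file.exists(path))
    stopf("file not found: %s", path, class = "tonetrace_io_error")
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  df$day <- as.integer(df$day)
  if ("quality_flag" %in% names(df))
    df$quality_flag <- isTRUE_vec(df$quality_flag)
  df
}
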