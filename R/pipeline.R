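# Config-driven orchestration: ingest -> repair/truncate -> normalize ->
# DCT -> distance -> cluster -> score -> summarize, with percentile
# bootstrap uncertainty on condition means and a JSON run manifest.

#' Run configuration
#'
#' Either `paths` (a list with `trajectories` and/or `naming` TSV paths
#' plus `targets`) or `simulate` (a [cohort_config()]) must be supplied --
#' exactly one of the two.
#'
#' @param paths list of input file paths (`trajectories`, `naming`,
#'   `targets`).
#' @param simulate a [cohort_config()] to generate inputs instead.
#' @param dialect [normtime_dialect()] for tabular input.
#' @param jump_ratio octave-jump repair threshold ([repair_contour()]).
#' @param n_drop edge samples truncated per side ([truncate_edges()]).
#' @param strict_range error (rather than clamp) on out-of-range samples.
#' @param cluster_scope [cluster_level_contours()] scope.
#' @param linkage clustering linkage method.
#' @param bootstrap_reps bootstrap replicates for condition-mean CIs
#'   (set 0 to skip CIs).
#' @param seed master seed; per-stage substreams are derived from it.
#' @param out_dir optional output directory; when given, tables and a run
#'   manifest are written there.
#' @return list, class `run_config`.
#' @export
run_config <- function(paths = NULL, simulate = NULL,
                       dialect = normtime_dialect(), jump_ratio = 1.8,
                       n_drop = 2L, strict_range = FALSE,
                       cluster_scope = "speaker_day", linkage = "ward.D2",
                       bootstrap_reps = 1000L, seed = 1L, out_dir = NULL) {
  if (is.null(paths) == is.null(simulate))
    stopf("exactly one of `paths` or `simulate` must be supplied",
          class = "tonetrace_validation_error")
  if (bootstrap_reps < 0)
    stopf("bootstrap_reps must be >= 0",
          class = "tonetrace_validation_error")
  structure(list(paths = paths, simulate = simulate, dialect = dialect,
                 jump_ratio = jump_ratio, n_drop = n_drop,
                 strict_range = strict_range,
                 cluster_scope = cluster_scope, linkage = linkage,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with `run_config` fields; a `simulate` block is
#'   passed to [cohort_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$simulate)) {
    sim_args <- obj$simulate
    if (isTRUE(sim_args) || identical(sim_args, "default")) sim_args <- list()
    obj$simulate <- do.call(cohort_config, sim_args)
  }
  if (!is.null(obj$dialect)) obj$dialect <- do.call(normtime_dialect,
                                                    obj$dialect)
  keep <- intersect(names(obj), names(formals(run_config)))
  do.call(run_config, obj[keep])
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- unclass(config)
  stripped$out_dir <- NULL
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

resolve_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    default_cohort(config$simulate,
                   seed = substream_seed(config$seed, "simulate"))
  } else {
    p <- config$paths
    targets <- if (!is.null(p$targets))
      read_normtime_table(p$targets, config$dialect)
    imitations <- if (!is.null(p$trajectories))
      read_normtime_table(p$trajectories, config$dialect)
    naming <- if (!is.null(p$naming)) read_naming_ledger(p$naming)
    list(targets = targets, imitations = imitations, naming = naming,
         speakers = NULL, config = NULL)
  }
}

#' Run the imitation (phonetic accuracy) analysis
#'
#' Full pipeline: repair and truncate trajectories, normalize to T-values
#' with observed speaker ranges (targets with the target speaker's own
#' range), compute DCT features, build target centroids, score tonal
#' distances, and summarize mean distance per L1 group x tone x day with
#' percentile-bootstrap confidence intervals. When `config$out_dir` is
#' set, writes `features.tsv`, `summary.tsv`, `exclusions.tsv`,
#' `centroids.json` and `manifest.json`.
#'
#' @param config a [run_config()].
#' @return list with `features` (per-production features + `distance`),
#'   `centroids`, `summary` (condition rows with `mean`, `lo`, `hi`, `n`),
#'   `ledger`, `manifest`.
#' @export
run_imitation_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- resolve_inputs(config)
  if (is.null(inputs$targets))
    stopf("imitation analysis requires a target stimulus set",
          class = "tonetrace_incomplete_reference")
  log_stage <- make_logger()

  targets <- inputs$targets
  imitations <- inputs$imitations
  if (is.null(imitations))
    stopf("imitation analysis requires production trajectories",
          class = "tonetrace_validation_error")
  log_stage("ingest", nrow(imitations), nrow(targets))

  imitations <- repair_contour(imitations, config$jump_ratio)
  ledger <- attr(imitations, "ledger")
  log_stage("repair", nrow(imitations),
            nrow(attr(imitations, "repairs")))
  # ranges from the full repaired contours: edge samples carry the contour
  # extremes, so the range must be fixed before truncation discards them
  ranges <- speaker_range(imitations)
  imitations <- truncate_edges(imitations, config$n_drop)
  targets_t <- truncate_edges(targets, config$n_drop)
  log_stage("truncate", nrow(imitations), n_f0_samples(imitations))
  trange <- attr(targets, "range")
  target_ranges <- if (!is.null(trange))
    speaker_range_table("target", trange[["xmin"]], trange[["xmax"]])
  else speaker_range(targets_t)
  dstats <- duration_stats(targets)
  t_targets <- t_normalize(targets_t, target_ranges,
                           strict = config$strict_range)
  t_imit <- t_normalize(imitations, ranges, strict = config$strict_range)
  target_features <- dct_features(t_targets, dstats)
  centroids <- tone_centroids(target_features)
  features <- tonal_distance(dct_features(t_imit, dstats), centroids)
  log_stage("features", nrow(features), nrow(centroids))

  summary <- condition_summary(features, config$bootstrap_reps,
                               substream_seed(config$seed, "bootstrap"))
  manifest <- list(analysis = "imitation", seed = config$seed,
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("tonetrace")),
                   n_productions = nrow(features),
                   ledger = if (!is.null(ledger)) ledger_counts(ledger))
  res <- list(features = features, centroids = centroids,
              summary = summary, ledger = ledger, manifest = manifest,
              target_features = target_features, dur_stats = dstats)
  if (!is.null(config$out_dir)) write_imitation_outputs(res, config)
  res
}

make_logger <- function() {
  function(stage, ...) {
    message(sprintf("[tonetrace] %-10s %s", stage,
                    paste(c(...), collapse = " / ")))
  }
}

condition_summary <- function(features, reps, seed) {
  cells <- split(features,
                 list(features$group, features$tone, features$day),
                 drop = TRUE)
  rows <- lapply(cells, function(s) {
    ci <- if (reps >= 100 && nrow(s) >= 2)
      bootstrap_mean_ci(s$distance, reps = reps,
                        seed = substream_seed(seed, s$group[1]))
    else list(mean = mean(s$distance), lo = NA_real_, hi = NA_real_)
    data.frame(group = s$group[1], tone = s$tone[1], day = s$day[1],
               n = nrow(s), mean = ci$mean, lo = ci$lo, hi = ci$hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, match(out$tone, TONE_LEVELS), out$day), ]
}

write_imitation_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write.table(as.data.frame(res$features), out("features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$summary, out("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(res$ledger)) write_exclusions(res$ledger,
                                             out("exclusions.tsv"))
  write_centroids(res$centroids, out("centroids.json"), res$dur_stats)
  jsonlite::write_json(res$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$out_dir)
}

#' Run the picture-naming (phono-lexical accuracy) analysis
#'
#' Scores the label ledger, optionally reconciles level-tone labels via
#' contour clustering when T-value contours are supplied, and produces
#' per-speaker/per-group accuracy summaries plus per-group 4 x 4 error
#' tables. When `config$out_dir` is set, writes `outcomes.tsv`,
#' `error_table.csv`, `summary.csv` and `manifest.json`.
#'
#' @param config a [run_config()].
#' @param level_contours optional `t_set` of level-tone naming contours
#'   for [cluster_level_contours()] reconciliation.
#' @return list with `outcomes`, `error_table`, `summary`,
#'   `assignments` (or `NULL`), `ledger`, `manifest`.
#' @export
run_naming_analysis <- function(config, level_contours = NULL) {
  stopifnot(inherits(config, "run_config"))
  inputs <- resolve_inputs(config)
  if (is.null(inputs$naming))
    stopf("naming analysis requires a label ledger",
          class = "tonetrace_validation_error")
  naming <- inputs$naming
  assignments <- NULL
  if (!is.null(level_contours)) {
    assignments <- cluster_level_contours(level_contours,
                                          scope = config$cluster_scope,
                                          linkage = config$linkage)
    assignments <- reconcile_labels(assignments)
    keys <- trial_key(naming$speaker, naming$day, naming$item)
    idx <- match(assignments$key, paste0(keys, "|r1"))
    orphan <- assignments$key[is.na(idx)]
    if (length(orphan))
      stopf("contour key(s) missing from the ledger: %s",
            paste(utils::head(orphan, 5), collapse = ", "),
            class = "tonetrace_join_error")
    naming$produced_tone[idx] <- assignments$prior_label
  }
  outcomes <- score_production(naming)
  tab <- tabulate_errors(outcomes, by = "group")
  summary <- summarize_accuracy(outcomes)
  ledger <- attr(naming, "ledger")
  manifest <- list(analysis = "naming", seed = config$seed,
                   config_hash = config_hash(config),
                   n_productions = nrow(outcomes),
                   ledger = if (!is.null(ledger)) ledger_counts(ledger))
  res <- list(outcomes = outcomes, error_table = tab, summary = summary,
              assignments = assignments, ledger = ledger,
              manifest = manifest)
  if (!is.null(config$out_dir)) write_naming_outputs(res, config)
  res
}

write_naming_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write.table(as.data.frame(res$outcomes), out("outcomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(error_type_counts(res$error_table),
                   out("error_table.csv"), row.names = FALSE)
  utils::write.csv(res$summary$groups, out("summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$out_dir)
}

# ---------------------------------------------------------------------------
# Bootstrap

#' Percentile bootstrap CI for a mean
#'
#' Nonparametric percentile confidence interval for the mean of `values`,
#' deterministic given `seed`.
#'
#' @param values numeric vector, length >= 2.
#' @param reps bootstrap replicates, >= 100.
#' @param seed optional integer seed.
#' @param conf confidence level (default 0.95).
#' @return list `mean`, `lo`, `hi`.
#' @export
bootstrap_mean_ci <- function(values, reps = 1000L, seed = NULL,
                              conf = 0.95) {
  if (!length(values))
    stopf("empty input", class = "tonetrace_empty_input")
  if (length(values) < 2)
    stopf("need at least 2 values", class = "tonetrace_invalid_argument")
  if (reps < 100)
    stopf("reps must be >= 100", class = "tonetrace_invalid_argument")
  n <- length(values)
  with_seed(seed, {
    draws <- matrix(sample(values, n * reps, replace = TRUE), nrow = reps)
    means <- rowMeans(draws)
    qs <- quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE, type = 7)
    list(mean = mean(values), lo = qs[1], hi = qs[2])
  })
}

#' Percentile bootstrap CI for a difference of group means
#'
#' Resamples the two groups independently; used for null-calibration
#' checks of between-group contrasts in mean tonal distance.
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @param reps bootstrap replicates, >= 100.
#' @param seed optional integer seed.
#' @param conf confidence level.
#' @return list `diff` (mean(x) - mean(y)), `lo`, `hi`.
#' @export
bootstrap_diff_ci <- function(x, y, reps = 1000L, seed = NULL,
                              conf = 0.95) {
  if (!length(x) || !length(y))
    stopf("empty input", class = "tonetrace_empty_input")
  if (length(x) < 2 || length(y) < 2)
    stopf("need at least 2 values per group",
          class = "tonetrace_invalid_argument")
  if (reps < 100)
    stopf("reps must be >= 100", class = "tonetrace_invalid_argument")
  with_seed(seed, {
    mx <- rowMeans(matrix(sample(x, length(x) * reps, replace = TRUE),
                          nrow = reps))
    my <- rowMeans(matrix(sample(y, length(y) * reps, replace = TRUE),
                          nrow = reps))
    qs <- quantile(mx - my, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE, type = 7)
    list(diff = mean(x) - mean(y), lo = qs[1], hi = qs[2])
  })
}
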