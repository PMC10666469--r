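# Two-cluster disambiguation of level-tone productions (mid-level vs
# low-level) and reconciliation of rater labels with the data-driven
# categorization.

# Midpoint between the canonical T-value heights of the low (Chao 11 -> 0)
# and mid (Chao 22 -> 1.25) level tones under the Chao-to-T mapping
# (d -> (d - 1) * 5/4); fallback threshold for degenerate (zero-variance)
# clustering input.
LEVEL_THRESHOLD <- 0.625

#' Cluster level-tone contours into mid vs low categories
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances between
#' equal-length T-value contours by default) cut at `k` clusters. For
#' `k = 2` the cluster with the higher grand-mean T-value is labeled
#' `"mid"` and the other `"low"`; ties on the mean are broken by lower
#' within-cluster variance, then by first occurrence. Clustering is run
#' separately per participant per day (`scope = "speaker_day"`) or on the
#' pooled set.
#'
#' The `tone` column of `x` is taken as the prior (rater) level label and
#' must be `"mid"` or `"low"` throughout.
#'
#' @param x a `t_set` of level-tone productions.
#' @param k number of clusters (2 for the mid/low split).
#' @param scope `"speaker_day"` or `"pooled"`.
#' @param linkage an [stats::hclust()] method; default `"ward.D2"`.
#' @return data frame with columns `key`, `speaker`, `day`, `item`,
#'   `cluster_index` (0/1), `assigned_level`, `prior_label`,
#'   `corresponds`; class `cluster_assignment`.
#' @export
cluster_level_contours <- function(x, k = 2L,
                                   scope = c("speaker_day", "pooled"),
                                   linkage = "ward.D2") {
  stopifnot(inherits(x, "t_set"))
  scope <- match.arg(scope)
  assert_tones(x$tone, allow = c("mid", "low"), what = "level-tone label")
  tv <- t_values(x)
  keys <- trial_key(x$speaker, x$day, x$item,
                    stats::ave(seq_len(nrow(x)),
                               paste(x$speaker, x$day, x$item, sep = "|"),
                               FUN = seq_along))
  grp <- if (scope == "speaker_day") paste(x$speaker, x$day, sep = "|")
  else rep("pooled", nrow(x))
  out <- vector("list", length(unique(grp)))
  names(out) <- unique(grp)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < k)
      stopf("scope group %s has %d contour(s), fewer than k = %d", g,
            length(idx), k, class = "tonetrace_insufficient_data")
    sub <- tv[idx, , drop = FALSE]
    if (nrow(unique(sub)) == 1L) {
      warnf("all contours identical in scope group %s; degenerate clustering",
            g, class = "tonetrace_degenerate_clustering")
      lev <- if (mean(sub) >= LEVEL_THRESHOLD) "mid" else "low"
      cl <- rep(1L, length(idx))
      assigned <- rep(lev, length(idx))
    } else {
      cl <- cutree(hclust(dist(sub, method = "euclidean"), method = linkage),
                   k = k)
      assigned <- label_clusters(sub, cl)
    }
    out[[g]] <- data.frame(key = keys[idx], speaker = x$speaker[idx],
                           day = x$day[idx], item = x$item[idx],
                           cluster_index = cl - 1L,
                           assigned_level = assigned,
                           prior_label = x$tone[idx],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$corresponds <- res$assigned_level == res$prior_label
  structure(res, class = c("cluster_assignment", "data.frame"))
}

# Deterministic mid/low labels from cluster mean heights (k = 2); for
# k > 2 the clusters above/below the grand mean split mid/low.
label_clusters <- function(tv, cl) {
  ids <- sort(unique(cl))
  means <- vapply(ids, function(i) mean(tv[cl == i, , drop = FALSE]),
                  numeric(1))
  vars <- vapply(ids, function(i) {
    v <- tv[cl == i, , drop = FALSE]
    mean((v - mean(v))^2)
  }, numeric(1))
  first <- vapply(ids, function(i) min(which(cl == i)), integer(1))
  # order: higher mean first; ties by lower variance, then first occurrence
  ord <- order(-means, vars, first)
  ranked <- ids[ord]
  n_mid <- max(1L, floor(length(ids) / 2))
  lev <- ifelse(cl %in% ranked[seq_len(n_mid)], "mid", "low")
  lev
}

#' Correspondence rate between prior labels and cluster categories
#'
#' Percentage of productions whose rater-assigned level label matches the
#' data-driven cluster category.
#'
#' @param assignments a [cluster_level_contours()] result.
#' @return percentage in `[0, 100]`.
#' @export
correspondence_rate <- function(assignments) {
  stopifnot(inherits(assignments, "cluster_assignment"))
  if (!nrow(assignments))
    stopf("empty assignment set", class = "tonetrace_empty_input")
  100 * mean(assignments$corresponds)
}

#' Reconcile prior labels with cluster categories
#'
#' Replaces the prior label of every non-corresponding production by its
#' cluster-assigned level and logs the change. Idempotent: a second pass
#' changes nothing.
#'
#' @param assignments a [cluster_level_contours()] result.
#' @return the assignments with `prior_label` updated and `corresponds`
#'   all `TRUE`; attribute `changes` is a data frame `key`, `old`, `new`.
#' @export
reconcile_labels <- function(assignments) {
  stopifnot(inherits(assignments, "cluster_assignment"))
  chg <- !assignments$corresponds
  changes <- data.frame(key = assignments$key[chg],
                        old = assignments$prior_label[chg],
                        new = assignments$assigned_level[chg],
                        stringsAsFactors = FALSE)
  assignments$prior_label[chg] <- assignments$assigned_level[chg]
  assignments$corresponds <- assignments$assigned_level ==
    assignments$prior_label
  attr(assignments, "changes") <- changes
  assignments
}
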