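#' Recall rate of a hit list
#'
#' Fraction of the test set's actives retrieved into the hit list. Hits
#' without a test-set label (background / unknown compounds) do not count
#' toward the numerator. A test set with zero actives leaves recall
#' undefined and returns `NA` (never 0).
#'
#' @param hits a [run_search()] hit list (or any data.frame with a
#'   `compound_id` column).
#' @param test_labels named character vector (`"active"`/`"inactive"`)
#'   over the test-set compound ids.
#' @return recall in \[0, 1\], or `NA` when undefined.
#' @export
recall_rate <- function(hits, test_labels) {
  test_actives <- names(test_labels)[test_labels == "active"]
  if (length(test_actives) == 0L) return(NA_real_)
  sum(hits$compound_id %in% test_actives) / length(test_actives)
}

#' Precision rate of a hit list
#'
#' Precision counted over explicitly labeled hits only: active hits
#' divided by (active hits + inactive hits). Hits with unknown bioactivity
#' — the bulk of any real screening database — are excluded from both
#' numerator and denominator, so the rate measures how well the search
#' separates tested actives from tested inactives rather than punishing
#' untested compounds. Undefined (`NA`) when the hit list contains no
#' labeled compound.
#'
#' @inheritParams recall_rate
#' @return precision in \[0, 1\], or `NA` when undefined.
#' @export
precision_rate <- function(hits, test_labels) {
  labels <- test_labels[hits$compound_id]
  n_act <- sum(labels == "active", na.rm = TRUE)
  n_inact <- sum(labels == "inactive", na.rm = TRUE)
  if (n_act + n_inact == 0L) return(NA_real_)
  n_act / (n_act + n_inact)
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen test-set active outscores a
#' randomly chosen test-set inactive, with ties counted one half — the
#' Mann-Whitney form of the area under the ROC curve, computed on the full
#' score vector (not the truncated hit list). Unknown-label compounds are
#' excluded. Compounds rejected by the classification engines carry a
#' score of `-Inf` in [run_search()]'s `all_scores`, so falsely rejected
#' actives lower the AUC. Undefined (`NA`) without at least one active and
#' one inactive.
#'
#' @param scores named numeric score vector over database compounds (e.g.
#'   `attr(hits, "all_scores")`).
#' @param test_labels named character vector (`"active"`/`"inactive"`).
#' @return AUC in \[0, 1\], or `NA` when undefined.
#' @export
roc_auc <- function(scores, test_labels) {
  ids <- intersect(names(scores), names(test_labels))
  labels <- test_labels[ids]
  s <- scores[ids]
  n_pos <- sum(labels == "active")
  n_neg <- sum(labels == "inactive")
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[labels == "active"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Top-k enrichment factor
#'
#' Active hit-rate in the hit list divided by the active prevalence in the
#' screened database: `(active_hits / |hits|) / (test_actives / db_size)`.
#' An uninformative (random) hit list has expected enrichment 1.
#'
#' @inheritParams recall_rate
#' @param db_size number of database compounds screened (test set plus
#'   background, after query/reference exclusion).
#' @return enrichment factor >= 0, or `NA` when prevalence is zero.
#' @export
enrichment_factor <- function(hits, test_labels, db_size) {
  test_actives <- names(test_labels)[test_labels == "active"]
  if (length(test_actives) == 0L || db_size <= 0 || nrow(hits) == 0L)
    return(NA_real_)
  (sum(hits$compound_id %in% test_actives) / nrow(hits)) /
    (length(test_actives) / db_size)
}

#' All per-query metrics for one search
#'
#' @inheritParams recall_rate
#' @param db_size screened database size, for the enrichment factor.
#' @return one-row data.frame: `rr`, `pr`, `auc`, `ef`, `n_active_hits`,
#'   `n_inactive_hits`.
#' @export
query_metrics <- function(hits, test_labels, db_size) {
  labels <- test_labels[hits$compound_id]
  data.frame(
    rr = recall_rate(hits, test_labels),
    pr = precision_rate(hits, test_labels),
    auc = roc_auc(attr(hits, "all_scores"), test_labels),
    ef = enrichment_factor(hits, test_labels, db_size),
    n_active_hits = sum(labels == "active", na.rm = TRUE),
    n_inactive_hits = sum(labels == "inactive", na.rm = TRUE))
}

#' Aggregate per-query metrics into per-class summaries
#'
#' Arithmetic means over all queries of each class and engine: ARR (mean
#' recall), APR (mean precision), mean AUC, AEF (mean enrichment).
#' Undefined per-query values are excluded from the means; the number of
#' queries dropped that way is reported per metric, never silently folded
#' in as zero.
#'
#' @param metrics data.frame with columns `class_id`, `engine`, `query_id`,
#'   `rr`, `pr`, `auc`, `ef` (one row per query), as produced by
#'   [run_benchmark()].
#' @return data.frame with one row per (class, engine): `arr`, `apr`,
#'   `mean_auc`, `aef`, `n_queries`, `n_undefined_rr`, `n_undefined_pr`,
#'   `n_undefined_auc`.
#' @export
class_metrics <- function(metrics) {
  split_by <- interaction(metrics$class_id, metrics$engine, drop = TRUE)
  rows <- lapply(split(metrics, split_by), function(m) {
    data.frame(class_id = m$class_id[1], engine = m$engine[1],
               arr = mean(m$rr, na.rm = TRUE),
               apr = mean(m$pr, na.rm = TRUE),
               mean_auc = mean(m$auc, na.rm = TRUE),
               aef = mean(m$ef, na.rm = TRUE),
               n_queries = nrow(m),
               n_undefined_rr = sum(is.na(m$rr)),
               n_undefined_pr = sum(is.na(m$pr)),
               n_undefined_auc = sum(is.na(m$auc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$engine, out$class_id), , drop = FALSE]
}

#' Paired comparison of two engines
#'
#' For every activity class, the difference in class-level ARR, APR and
#' mean AUC between engines A and B, plus a two-sided Mann-Whitney U test
#' comparing the per-query recall rates of the two engines within the
#' class. Returns the per-class table with summary counts (classes where
#' A beats B, classes significant at `alpha`) as attributes.
#'
#' @param metrics per-query metrics data.frame (same classes, splits and
#'   queries for both engines).
#' @param engine_a,engine_b engine names to compare (A minus B).
#' @param alpha significance level for the U test (default 0.05).
#' @return data.frame `class_id, engine_a, engine_b, d_arr, d_apr, d_auc,
#'   u_pvalue`, with attributes `n_arr_improved`, `n_auc_improved`,
#'   `n_significant`.
#' @export
compare_engines <- function(metrics, engine_a, engine_b, alpha = 0.05) {
  ma <- metrics[metrics$engine == engine_a, , drop = FALSE]
  mb <- metrics[metrics$engine == engine_b, , drop = FALSE]
  classes_a <- sort(unique(ma$class_id))
  classes_b <- sort(unique(mb$class_id))
  if (!identical(classes_a, classes_b))
    stop("engines were not run on the same classes")
  rows <- lapply(classes_a, function(cid) {
    qa <- ma[ma$class_id == cid, , drop = FALSE]
    qb <- mb[mb$class_id == cid, , drop = FALSE]
    pv <- tryCatch(
      suppressWarnings(stats::wilcox.test(qa$rr, qb$rr,
                                          exact = FALSE)$p.value),
      error = function(e) NA_real_)
    data.frame(class_id = cid, engine_a = engine_a, engine_b = engine_b,
               d_arr = mean(qa$rr, na.rm = TRUE) - mean(qb$rr, na.rm = TRUE),
               d_apr = mean(qa$pr, na.rm = TRUE) - mean(qb$pr, na.rm = TRUE),
               d_auc = mean(qa$auc, na.rm = TRUE) - mean(qb$auc, na.rm = TRUE),
               u_pvalue = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            n_arr_improved = sum(out$d_arr > 0, na.rm = TRUE),
            n_auc_improved = sum(out$d_auc > 0, na.rm = TRUE),
            n_significant = sum(out$u_pvalue < alpha, na.rm = TRUE))
}
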