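#' The six search engines
#'
#' @return character vector of engine names: `css` (conventional Tanimoto
#'   similarity search), `pbss` (single average-profile search), `iss`
#'   (iterative MAX-fusion search over active references), `pbiss`
#'   (profile-based ISS), `isc` (ISS with neighbor classification against
#'   inactive references), `pbisc` (profile-based ISC).
#' @export
search_engines <- function() c("css", "pbss", "iss", "pbiss", "isc", "pbisc")

#' Build the neighbor list of a query
#'
#' Retrieves every reference compound with binary Tanimoto similarity
#' strictly greater than `cutoff` to the query, separated into active and
#' inactive references. The neighbor list is the shared starting point of
#' all five target-enhanced engines; it may be empty, in which case each
#' engine degenerates to conventional similarity search.
#'
#' @param query binary fingerprint vector.
#' @param ref_fps fingerprint matrix of the reference set (rownames = ids).
#' @param ref_labels named character vector (`"active"`/`"inactive"`) over
#'   the reference ids.
#' @param cutoff similarity threshold, strict inequality (default 0.3).
#' @return object of class `neighbor_list`: list with `query`, `active`
#'   and `inactive` fingerprint matrices (possibly 0-row), and `cutoff`.
#' @export
build_neighbor_list <- function(query, ref_fps, ref_labels, cutoff = 0.3) {
  query <- as.numeric(query)
  if (nrow(ref_fps) > 0 && ncol(ref_fps) != length(query))
    stop("query and reference fingerprints differ in length")
  if (nrow(ref_fps) == 0) {
    keep <- character(0)
  } else {
    sims <- .tanimoto_rows(query, ref_fps)
    keep <- rownames(ref_fps)[sims > cutoff]
  }
  labels <- ref_labels[keep]
  pick <- function(ids) {
    if (length(ids) == 0)
      matrix(numeric(0), nrow = 0, ncol = length(query))
    else ref_fps[ids, , drop = FALSE]
  }
  structure(list(
    query = query,
    active = pick(keep[labels == "active"]),
    inactive = pick(keep[labels == "inactive"]),
    cutoff = cutoff), class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat(sprintf("Neighbor list (Tc > %.2f): %d active, %d inactive references\n",
              x$cutoff, nrow(x$active), nrow(x$inactive)))
  invisible(x)
}

#' Cluster and profile the references of a neighbor list
#'
#' Compresses the reference units used by the profile-based iterative
#' engines. In `pbiss` mode the active references (with the query
#' fingerprint always included among them) are Taylor-Butina clustered at
#' `cluster_cutoff` and each cluster is replaced by one average profile.
#' In `pbisc` mode all references are clustered together: a pure cluster
#' yields a single profile carrying its label, a mixed cluster is split by
#' label into two profiles. In `fingerprints` mode the units are the
#' references themselves (used by `iss`/`isc`). The compression ratio —
#' reference fingerprints per resulting unit — is recorded; it is the
#' quantity the profile approach trades against the plain iterative search.
#'
#' @param nl a [build_neighbor_list()] result.
#' @param mode `"pbiss"`, `"pbisc"`, or `"fingerprints"`.
#' @param cluster_cutoff Taylor-Butina similarity cutoff (default 0.4).
#' @param include_query include the query fingerprint among the active
#'   units (default `TRUE`).
#' @return object of class `reference_model`: list with `mode`,
#'   `active_units` / `inactive_units` (matrices, one unit per row),
#'   `unit_sizes` (members per active unit), `n_refs`, `compression_ratio`.
#' @export
build_profile_units <- function(nl, mode = c("pbiss", "pbisc", "fingerprints"),
                                cluster_cutoff = 0.4, include_query = TRUE) {
  mode <- match.arg(mode)
  M <- length(nl$query)
  qmat <- matrix(nl$query, nrow = 1, dimnames = list(".query", NULL))
  act <- if (include_query) rbind(qmat, nl$active) else nl$active
  inact <- nl$inactive

  empty <- function() matrix(numeric(0), nrow = 0, ncol = M)
  if (mode == "fingerprints") {
    n_refs <- nrow(act) + nrow(inact)
    return(structure(list(mode = mode, active_units = act,
                          inactive_units = inact,
                          unit_sizes = rep(1L, nrow(act)), n_refs = n_refs,
                          compression_ratio = 1),
                     class = "reference_model"))
  }

  profile_rows <- function(fps, clustering) {
    rows <- lapply(clustering$clusters, function(cl)
      colMeans(fps[cl$members, , drop = FALSE]))
    do.call(rbind, rows)
  }

  if (mode == "pbiss") {
    if (nrow(act) == 0)
      return(structure(list(mode = mode, active_units = empty(),
                            inactive_units = empty(), unit_sizes = integer(0),
                            n_refs = 0, compression_ratio = 1),
                       class = "reference_model"))
    clust <- taylor_butina(act, cluster_cutoff)
    units <- profile_rows(act, clust)
    structure(list(mode = mode, active_units = units,
                   inactive_units = empty(),
                   unit_sizes = cluster_sizes(clust), n_refs = nrow(act),
                   compression_ratio = nrow(act) / nrow(units)),
              class = "reference_model")
  } else {
    all_fps <- rbind(act, inact)
    if (nrow(all_fps) == 0)
      return(structure(list(mode = mode, active_units = empty(),
                            inactive_units = empty(), unit_sizes = integer(0),
                            n_refs = 0, compression_ratio = 1),
                       class = "reference_model"))
    labels <- rep(c("active", "inactive"), c(nrow(act), nrow(inact)))
    names(labels) <- rownames(all_fps)
    clust <- taylor_butina(all_fps, cluster_cutoff)
    act_units <- list(); act_sizes <- integer(0); inact_units <- list()
    for (cl in clust$clusters) {
      mem_labels <- labels[cl$members]
      for (lab in unique(mem_labels)) {
        mem <- cl$members[mem_labels == lab]
        prof <- colMeans(all_fps[mem, , drop = FALSE])
        if (lab == "active") {
          act_units[[length(act_units) + 1L]] <- prof
          act_sizes <- c(act_sizes, length(mem))
        } else {
          inact_units[[length(inact_units) + 1L]] <- prof
        }
      }
    }
    to_mat <- function(l) if (length(l)) do.call(rbind, l) else empty()
    n_units <- length(act_units) + length(inact_units)
    structure(list(mode = mode, active_units = to_mat(act_units),
                   inactive_units = to_mat(inact_units),
                   unit_sizes = act_sizes, n_refs = nrow(all_fps),
                   compression_ratio = nrow(all_fps) / n_units),
              class = "reference_model")
  }
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(paste0("Reference model (%s): %d active / %d inactive units ",
                     "from %d references (compression %.2f)\n"),
              x$mode, nrow(x$active_units), nrow(x$inactive_units),
              x$n_refs, x$compression_ratio))
  invisible(x)
}

# Engine scorers. Each returns list(scores = named numeric over db rows,
# kept = logical). `kept` is FALSE where the neighbor-classification rule
# rejects a database compound (ISC/PBISC only).
.score_engine <- function(engine, query, db, ref_fps, ref_labels,
                          neighbor_cutoff = 0.3, cluster_cutoff = 0.4,
                          reject_ties = TRUE, db_sq = rowSums(db * db)) {
  query <- as.numeric(query)
  n <- nrow(db)
  if (engine == "css") {
    scores <- .tanimoto_rows(query, db, db_sq)
    return(list(scores = scores, kept = rep(TRUE, n)))
  }
  nl <- build_neighbor_list(query, ref_fps, ref_labels, neighbor_cutoff)
  qmat <- matrix(query, nrow = 1)
  active_fps <- rbind(qmat, nl$active)  # query always among the active units
  switch(engine,
    pbss = {
      prof <- colMeans(active_fps)
      list(scores = .tanimoto_rows(prof, db, db_sq), kept = rep(TRUE, n))
    },
    iss = {
      list(scores = .max_fusion_rows(active_fps, db, db_sq),
           kept = rep(TRUE, n))
    },
    isc = {
      scores <- .max_fusion_rows(active_fps, db, db_sq)
      if (nrow(nl$inactive) == 0) {
        kept <- rep(TRUE, n)
      } else {
        inact_max <- .max_fusion_rows(nl$inactive, db, db_sq)
        kept <- if (reject_ties) scores > inact_max else scores >= inact_max
      }
      list(scores = scores, kept = kept)
    },
    pbiss = {
      rm_units <- build_profile_units(nl, "pbiss", cluster_cutoff)
      list(scores = .max_fusion_rows(rm_units$active_units, db, db_sq),
           kept = rep(TRUE, n))
    },
    pbisc = {
      rm_units <- build_profile_units(nl, "pbisc", cluster_cutoff)
      scores <- .max_fusion_rows(rm_units$active_units, db, db_sq)
      if (nrow(rm_units$inactive_units) == 0) {
        kept <- rep(TRUE, n)
      } else {
        inact_max <- .max_fusion_rows(rm_units$inactive_units, db, db_sq)
        kept <- if (reject_ties) scores > inact_max else scores >= inact_max
      }
      list(scores = scores, kept = kept)
    },
    stop("unknown engine: ", engine))
}

#' Default hit-list size
#'
#' Top 1% of the screened database, `floor(top_frac * db_size)` — for the
#' canonical 494,199-compound screening database this gives 4941 hits.
#'
#' @param db_size number of database compounds screened.
#' @param top_frac fraction retained (default 0.01).
#' @return integer truncation size k.
#' @export
hit_list_size <- function(db_size, top_frac = 0.01) {
  as.integer(floor(top_frac * db_size))
}

#' Run one similarity search
#'
#' Scores every database compound with the chosen engine, applies the
#' neighbor-classification rejection where the engine has one (`isc`,
#' `pbisc`; rejection happens before ranking), ranks the survivors by
#' descending score with ties broken by ascending compound id, and
#' truncates to the top k. Query and reference compounds are removed from
#' the database before scoring, so hits can only come from test-set and
#' background compounds.
#'
#' @param engine one of [search_engines()].
#' @param query binary fingerprint vector of the query compound.
#' @param db fingerprint matrix of the database (rownames = ids).
#' @param ref_fps,ref_labels the reference set: fingerprint matrix and
#'   named `"active"`/`"inactive"` labels.
#' @param k hit-list truncation size; default `hit_list_size(nrow(db),
#'   top_frac)` after query/reference exclusion. Must be positive.
#' @param top_frac fraction of the database retained when `k` is not given
#'   (default 0.01).
#' @param neighbor_cutoff neighbor-list similarity threshold (default 0.3,
#'   strict inequality).
#' @param cluster_cutoff Taylor-Butina cutoff for the profile-based
#'   engines (default 0.4).
#' @param reject_ties when the maximal active and inactive similarities
#'   tie, reject the compound (default `TRUE`, the literal classification
#'   rule).
#' @param query_id id recorded on the hit list (also excluded from the
#'   database when present among its rownames).
#' @return object of class `hit_list`: data.frame with columns `rank`,
#'   `compound_id`, `score`, and attributes `engine`, `query_id`, `k`,
#'   `n_rejected`, `rejected_ids`, and `all_scores` (the full score vector
#'   over the screened database, with rejected compounds at `-Inf`, for
#'   ROC analysis).
#' @export
run_search <- function(engine, query, db, ref_fps, ref_labels, k = NULL,
                       top_frac = 0.01, neighbor_cutoff = 0.3,
                       cluster_cutoff = 0.4, reject_ties = TRUE,
                       query_id = "query") {
  engine <- match.arg(engine, search_engines())
  db <- as_fingerprint_matrix(db)
  exclude <- c(query_id, rownames(ref_fps))
  db <- db[!(rownames(db) %in% exclude), , drop = FALSE]
  if (nrow(db) == 0) stop("database is empty after query/reference exclusion")
  if (is.null(k)) k <- hit_list_size(nrow(db), top_frac)
  if (k <= 0) stop("hit-list size k must be positive (got ", k, ")")

  sc <- .score_engine(engine, query, db, ref_fps, ref_labels,
                      neighbor_cutoff, cluster_cutoff, reject_ties)
  all_scores <- sc$scores
  all_scores[!sc$kept] <- -Inf
  ids <- rownames(db)
  keep_ids <- ids[sc$kept]
  keep_scores <- sc$scores[sc$kept]
  ord <- order(-keep_scores, keep_ids)
  top <- utils::head(ord, k)
  hits <- data.frame(rank = seq_along(top), compound_id = keep_ids[top],
                     score = as.numeric(keep_scores[top]),
                     stringsAsFactors = FALSE)
  structure(hits, engine = engine, query_id = query_id, k = as.integer(k),
            n_rejected = sum(!sc$kept), rejected_ids = ids[!sc$kept],
            all_scores = all_scores, class = c("hit_list", "data.frame"))
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("Hit list: engine %s, query %s, %d/%d hits (k = %d, %d rejected)\n",
              attr(x, "engine"), attr(x, "query_id"), nrow(x),
              length(attr(x, "all_scores")), attr(x, "k"),
              attr(x, "n_rejected")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write a hit list to CSV
#'
#' Columns `rank,compound_id,score,engine,query_id`.
#'
#' @param hits a `hit_list`.
#' @param path output CSV.
#' @export
write_hit_list <- function(hits, path) {
  df <- data.frame(rank = hits$rank, compound_id = hits$compound_id,
                   score = hits$score, engine = attr(hits, "engine"),
                   query_id = attr(hits, "query_id"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
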