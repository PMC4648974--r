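#' Taylor-Butina exclusion-sphere clustering
#'
#' Classic sphere-exclusion clustering of binary fingerprints. Neighbor
#' lists are built once at Tanimoto similarity >= `cutoff` (inclusive);
#' candidates are visited in order of decreasing original neighbor count
#' (ties broken by input position, so the result is deterministic); each
#' visited unassigned compound becomes a cluster centroid and claims its
#' still-unassigned neighbors. Compounds whose neighbors were all claimed
#' earlier remain "false singletons", as in the original algorithm.
#'
#' @param fps matrix of binary fingerprints, one compound per row; rownames
#'   are compound ids (row indices are used when absent).
#' @param cutoff similarity threshold in (0, 1).
#' @return an object of class `tb_clustering`: a list with `clusters` (each
#'   a list with `centroid` id and `members` ids, centroid included),
#'   `cutoff`, and `ids` (the input ids, in input order).
#' @export
#' @examples
#' fps <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
#' taylor_butina(fps, cutoff = 0.5)
taylor_butina <- function(fps, cutoff) {
  if (is.null(dim(fps))) fps <- matrix(fps, nrow = 1)
  n <- nrow(fps)
  if (n == 0L) stop("cannot cluster an empty fingerprint set")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie in (0, 1)")
  ids <- rownames(fps)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  sims <- .tanimoto_matrix(fps)
  nbr <- sims >= cutoff
  diag(nbr) <- FALSE
  counts <- rowSums(nbr)

  order_idx <- order(-counts, seq_len(n))
  assigned <- rep(FALSE, n)
  clusters <- list()
  for (i in order_idx) {
    if (assigned[i]) next
    members <- c(i, which(nbr[i, ] & !assigned))
    members <- unique(members)
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <-
      list(centroid = ids[i], members = ids[members])
  }
  structure(list(clusters = clusters, cutoff = cutoff, ids = ids),
            class = "tb_clustering")
}

#' @export
print.tb_clustering <- function(x, ...) {
  sizes <- cluster_sizes(x)
  cat(sprintf("Taylor-Butina clustering: %d compounds, %d clusters (cutoff %.2f)\n",
              length(x$ids), length(sizes), x$cutoff))
  cat("cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Cluster sizes and centroids of a clustering
#'
#' @param clustering a `tb_clustering` object.
#' @return `cluster_sizes`: integer vector of member counts;
#'   `cluster_centroids`: character vector of centroid ids.
#' @export
cluster_sizes <- function(clustering) {
  vapply(clustering$clusters, function(cl) length(cl$members), integer(1))
}

#' @rdname cluster_sizes
#' @export
cluster_centroids <- function(clustering) {
  vapply(clustering$clusters, function(cl) cl$centroid, character(1))
}

#' Structural diversity index of an activity class
#'
#' Shannon entropy (base 2) of the cluster-size distribution:
#' `H = -sum_i (n_i / n) * log2(n_i / n)` over the k clusters, where `n_i`
#' is the size of cluster i and `n` the total compound count. A single
#' cluster gives H = 0; k equal-size clusters give H = log2(k). Higher H
#' means more scaffold-diverse actives, hence a harder retrieval problem
#' for any single query.
#'
#' @param clustering a `tb_clustering` object.
#' @return H >= 0.
#' @export
diversity_index <- function(clustering) {
  sizes <- cluster_sizes(clustering)
  if (length(sizes) == 0L) stop("empty clustering")
  p <- sizes / sum(sizes)
  -sum(p * log2(p))
}

#' Serialize / deserialize a clustering
#'
#' Tab-separated plain text, one cluster per line:
#' `cluster_id<TAB>centroid_id<TAB>member_ids(comma-sep)`.
#'
#' @param clustering a `tb_clustering` object.
#' @param path output file.
#' @return `write_clustering` returns `path` invisibly; `read_clustering`
#'   returns a `tb_clustering` (with `cutoff` of `NA` unless stored in the
#'   optional `#cutoff=` header).
#' @export
write_clustering <- function(clustering, path) {
  lines <- c(sprintf("#cutoff=%.10g", clustering$cutoff),
             vapply(seq_along(clustering$clusters), function(i) {
               cl <- clustering$clusters[[i]]
               paste(i, cl$centroid, paste(cl$members, collapse = ","),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clustering
#' @export
read_clustering <- function(path) {
  lines <- readLines(path)
  cutoff <- NA_real_
  hdr <- grepl("^#cutoff=", lines)
  if (any(hdr)) cutoff <- as.numeric(sub("^#cutoff=", "", lines[hdr][1]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  clusters <- lapply(strsplit(lines, "\t", fixed = TRUE), function(p) {
    list(centroid = p[2], members = strsplit(p[3], ",", fixed = TRUE)[[1]])
  })
  ids <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
  structure(list(clusters = clusters, cutoff = cutoff, ids = ids),
            class = "tb_clustering")
}
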