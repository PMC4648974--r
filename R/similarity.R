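#' Binary Tanimoto coefficient
#'
#' Similarity between two binary fingerprints, `c / (a + b - c)` where `a`
#' and `b` are the popcounts of the two fingerprints and `c` the popcount of
#' their intersection. Two all-zero fingerprints return 0 by convention: a
#' featureless molecule should not match everything.
#'
#' @param a,b binary vectors (elements 0/1) of equal length.
#' @return similarity in \[0, 1\].
#' @seealso [tanimoto_continuous()] for the real-valued form used with
#'   profiles; both agree exactly on binary inputs.
#' @export
#' @examples
#' x <- c(1, 1, 1, 0); y <- c(0, 1, 1, 1)
#' tanimoto_binary(x, y)  # 2 / (3 + 3 - 2) = 0.5
tanimoto_binary <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("tanimoto_binary requires binary (0/1) fingerprints")
  ca <- sum(a); cb <- sum(b); cc <- sum(a * b)
  denom <- ca + cb - cc
  if (denom == 0) return(0)
  cc / denom
}

#' Continuous Tanimoto coefficient
#'
#' Real-valued Tanimoto similarity,
#' `sum(a*b) / sum(a^2 + b^2 - a*b)`, defined for any pair of vectors with
#' elements in \[0, 1\] — two fingerprints, two average profiles, or one of
#' each (fingerprint bits are treated as the reals 0/1). Restricted to
#' binary inputs it equals [tanimoto_binary()] exactly. Two all-zero inputs
#' return 0 by convention.
#'
#' @param a,b numeric vectors of equal length with elements in \[0, 1\];
#'   [make_profile()] output is accepted directly.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' tanimoto_continuous(c(1, 0, 1), c(1, 1, 0))  # 1 / (2 + 2 - 1) = 1/3
tanimoto_continuous <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("vector length mismatch: ", length(a), " vs ", length(b))
  num <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - num
  if (denom == 0) return(0)
  num / denom
}

#' Average (AVE) profile of a group of fingerprints
#'
#' The element-wise arithmetic mean of a set of binary fingerprints: a
#' real-valued vector of the same length where position i holds the fraction
#' of member fingerprints with bit i set. A profile built from a single
#' fingerprint is numerically identical to that fingerprint, so profile
#' searches degenerate gracefully to fingerprint searches.
#'
#' @param members matrix of fingerprints (one row each, equal length), or a
#'   list of binary vectors, or a single vector. Must be nonempty.
#' @param label `"active"` or `"inactive"` — which reference group the
#'   profile summarizes.
#' @return numeric vector of class `ave_profile` with attributes
#'   `n_members` (group size) and `label`.
#' @export
#' @examples
#' p <- make_profile(rbind(c(1, 1, 0), c(1, 0, 0)), "active")
#' as.numeric(p)  # 1.0 0.5 0.0
make_profile <- function(members, label = c("active", "inactive")) {
  label <- match.arg(label)
  if (is.list(members) && !is.data.frame(members)) {
    if (length(members) == 0L) stop("cannot build a profile from zero members")
    members <- do.call(rbind, lapply(members, as.numeric))
  }
  if (is.null(dim(members))) members <- matrix(as.numeric(members), nrow = 1)
  if (nrow(members) == 0L) stop("cannot build a profile from zero members")
  values <- colMeans(members)
  structure(values, n_members = nrow(members), label = label,
            class = "ave_profile")
}

#' @export
print.ave_profile <- function(x, ...) {
  cat(sprintf("AVE profile (%s): length %d, mean of %d fingerprint(s)\n",
              attr(x, "label"), length(x), attr(x, "n_members")))
  invisible(x)
}

#' Write / read average profiles
#'
#' Plain-text serialization (`id<TAB>comma-separated reals`) so that
#' pre-clustered, pre-profiled reference sets can be stored and reused
#' across searches.
#'
#' @param profiles named list of profiles (or numeric vectors).
#' @param path output file.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns a named list of numeric vectors.
#' @export
write_profiles <- function(profiles, path) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("profile_", seq_along(profiles))
  lines <- vapply(seq_along(profiles), function(i) {
    paste0(ids[i], "\t",
           paste(format(as.numeric(profiles[[i]]), digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) as.numeric(strsplit(p[2], ",")[[1]]))
  names(out) <- vapply(parts, `[[`, character(1), 1)
  out
}

# ---- vectorized internals shared by clustering and the search engines ----

# Continuous Tanimoto of one vector against every row of a matrix.
# db_sq = rowSums(db^2) may be precomputed once per database.
.tanimoto_rows <- function(x, db, db_sq = rowSums(db * db)) {
  num <- as.numeric(db %*% x)
  denom <- sum(x * x) + db_sq - num
  out <- ifelse(denom == 0, 0, num / denom)
  names(out) <- rownames(db)
  out
}

# MAX-fusion: for each row of db, the maximum continuous Tanimoto over the
# unit vectors (rows of `units`). Returns a numeric vector over db rows.
.max_fusion_rows <- function(units, db, db_sq = rowSums(db * db)) {
  if (is.null(dim(units))) units <- matrix(units, nrow = 1)
  num <- db %*% t(units)                      # n_db x n_units
  unit_sq <- rowSums(units * units)
  denom <- outer(db_sq, unit_sq, "+") - num
  sims <- ifelse(denom == 0, 0, num / denom)
  out <- do.call(pmax, c(as.data.frame(sims), list(na.rm = FALSE)))
  out <- as.numeric(out)
  names(out) <- rownames(db)
  out
}

# All-pairs continuous Tanimoto similarity matrix for rows of a matrix.
.tanimoto_matrix <- function(fps) {
  sq <- rowSums(fps * fps)
  num <- tcrossprod(fps)
  denom <- outer(sq, sq, "+") - num
  sims <- ifelse(denom == 0, 0, num / denom)
  dimnames(sims) <- list(rownames(fps), rownames(fps))
  sims
}
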