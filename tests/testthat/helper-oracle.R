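# Independent brute-force reimplementation of the six search engines,
# written with plain loops and no shared code paths with the package
# internals. Used as the oracle for ranked-output equivalence tests.

oracle_tc_binary <- function(a, b) {
  ca <- 0; cb <- 0; cc <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1) ca <- ca + 1
    if (b[i] == 1) cb <- cb + 1
    if (a[i] == 1 && b[i] == 1) cc <- cc + 1
  }
  if (ca + cb - cc == 0) return(0)
  cc / (ca + cb - cc)
}

oracle_tc_continuous <- function(a, b) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    den <- den + a[i]^2 + b[i]^2 - a[i] * b[i]
  }
  if (den == 0) return(0)
  num / den
}

oracle_mean_profile <- function(rows) {
  out <- numeric(ncol(rows))
  for (j in seq_len(ncol(rows))) out[j] <- mean(rows[, j])
  out
}

# Classic Taylor-Butina with neighbor counts computed once, ties broken by
# input position.
oracle_butina <- function(fps, cutoff) {
  n <- nrow(fps)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (i != j && oracle_tc_continuous(fps[i, ], fps[j, ]) >= cutoff)
        nb <- c(nb, j)
    }
    nbrs[[i]] <- nb
  }
  counts <- vapply(nbrs, length, integer(1))
  assigned <- rep(FALSE, n)
  clusters <- list()
  for (i in order(-counts, seq_len(n))) {
    if (assigned[i]) next
    members <- i
    for (j in nbrs[[i]]) if (!assigned[j]) members <- c(members, j)
    members <- unique(members)
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- members
  }
  clusters
}

# Full brute-force engine: returns the ranked hit list (ids and scores).
oracle_search <- function(engine, query, db, ref_fps, ref_labels, k,
                          neighbor_cutoff = 0.3, cluster_cutoff = 0.4) {
  n <- nrow(db)
  # neighbor list: strict > cutoff
  act_idx <- integer(0); inact_idx <- integer(0)
  for (r in seq_len(nrow(ref_fps))) {
    if (oracle_tc_binary(query, ref_fps[r, ]) > neighbor_cutoff) {
      if (ref_labels[rownames(ref_fps)[r]] == "active")
        act_idx <- c(act_idx, r)
      else inact_idx <- c(inact_idx, r)
    }
  }
  act_units <- rbind(matrix(query, nrow = 1),
                     ref_fps[act_idx, , drop = FALSE])
  inact_fps <- ref_fps[inact_idx, , drop = FALSE]

  max_sim <- function(units, x) {
    best <- -Inf
    for (u in seq_len(nrow(units)))
      best <- max(best, oracle_tc_continuous(units[u, ], x))
    best
  }

  scores <- numeric(n)
  kept <- rep(TRUE, n)
  if (engine == "css") {
    for (i in seq_len(n)) scores[i] <- oracle_tc_binary(query, db[i, ])
  } else if (engine == "pbss") {
    prof <- oracle_mean_profile(act_units)
    for (i in seq_len(n)) scores[i] <- oracle_tc_continuous(prof, db[i, ])
  } else if (engine == "iss") {
    for (i in seq_len(n)) scores[i] <- max_sim(act_units, db[i, ])
  } else if (engine == "isc") {
    for (i in seq_len(n)) {
      scores[i] <- max_sim(act_units, db[i, ])
      if (nrow(inact_fps) > 0)
        kept[i] <- scores[i] > max_sim(inact_fps, db[i, ])
    }
  } else if (engine %in% c("pbiss", "pbisc")) {
    if (engine == "pbiss") {
      cl <- oracle_butina(act_units, cluster_cutoff)
      act_profiles <- t(vapply(cl, function(m)
        oracle_mean_profile(act_units[m, , drop = FALSE]),
        numeric(ncol(db))))
      inact_profiles <- matrix(numeric(0), 0, ncol(db))
    } else {
      all_fps <- rbind(act_units, inact_fps)
      lab <- c(rep("active", nrow(act_units)),
               rep("inactive", nrow(inact_fps)))
      cl <- oracle_butina(all_fps, cluster_cutoff)
      act_profiles <- NULL; inact_profiles <- NULL
      for (m in cl) {
        for (l in unique(lab[m])) {
          prof <- oracle_mean_profile(all_fps[m[lab[m] == l], , drop = FALSE])
          if (l == "active") act_profiles <- rbind(act_profiles, prof)
          else inact_profiles <- rbind(inact_profiles, prof)
        }
      }
      if (is.null(act_profiles)) act_profiles <- matrix(numeric(0), 0, ncol(db))
      if (is.null(inact_profiles))
        inact_profiles <- matrix(numeric(0), 0, ncol(db))
    }
    boundary <- rep(FALSE, n)
    for (i in seq_len(n)) {
      scores[i] <- max_sim(act_profiles, db[i, ])
      if (engine == "pbisc" && nrow(inact_profiles) > 0) {
        im <- max_sim(inact_profiles, db[i, ])
        kept[i] <- scores[i] > im
        # profile maxima that tie mathematically sit exactly on the
        # keep/reject decision boundary; flag them for the caller
        boundary[i] <- abs(scores[i] - im) < 1e-9
      }
    }
  } else stop("unknown engine")

  ids <- rownames(db)
  keep_ids <- ids[kept]; keep_scores <- scores[kept]
  ord <- order(-keep_scores, keep_ids)
  top <- head(ord, k)
  out <- list(compound_id = keep_ids[top], score = keep_scores[top],
              boundary_ids = character(0))
  if (exists("boundary", inherits = FALSE)) out$boundary_ids <- ids[boundary]
  out
}

# Random binary fingerprint matrix with unique ids.
random_fps <- function(n, M, density = 0.3, prefix = "c") {
  m <- matrix(as.numeric(rbinom(n * M, 1, density)), nrow = n)
  rownames(m) <- sprintf("%s%04d", prefix, seq_len(n))
  m
}
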