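# Small labeled reference fixture shared across the engine tests.
make_ref_set <- function(n_act = 6, n_inact = 6, M = 48, seed = 101) {
  set.seed(seed)
  fps <- random_fps(n_act + n_inact, M, density = 0.35, prefix = "ref")
  labels <- stats::setNames(rep(c("active", "inactive"), c(n_act, n_inact)),
                            rownames(fps))
  list(fps = fps, labels = labels)
}

test_that("neighbor lists use a strict similarity threshold", {
  q <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  refs <- rbind(
    far = c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0),              # Tc = 0
    edge = c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1),             # Tc = 3/10 = 0.3
    near = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0),             # Tc = 3/5  = 0.6
    self = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))             # Tc = 1
  labels <- c(far = "active", edge = "active", near = "inactive",
              self = "active")
  nl <- build_neighbor_list(q, refs, labels, cutoff = 0.3)
  expect_setequal(rownames(nl$active), "self")
  expect_setequal(rownames(nl$inactive), "near")
  expect_equal(nrow(nl$active) + nrow(nl$inactive), 2)  # 0.3 itself excluded
  expect_false("edge" %in% c(rownames(nl$active), rownames(nl$inactive)))
})

test_that("an empty reference set gives an empty neighbor list, not an error", {
  empty <- matrix(numeric(0), nrow = 0, ncol = 8)
  nl <- build_neighbor_list(rep(1, 8), empty, character(0))
  expect_equal(nrow(nl$active), 0)
  expect_equal(nrow(nl$inactive), 0)
})

test_that("the PBSS profile score matches the worked example", {
  # query (1,1,0,0) + active ref (1,0,1,0): profile (1,.5,.5,0);
  # against db compound (1,0,0,0): 1 / (1.5 + 1 - 1) = 2/3
  q <- c(1, 1, 0, 0)
  ref <- matrix(c(1, 0, 1, 0), nrow = 1, dimnames = list("r1", NULL))
  db <- rbind(d1 = c(1, 0, 0, 0), d2 = c(0, 0, 0, 1))
  hits <- run_search("pbss", q, db, ref, c(r1 = "active"), k = 2,
                     neighbor_cutoff = 0.2)
  expect_equal(hits$score[hits$compound_id == "d1"], 2 / 3)
})

test_that("MAX fusion takes the best active unit and never loses from more units", {
  set.seed(55)
  M <- 40
  db <- random_fps(30, M, prefix = "db")
  q <- rbinom(M, 1, 0.4)
  refs <- make_ref_set(M = M)
  # adding one more active unit can only raise scores (monotonicity)
  base <- run_search("iss", q, db, refs$fps[1:4, , drop = FALSE],
                     refs$labels[1:4], k = 30, neighbor_cutoff = 0)
  more <- run_search("iss", q, db, refs$fps[1:5, , drop = FALSE],
                     refs$labels[1:5], k = 30, neighbor_cutoff = 0)
  b <- stats::setNames(base$score, base$compound_id)
  m <- stats::setNames(more$score, more$compound_id)
  expect_true(all(m[names(b)] >= b - 1e-12))
  # and ISS dominates CSS because the query is always among the units
  css <- run_search("css", q, db, refs$fps, refs$labels, k = 30)
  iss <- run_search("iss", q, db, refs$fps, refs$labels, k = 30)
  cs <- stats::setNames(css$score, css$compound_id)
  is <- stats::setNames(iss$score, iss$compound_id)
  expect_true(all(is[names(cs)] >= cs - 1e-12))
})

test_that("neighbor classification keeps and rejects by the max-similarity rule", {
  M <- 12
  q <- c(rep(1, 6), rep(0, 6))
  active_ref <- matrix(q, nrow = 1, dimnames = list("a1", NULL))
  decoy <- c(rep(1, 5), 0, 1, rep(0, 5))   # close to the query
  inactive_ref <- matrix(decoy, nrow = 1, dimnames = list("i1", NULL))
  db <- rbind(decoy_copy = decoy,          # identical to the inactive ref
              near_q = c(rep(1, 6), 0, 1, rep(0, 4)),
              random = c(0, 0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 1))
  refs <- rbind(active_ref, inactive_ref)
  labels <- c(a1 = "active", i1 = "inactive")
  isc <- run_search("isc", q, db, refs, labels, k = 3)
  # the decoy matches the inactive reference at Tc = 1 > any active sim
  expect_false("decoy_copy" %in% isc$compound_id)
  expect_true("decoy_copy" %in% attr(isc, "rejected_ids"))
  expect_true("near_q" %in% isc$compound_id)
  expect_equal(attr(isc, "all_scores")[["decoy_copy"]], -Inf)
  # without inactive references the output is exactly ISS
  iss <- run_search("iss", q, db, active_ref, c(a1 = "active"), k = 3)
  isc2 <- run_search("isc", q, db, active_ref, c(a1 = "active"), k = 3)
  expect_equal(isc2$compound_id, iss$compound_id)
  expect_equal(isc2$score, iss$score)
})

test_that("ties between active and inactive maxima are rejected by default", {
  M <- 8
  q <- c(1, 1, 1, 1, 0, 0, 0, 0)
  tied <- c(1, 1, 0, 0, 1, 1, 0, 0)
  refs <- rbind(a1 = q, i1 = q)  # both at Tc = 1 to the query
  labels <- c(a1 = "active", i1 = "inactive")
  db <- rbind(t1 = tied, other = c(0, 0, 0, 0, 0, 0, 1, 1))
  isc <- run_search("isc", q, db, refs, labels, k = 2)
  expect_false("t1" %in% isc$compound_id)   # max_active == max_inactive
  kept <- run_search("isc", q, db, refs, labels, k = 2, reject_ties = FALSE)
  expect_true("t1" %in% kept$compound_id)
})

test_that("profile units compress identical references and preserve labels", {
  M <- 16
  q <- c(rep(1, 8), rep(0, 8))
  same <- do.call(rbind, replicate(5, q, simplify = FALSE))
  rownames(same) <- paste0("a", 1:5)
  labels <- stats::setNames(rep("active", 5), rownames(same))
  nl <- build_neighbor_list(q, same, labels, cutoff = 0.3)
  rm_ <- build_profile_units(nl, "pbiss", cluster_cutoff = 0.4)
  expect_equal(nrow(rm_$active_units), 1)       # one cluster, one profile
  expect_equal(rm_$compression_ratio, 6)        # 5 refs + the query
  expect_equal(as.numeric(rm_$active_units[1, ]), q)

  # a mixed cluster splits into one profile per label
  inact <- matrix(rep(q, 2), nrow = 2, byrow = TRUE,
                  dimnames = list(c("i1", "i2"), NULL))
  refs <- rbind(same, inact)
  labels2 <- stats::setNames(rep(c("active", "inactive"), c(5, 2)),
                             rownames(refs))
  nl2 <- build_neighbor_list(q, refs, labels2, cutoff = 0.3)
  rm2 <- build_profile_units(nl2, "pbisc", cluster_cutoff = 0.4)
  expect_equal(nrow(rm2$active_units), 1)
  expect_equal(nrow(rm2$inactive_units), 1)
  expect_equal(rm2$compression_ratio, 8 / 2)    # 6 active + 2 inactive refs
})

test_that("hit lists are ranked descending with ascending-id tie-break and truncated", {
  M <- 8
  q <- c(1, 1, 1, 1, 0, 0, 0, 0)
  same <- c(1, 1, 1, 0, 0, 0, 0, 0)
  db <- rbind(zz = same, aa = same, mm = q, low = c(0, 0, 0, 0, 1, 1, 1, 1))
  hits <- run_search("css", q, db, matrix(numeric(0), 0, M), character(0),
                     k = 3)
  expect_equal(hits$compound_id, c("mm", "aa", "zz"))  # exact copy first
  expect_equal(hits$score[1], 1)
  expect_equal(hits$rank, 1:3)
  expect_true(all(diff(hits$score) <= 0))
})

test_that("query and reference compounds are excluded from the database", {
  set.seed(77)
  db <- random_fps(20, 30, prefix = "db")
  refs <- make_ref_set(M = 30)
  db_plus <- rbind(db, refs$fps, query1 = rbinom(30, 1, 0.4))
  hits <- run_search("css", db_plus["query1", ], db_plus, refs$fps,
                     refs$labels, k = 20, query_id = "query1")
  expect_false("query1" %in% hits$compound_id)
  expect_length(intersect(hits$compound_id, rownames(refs$fps)), 0)
  expect_length(attr(hits, "all_scores"), 20)
})

test_that("the default truncation is the top 1% of the database", {
  expect_equal(hit_list_size(494199), 4941L)
  expect_equal(hit_list_size(100), 1L)
  expect_equal(hit_list_size(1000, top_frac = 0.05), 50L)
  set.seed(9)
  db <- random_fps(50, 20, prefix = "db")  # floor(0.01 * 50) = 0
  expect_error(run_search("css", rbinom(20, 1, 0.4), db,
                          matrix(numeric(0), 0, 20), character(0)),
               "positive")
})
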