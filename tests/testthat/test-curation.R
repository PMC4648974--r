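test_that("end points are labeled by the 10/30 uM thresholds", {
  expect_equal(label_endpoint("IC50", 5), "active")
  expect_equal(label_endpoint("Ki", 50), "inactive")
  expect_equal(label_endpoint("EC50", 20), "undetermined")
  # threshold values themselves fall in the gray zone (strict inequalities)
  expect_equal(label_endpoint("IC50", 10), "undetermined")
  expect_equal(label_endpoint("IC50", 30), "undetermined")
  # explicit annotations pass through unchanged
  expect_equal(label_endpoint("explicit_label", label = "inactive"), "inactive")
  expect_equal(label_endpoint(c("IC50", "explicit_label"), c(2, NA),
                              c(NA, "active")), c("active", "active"))
  expect_error(label_endpoint("IC50", -1), "positive")
  expect_error(label_endpoint("IC50", NA), "positive")
})

# A class builder: n_act actives, n_inact inactives, plus optional
# conflicted compounds carrying one active and one inactive end point each.
make_class_eps <- function(cid, n_act, n_inact, n_conflicted = 0,
                           n_undetermined = 0) {
  cmp <- function(prefix, n) sprintf("%s_%s_%03d", cid, prefix, seq_len(n))
  rows <- list(
    data.frame(compound_id = cmp("a", n_act), class_id = cid,
               measure = "IC50", value_uM = 1, label = NA),
    data.frame(compound_id = cmp("i", n_inact), class_id = cid,
               measure = "IC50", value_uM = 100, label = NA))
  if (n_conflicted > 0) {
    ids <- cmp("x", n_conflicted)
    rows <- c(rows, list(
      data.frame(compound_id = ids, class_id = cid, measure = "IC50",
                 value_uM = 1, label = NA),
      data.frame(compound_id = ids, class_id = cid, measure = "IC50",
                 value_uM = 100, label = NA)))
  }
  if (n_undetermined > 0)
    rows <- c(rows, list(
      data.frame(compound_id = cmp("u", n_undetermined), class_id = cid,
                 measure = "IC50", value_uM = 20, label = NA)))
  do.call(rbind, rows)
}

test_that("noisy classes are dropped by the 5% conflict rule", {
  # 100 end points of which 6 (3 compounds x 2) are in conflict: 6% > 5%
  noisy <- make_class_eps("noisy", n_act = 50, n_inact = 44, n_conflicted = 3)
  expect_equal(nrow(noisy), 100)
  # 100 end points with 4 conflicting: 4% <= 5%, kept, conflicts removed
  ok <- make_class_eps("ok", n_act = 80, n_inact = 80, n_conflicted = 2)
  out <- filter_classes(rbind(noisy, ok), min_class_size = 10)
  expect_equal(names(out), "ok")
  expect_equal(length(out$ok$actives), 80)
  expect_equal(length(out$ok$inactives), 80)
  expect_false(any(grepl("_x_", out$ok$actives)))  # conflicted removed
  expect_equal(out$ok$n_conflicted_endpoints, 4)
})

test_that("the class-size rule is strictly greater than 70 on both sides", {
  retained <- make_class_eps("big", 100, 71)
  boundary <- make_class_eps("edge", 100, 70)
  out <- filter_classes(rbind(retained, boundary))
  expect_equal(names(out), "big")
})

test_that("undetermined compounds count toward neither actives nor inactives", {
  eps <- make_class_eps("c1", 75, 75, n_undetermined = 40)
  out <- filter_classes(eps)
  expect_equal(length(out$c1$actives), 75)
  expect_equal(length(out$c1$inactives), 75)
})

test_that("retained classes preserve input order", {
  eps <- rbind(make_class_eps("z_first", 80, 80),
               make_class_eps("a_second", 80, 80))
  expect_equal(names(filter_classes(eps)), c("z_first", "a_second"))
})

# Small two-scaffold activity class used by the split tests: 10 actives in
# two tight families, 100 unrelated inactives.
make_two_scaffold_class <- function(seed = 1) {
  set.seed(seed)
  a <- c(rep(1, 12), rep(0, 36)); b <- c(rep(0, 36), rep(1, 12))
  actives <- rbind(
    do.call(rbind, replicate(5, a, simplify = FALSE)),
    do.call(rbind, replicate(5, b, simplify = FALSE)))
  rownames(actives) <- sprintf("act%02d", 1:10)
  inactives <- random_fps(100, 48, density = 0.25, prefix = "inact")
  fps <- rbind(actives, inactives)
  labels <- stats::setNames(rep(c("active", "inactive"), c(10, 100)),
                            rownames(fps))
  activity_class("two_scaffold", fps, labels)
}

test_that("split extracts cluster centroids as queries and splits the rest", {
  ac <- make_two_scaffold_class()
  sp <- split_class(ac, div_cutoff = 0.4, seed = 42)
  expect_length(sp$query_ids, 2)  # one centroid per scaffold family
  ref_act <- sp$reference$id[sp$reference$label == "active"]
  test_act <- sp$test$id[sp$test$label == "active"]
  expect_length(ref_act, 4)
  expect_length(test_act, 4)
  expect_equal(sum(sp$reference$label == "inactive"), 50)
  expect_equal(sum(sp$test$label == "inactive"), 50)
  # the three roles partition the class
  all_ids <- c(sp$query_ids, sp$reference$id, sp$test$id)
  expect_setequal(all_ids, rownames(ac$fps))
  expect_equal(anyDuplicated(all_ids), 0)
  expect_equal(sp$diversity_index, 1)  # two equal families
})

test_that("splitting is bit-identical under a fixed seed", {
  ac <- make_two_scaffold_class()
  s1 <- split_class(ac, 0.4, seed = 7)
  s2 <- split_class(ac, 0.4, seed = 7)
  expect_identical(s1, s2)
  s3 <- split_class(ac, 0.4, seed = 8)
  expect_false(identical(s1$reference$id, s3$reference$id))
})

test_that("the inactive reference share is capped at one fourth for huge classes", {
  set.seed(2)
  actives <- rbind(do.call(rbind, replicate(6, c(rep(1, 10), rep(0, 10)),
                                            simplify = FALSE)))
  rownames(actives) <- paste0("act", 1:6)
  inactives <- random_fps(400, 20, prefix = "inact")
  fps <- rbind(actives, inactives)
  labels <- stats::setNames(rep(c("active", "inactive"), c(6, 400)),
                            rownames(fps))
  ac <- activity_class("capped", fps, labels)
  sp <- split_class(ac, 0.4, seed = 1, inactive_cap_threshold = 300)
  expect_equal(sum(sp$reference$label == "inactive"), 100)  # 400 / 4
  expect_equal(sum(sp$test$label == "inactive"), 300)
})

test_that("a class of singleton actives cannot be split", {
  fps <- rbind(diag(6), random_fps(80, 6, prefix = "inact"))
  rownames(fps)[1:6] <- paste0("act", 1:6)
  labels <- stats::setNames(rep(c("active", "inactive"), c(6, 80)),
                            rownames(fps))
  ac <- activity_class("singletons", fps, labels)
  expect_error(split_class(ac, 0.3, seed = 1), "non-centroid")
})

test_that("inactive reference subsampling enforces the 1:5 ratio cap", {
  ac <- make_two_scaffold_class()
  sp <- split_class(ac, 0.4, seed = 3)
  thinned <- subsample_inactive_refs(sp, max_ratio = 5, seed = 3)
  n_act <- sum(thinned$reference$label == "active")
  expect_lte(sum(thinned$reference$label == "inactive"), 5 * n_act)
  # actives untouched
  expect_setequal(thinned$reference$id[thinned$reference$label == "active"],
                  sp$reference$id[sp$reference$label == "active"])
})

test_that("split manifests round-trip through CSV", {
  ac <- make_two_scaffold_class()
  sp <- split_class(ac, 0.4, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  back <- read_split_manifest(path)
  expect_equal(back$query_ids, sp$query_ids)
  expect_equal(back$reference, sp$reference)
  expect_equal(back$test, sp$test)
})

test_that("zero flip-rate gives identical actives per scaffold and zero entropy at one scaffold", {
  g <- generate_synthetic_class(n_scaffolds = 3, actives_per_scaffold = 4,
                                n_near_inactives = 0, n_far_inactives = 10,
                                n_background = 0, M = 128, flip_rate = 0,
                                seed = 11)
  act <- g$class$fps[class_actives(g$class), ]
  cl <- taylor_butina(act, 0.7)
  expect_length(cl$clusters, 3)  # exactly one cluster per scaffold
  expect_true(all(cluster_sizes(cl) == 4))

  g1 <- generate_synthetic_class(n_scaffolds = 1, actives_per_scaffold = 6,
                                 n_near_inactives = 0, n_far_inactives = 5,
                                 n_background = 0, M = 128, flip_rate = 0,
                                 seed = 11)
  act1 <- g1$class$fps[class_actives(g1$class), ]
  expect_equal(diversity_index(taylor_butina(act1, 0.5)), 0)
})

test_that("within-scaffold similarity decreases as the flip rate grows", {
  mean_within <- function(fr) {
    sims <- vapply(1:20, function(s) {
      g <- generate_synthetic_class(n_scaffolds = 1, actives_per_scaffold = 2,
                                    n_near_inactives = 0, n_far_inactives = 0,
                                    n_background = 0, M = 256, flip_rate = fr,
                                    seed = 1000 + s)
      act <- g$class$fps[class_actives(g$class), ]
      tanimoto_binary(act[1, ], act[2, ])
    }, numeric(1))
    mean(sims)
  }
  m0 <- mean_within(0.01); m1 <- mean_within(0.1); m2 <- mean_within(0.3)
  expect_gt(m0, m1)
  expect_gt(m1, m2)
})

test_that("the generator is reproducible from its seed and labels are disjoint", {
  g1 <- generate_synthetic_class(n_scaffolds = 2, actives_per_scaffold = 5,
                                 n_near_inactives = 8, n_far_inactives = 8,
                                 n_background = 20, M = 128, seed = 3)
  g2 <- generate_synthetic_class(n_scaffolds = 2, actives_per_scaffold = 5,
                                 n_near_inactives = 8, n_far_inactives = 8,
                                 n_background = 20, M = 128, seed = 3)
  expect_identical(g1$class$fps, g2$class$fps)
  expect_identical(g1$background, g2$background)
  expect_length(intersect(class_actives(g1$class), class_inactives(g1$class)),
                0)
  expect_equal(nrow(g1$background), 20)
})
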