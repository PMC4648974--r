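#' Label a bioactivity end point
#'
#' Concentration end points (IC50, EC50, Ki, in micromolar) are called
#' active below `active_below_uM` and inactive above `inactive_above_uM`;
#' concentrations in the gray zone between the two thresholds are
#' undetermined. End points that already carry an explicit active/inactive
#' annotation (`measure = "explicit_label"`) pass through unchanged.
#' Vectorized over end points.
#'
#' @param measure character: `"IC50"`, `"EC50"`, `"Ki"`, or
#'   `"explicit_label"`.
#' @param value_uM positive concentration in micromolar (ignored for
#'   explicit labels).
#' @param label for explicit labels, `"active"` or `"inactive"`.
#' @param active_below_uM,inactive_above_uM labeling thresholds in
#'   micromolar (defaults 10 and 30).
#' @return character vector over `{"active", "inactive", "undetermined"}`.
#' @export
#' @examples
#' label_endpoint("IC50", 5)    # active
#' label_endpoint("Ki", 50)     # inactive
#' label_endpoint("EC50", 20)   # undetermined
label_endpoint <- function(measure, value_uM = NA_real_, label = NA_character_,
                           active_below_uM = 10, inactive_above_uM = 30) {
  n <- max(length(measure), length(value_uM), length(label))
  measure <- rep_len(as.character(measure), n)
  value_uM <- rep_len(as.numeric(value_uM), n)
  label <- rep_len(as.character(label), n)
  conc_measures <- c("IC50", "EC50", "Ki")
  bad <- !(measure %in% c(conc_measures, "explicit_label"))
  if (any(bad)) stop("unknown measure: ", paste(unique(measure[bad]),
                                                collapse = ", "))
  is_conc <- measure %in% conc_measures
  if (any(is_conc & (is.na(value_uM) | value_uM <= 0)))
    stop("concentration end points require a positive value_uM")
  if (any(!is_conc & !(label %in% c("active", "inactive"))))
    stop("explicit_label end points require label 'active' or 'inactive'")
  out <- rep("undetermined", n)
  out[is_conc & value_uM < active_below_uM] <- "active"
  out[is_conc & value_uM > inactive_above_uM] <- "inactive"
  out[!is_conc] <- label[!is_conc]
  out
}

#' Read an end-point table
#'
#' CSV with header `compound_id,class_id,measure,value_uM,label`.
#'
#' @param path input CSV file.
#' @return data.frame of end points.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "class_id", "measure")
  if (!all(required %in% names(df)))
    stop("end-point table must have columns ", paste(required, collapse = ", "))
  if (is.null(df$value_uM)) df$value_uM <- NA_real_
  if (is.null(df$label)) df$label <- NA_character_
  df
}

#' Curate end-point tables into benchmark-ready activity classes
#'
#' Applies the three-stage filtering protocol to a table of labeled end
#' points: (1) drop a class outright when more than `max_conflict_frac` of
#' its end points are in conflict — an end point is "in conflict" when its
#' compound carries both active and inactive end points within the class;
#' (2) in surviving classes, remove the conflicted compounds and all their
#' end points; (3) keep only classes whose deduplicated actives and
#' inactives each exceed `min_class_size`. Compounds whose end points are
#' all undetermined contribute to neither set. Input class order is
#' preserved in the output.
#'
#' @param endpoints data.frame with columns `compound_id`, `class_id`,
#'   `measure`, and `value_uM` / `label` as required by [label_endpoint()].
#' @param active_below_uM,inactive_above_uM thresholds passed to
#'   [label_endpoint()].
#' @param max_conflict_frac maximum tolerated conflict fraction (default
#'   0.05, strict `>` drops the class).
#' @param min_class_size both actives and inactives must exceed this count
#'   (strictly) for a class to be retained; default 70.
#' @return named list of retained classes, each a list with `class_id`,
#'   `actives` and `inactives` (compound id vectors), `n_endpoints`, and
#'   `n_conflicted_endpoints`.
#' @export
filter_classes <- function(endpoints, active_below_uM = 10,
                           inactive_above_uM = 30,
                           max_conflict_frac = 0.05, min_class_size = 70) {
  endpoints$ep_label <- label_endpoint(endpoints$measure, endpoints$value_uM,
                                       endpoints$label, active_below_uM,
                                       inactive_above_uM)
  out <- list()
  for (cid in unique(endpoints$class_id)) {
    eps <- endpoints[endpoints$class_id == cid, , drop = FALSE]
    act_cpds <- unique(eps$compound_id[eps$ep_label == "active"])
    inact_cpds <- unique(eps$compound_id[eps$ep_label == "inactive"])
    conflicted <- intersect(act_cpds, inact_cpds)
    n_conf_eps <- sum(eps$compound_id %in% conflicted &
                        eps$ep_label %in% c("active", "inactive"))
    n_total <- nrow(eps)
    if (n_conf_eps / n_total > max_conflict_frac) next
    eps <- eps[!(eps$compound_id %in% conflicted), , drop = FALSE]
    actives <- unique(eps$compound_id[eps$ep_label == "active"])
    inactives <- unique(eps$compound_id[eps$ep_label == "inactive"])
    if (length(actives) <= min_class_size ||
        length(inactives) <= min_class_size) next
    out[[as.character(cid)]] <- list(class_id = as.character(cid),
                                     actives = actives, inactives = inactives,
                                     n_endpoints = n_total,
                                     n_conflicted_endpoints = n_conf_eps)
  }
  out
}

#' Construct an activity class
#'
#' Bundles the curated compounds of one protein target: a fingerprint
#' matrix over all labeled compounds of the class plus their
#' active/inactive annotations. Actives and inactives must be disjoint.
#'
#' @param class_id class identifier.
#' @param fps binary fingerprint matrix (rownames = compound ids) covering
#'   every labeled compound of the class.
#' @param labels named character vector over the rownames of `fps`, values
#'   `"active"` or `"inactive"`.
#' @return object of class `activity_class`.
#' @export
activity_class <- function(class_id, fps, labels) {
  fps <- as_fingerprint_matrix(fps)
  if (is.null(names(labels))) stop("labels must be named by compound id")
  if (!setequal(names(labels), rownames(fps)))
    stop("labels and fingerprint rows must cover the same compounds")
  labels <- labels[rownames(fps)]
  if (!all(labels %in% c("active", "inactive")))
    stop("labels must be 'active' or 'inactive'")
  structure(list(class_id = as.character(class_id), fps = fps,
                 labels = labels),
            class = "activity_class")
}

#' @export
print.activity_class <- function(x, ...) {
  cat(sprintf("Activity class '%s': %d actives, %d inactives, %d-bit fingerprints\n",
              x$class_id, sum(x$labels == "active"),
              sum(x$labels == "inactive"), ncol(x$fps)))
  invisible(x)
}

#' Active / inactive compound ids of an activity class
#' @param ac an `activity_class`.
#' @return character vector of compound ids.
#' @export
class_actives <- function(ac) names(ac$labels)[ac$labels == "active"]

#' @rdname class_actives
#' @export
class_inactives <- function(ac) names(ac$labels)[ac$labels == "inactive"]

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split an activity class into query, reference and test sets
#'
#' The query set is the set of Taylor-Butina cluster centroids of the
#' class's actives at `div_cutoff` — one structurally representative query
#' per scaffold cluster. The remaining actives are randomly assigned to the
#' reference and test sets (fraction `ref_frac` to the reference set);
#' inactives are split the same way, except that when the class holds more
#' than `inactive_cap_threshold` inactives the reference share is capped at
#' one fourth of the total, the remainder going to the test set. The split
#' is deterministic given `seed`. The class's structural diversity index is
#' computed from the same clustering and stored on the result.
#'
#' @param ac an [activity_class()].
#' @param div_cutoff Taylor-Butina similarity cutoff used for the query-set
#'   clustering (and the diversity index).
#' @param seed integer seed controlling the random assignments.
#' @param inactive_cap_threshold inactive count above which the reference
#'   share of inactives is capped at 1/4 (default 20000).
#' @param ref_frac fraction of the non-centroid compounds assigned to the
#'   reference set in the uncapped case (default 0.5).
#' @return object of class `split_dataset`: list with `class_id`,
#'   `query_ids`, `reference` and `test` (data.frames of `id`, `label`),
#'   `diversity_index`, `div_cutoff`, `seed`.
#' @export
split_class <- function(ac, div_cutoff, seed,
                        inactive_cap_threshold = 20000L, ref_frac = 0.5) {
  stopifnot(inherits(ac, "activity_class"))
  actives <- class_actives(ac)
  inactives <- class_inactives(ac)
  clust <- taylor_butina(ac$fps[actives, , drop = FALSE], div_cutoff)
  queries <- cluster_centroids(clust)
  H <- diversity_index(clust)
  rest_act <- setdiff(actives, queries)
  if (length(rest_act) < 2L)
    stop("class '", ac$class_id, "': fewer than 2 non-centroid actives; ",
         "cannot populate both reference and test sets")
  assignment <- .with_seed(seed, {
    act_perm <- sample(rest_act)
    inact_perm <- sample(inactives)
    list(act = act_perm, inact = inact_perm)
  })
  n_act_ref <- floor(ref_frac * length(rest_act))
  ref_act <- assignment$act[seq_len(n_act_ref)]
  test_act <- setdiff(assignment$act, ref_act)
  n_inact <- length(inactives)
  n_inact_ref <- if (n_inact > inactive_cap_threshold)
    floor(n_inact / 4) else floor(ref_frac * n_inact)
  ref_inact <- assignment$inact[seq_len(n_inact_ref)]
  test_inact <- setdiff(assignment$inact, ref_inact)
  mkdf <- function(act, inact) data.frame(
    id = c(act, inact),
    label = rep(c("active", "inactive"), c(length(act), length(inact))),
    stringsAsFactors = FALSE)
  structure(list(class_id = ac$class_id, query_ids = queries,
                 reference = mkdf(ref_act, ref_inact),
                 test = mkdf(test_act, test_inact),
                 diversity_index = H, div_cutoff = div_cutoff, seed = seed),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf(paste0("Split of class '%s' (H = %.2f): %d queries, ",
                     "%d reference (%d active), %d test (%d active)\n"),
              x$class_id, x$diversity_index, length(x$query_ids),
              nrow(x$reference), sum(x$reference$label == "active"),
              nrow(x$test), sum(x$test$label == "active")))
  invisible(x)
}

#' Subsample inactive references
#'
#' Optional reference-set thinning: randomly drops inactive references in
#' excess of `max_ratio` times the number of active references, keeping the
#' active:inactive ratio at or above 1:`max_ratio`. Off by default in the
#' benchmark pipeline.
#'
#' @param split a `split_dataset`.
#' @param max_ratio maximum inactive:active ratio in the reference set
#'   (default 5).
#' @param seed integer seed for the random drop.
#' @return the `split_dataset` with a thinned reference set.
#' @export
subsample_inactive_refs <- function(split, max_ratio = 5, seed = 1L) {
  ref <- split$reference
  act_ids <- ref$id[ref$label == "active"]
  inact_ids <- ref$id[ref$label == "inactive"]
  cap <- floor(max_ratio * length(act_ids))
  if (length(inact_ids) > cap) {
    keep <- .with_seed(seed, sample(inact_ids, cap))
    ref <- ref[ref$id %in% c(act_ids, keep), , drop = FALSE]
    rownames(ref) <- NULL
    split$reference <- ref
  }
  split
}

#' Write / read a split manifest
#'
#' CSV with columns `compound_id,class_id,role,label` where role is one of
#' `query`, `reference`, `test` (label `unknown` is used for background
#' records when present).
#'
#' @param split a `split_dataset`.
#' @param path output CSV.
#' @export
write_split_manifest <- function(split, path) {
  df <- rbind(
    data.frame(compound_id = split$query_ids, class_id = split$class_id,
               role = "query", label = "active", stringsAsFactors = FALSE),
    data.frame(compound_id = split$reference$id, class_id = split$class_id,
               role = "reference", label = split$reference$label,
               stringsAsFactors = FALSE),
    data.frame(compound_id = split$test$id, class_id = split$class_id,
               role = "test", label = split$test$label,
               stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @return `read_split_manifest`: a `split_dataset` (without clustering
#'   metadata, which the manifest does not store).
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(role) df[df$role == role, , drop = FALSE]
  q <- pick("query"); r <- pick("reference"); te <- pick("test")
  structure(list(class_id = as.character(df$class_id[1]),
                 query_ids = q$compound_id,
                 reference = data.frame(id = r$compound_id, label = r$label,
                                        stringsAsFactors = FALSE),
                 test = data.frame(id = te$compound_id, label = te$label,
                                   stringsAsFactors = FALSE),
                 diversity_index = NA_real_, div_cutoff = NA_real_,
                 seed = NA_integer_),
            class = "split_dataset")
}

#' Generate a synthetic activity class
#'
#' Emulates the structure of a curated bioassay activity class without any
#' chemistry: actives come in scaffold families (clusters of
#' near-duplicate fingerprints around random prototypes), annotated
#' inactives are planted both near the active scaffolds (activity-cliff
#' decoys, derived from the same prototypes with a larger bit-flip rate)
#' and far from them (independent random fingerprints), and a large
#' unknown-label background plays the role of the screening database.
#'
#' All prototypes of a class share a common "core" bit vector — ligands of
#' one target carry common substructure features even across scaffold
#' families — so actives of different scaffolds are measurably more
#' similar to each other than to random database compounds. On top of the
#' core (density `core_frac * prototype_density`), each prototype sets
#' scaffold-specific bits so its total density is `prototype_density`.
#' Each active flips every prototype bit independently with probability
#' `flip_rate`, each near-inactive with probability `near_flip_rate`. Far
#' inactives and background compounds are i.i.d. random fingerprints whose
#' bit density matches the expected popcount of the actives, so they are
#' indistinguishable from actives by popcount alone. With `flip_rate = 0`
#' all actives of a scaffold are identical. Fully reproducible from
#' `seed`.
#'
#' @param n_scaffolds number of scaffold families (default 8).
#' @param actives_per_scaffold actives drawn per family (default 25).
#' @param n_near_inactives activity-cliff decoys, assigned to scaffolds in
#'   round-robin (default 100).
#' @param n_far_inactives unrelated annotated inactives (default 100).
#' @param n_background unknown-label database compounds (default 2000).
#' @param M fingerprint length in bits (default 1024).
#' @param flip_rate per-bit flip probability for actives, in \[0, 0.5)
#'   (default 0.05).
#' @param seed integer seed.
#' @param prototype_density total bit density of each scaffold prototype
#'   (default 0.3).
#' @param core_frac fraction of the prototype density carried by the
#'   class-wide shared core (default 0.5).
#' @param near_flip_rate per-bit flip probability for near-inactives
#'   (default `3 * flip_rate`, capped at 0.45).
#' @return list with `class` (an [activity_class()]) and `background`
#'   (fingerprint matrix of unknown-label compounds).
#' @export
generate_synthetic_class <- function(n_scaffolds = 8L,
                                     actives_per_scaffold = 25L,
                                     n_near_inactives = 100L,
                                     n_far_inactives = 100L,
                                     n_background = 2000L,
                                     M = 1024L, flip_rate = 0.05, seed = 1L,
                                     prototype_density = 0.3,
                                     core_frac = 0.5,
                                     near_flip_rate = min(3 * flip_rate, 0.45)) {
  stopifnot(n_scaffolds >= 1, actives_per_scaffold >= 1, M > 0,
            flip_rate >= 0, flip_rate < 0.5,
            near_flip_rate >= 0, near_flip_rate < 0.5,
            core_frac >= 0, core_frac <= 1)
  .with_seed(seed, {
    p <- prototype_density
    p_core <- core_frac * p
    # density of the scaffold-specific bits so that the total stays at p
    p_spec <- if (p_core < 1) (p - p_core) / (1 - p_core) else 0
    core <- rbinom(M, 1, p_core)
    protos <- t(vapply(seq_len(n_scaffolds), function(s)
      pmax(core, rbinom(M, 1, p_spec)), numeric(M)))
    flip <- function(proto, rate, n) {
      base <- matrix(rep(proto, each = n), nrow = n)
      if (rate > 0) {
        flips <- matrix(rbinom(n * M, 1, rate), nrow = n)
        base <- abs(base - flips)
      }
      base
    }
    actives <- do.call(rbind, lapply(seq_len(n_scaffolds), function(s)
      flip(protos[s, ], flip_rate, actives_per_scaffold)))
    rownames(actives) <- sprintf("act_s%02d_%03d",
                                 rep(seq_len(n_scaffolds),
                                     each = actives_per_scaffold),
                                 sequence(rep(actives_per_scaffold,
                                              n_scaffolds)))
    near <- NULL
    if (n_near_inactives > 0) {
      scaffold_of <- rep_len(seq_len(n_scaffolds), n_near_inactives)
      near <- do.call(rbind, lapply(seq_len(n_near_inactives), function(i)
        flip(protos[scaffold_of[i], ], near_flip_rate, 1L)))
      rownames(near) <- sprintf("ninact_%04d", seq_len(n_near_inactives))
    }
    # density matched to the expected active popcount
    q <- p * (1 - flip_rate) + (1 - p) * flip_rate
    rand_fps <- function(n, prefix) {
      if (n == 0) return(NULL)
      m <- matrix(rbinom(n * M, 1, q), nrow = n)
      rownames(m) <- sprintf("%s_%04d", prefix, seq_len(n))
      m
    }
    far <- rand_fps(n_far_inactives, "finact")
    background <- rand_fps(n_background, "bg")
    if (is.null(background))
      background <- matrix(numeric(0), nrow = 0, ncol = M)
    fps <- rbind(actives, near, far)
    labels <- stats::setNames(
      rep(c("active", "inactive"),
          c(nrow(actives), nrow(fps) - nrow(actives))),
      rownames(fps))
    list(class = activity_class(sprintf("synth_seed%d", seed), fps, labels),
         background = background)
  })
}
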