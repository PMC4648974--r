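#' Benchmark configuration
#'
#' Collects every tunable of an end-to-end benchmark run into one
#' validated list. Defaults mirror the standard screening protocol:
#' neighbor lists at Tanimoto > 0.3, reference profiling by Taylor-Butina
#' at 0.4, hit lists truncated to the top 1% of the database, 1024-bit
#' circular fingerprints.
#'
#' @param engines engines to run (default all six).
#' @param n_classes number of synthetic activity classes (default 20).
#' @param neighbor_cutoff neighbor-list threshold (default 0.3).
#' @param cluster_cutoff profiling cluster cutoff (default 0.4).
#' @param div_cutoff query-set / diversity-index cluster cutoff (default
#'   0.4).
#' @param top_frac hit-list fraction (default 0.01).
#' @param seed master seed; each class derives its own seed from it.
#' @param synth list of [generate_synthetic_class()] arguments overriding
#'   the generator defaults.
#' @param ref_frac reference share of the random active/inactive splits.
#' @param inactive_cap_threshold see [split_class()].
#' @param comparisons list of engine pairs for [compare_engines()];
#'   default compares each enhanced engine to CSS.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(engines = search_engines(), n_classes = 20L,
                             neighbor_cutoff = 0.3, cluster_cutoff = 0.4,
                             div_cutoff = 0.4, top_frac = 0.01, seed = 1L,
                             synth = list(), ref_frac = 0.5,
                             inactive_cap_threshold = 20000L,
                             comparisons = NULL) {
  engines <- match.arg(engines, search_engines(), several.ok = TRUE)
  stopifnot(n_classes >= 1,
            neighbor_cutoff > 0, neighbor_cutoff < 1,
            cluster_cutoff > 0, cluster_cutoff < 1,
            div_cutoff > 0, div_cutoff < 1,
            top_frac > 0, top_frac <= 1)
  if (is.null(comparisons))
    comparisons <- lapply(setdiff(engines, "css"), function(e) c(e, "css"))
  structure(list(engines = engines, n_classes = as.integer(n_classes),
                 neighbor_cutoff = neighbor_cutoff,
                 cluster_cutoff = cluster_cutoff, div_cutoff = div_cutoff,
                 top_frac = top_frac, seed = as.integer(seed), synth = synth,
                 ref_frac = ref_frac,
                 inactive_cap_threshold = as.integer(inactive_cap_threshold),
                 comparisons = comparisons),
            class = "benchmark_config")
}

#' Read a benchmark configuration from YAML
#'
#' @param path YAML file whose top-level keys are [benchmark_config()]
#'   arguments.
#' @return a `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$comparisons <- if (!is.null(cfg$comparisons))
    lapply(cfg$comparisons, unlist)
  do.call(benchmark_config, cfg[!vapply(cfg, is.null, logical(1))])
}

# Run every query of one prepared class through one engine and collect
# per-query metrics. `db` holds test + background fingerprints only.
.run_class_engine <- function(engine, prepared, config) {
  split <- prepared$split
  test_labels <- stats::setNames(split$test$label, split$test$id)
  ref_ids <- split$reference$id
  ref_fps <- prepared$fps[ref_ids, , drop = FALSE]
  ref_labels <- stats::setNames(split$reference$label, ref_ids)
  db <- prepared$db
  rows <- lapply(split$query_ids, function(qid) {
    hits <- run_search(engine, prepared$fps[qid, ], db, ref_fps, ref_labels,
                       top_frac = config$top_frac,
                       neighbor_cutoff = config$neighbor_cutoff,
                       cluster_cutoff = config$cluster_cutoff,
                       query_id = qid)
    qm <- query_metrics(hits, test_labels, nrow(db))
    nl <- build_neighbor_list(prepared$fps[qid, ], ref_fps, ref_labels,
                              config$neighbor_cutoff)
    comp <- build_profile_units(nl, "pbisc", config$cluster_cutoff)
    cbind(data.frame(class_id = split$class_id, query_id = qid,
                     engine = engine, stringsAsFactors = FALSE),
          qm,
          data.frame(compression_ratio = comp$compression_ratio))
  })
  do.call(rbind, rows)
}

# Generate, split and assemble one synthetic class; returns fingerprints,
# the split, and the screening database (test + background).
.prepare_synthetic_class <- function(class_seed, config) {
  synth_args <- config$synth
  synth_args$seed <- class_seed
  gen <- do.call(generate_synthetic_class, synth_args)
  ac <- gen$class
  split <- split_class(ac, div_cutoff = config$div_cutoff, seed = class_seed,
                       inactive_cap_threshold = config$inactive_cap_threshold,
                       ref_frac = config$ref_frac)
  fps <- ac$fps
  db <- rbind(fps[split$test$id, , drop = FALSE], gen$background)
  list(class = ac, split = split, fps = fps, db = db)
}

#' Run a full benchmark over synthetic activity classes
#'
#' End-to-end orchestration of the screening protocol: for each of
#' `n_classes` synthetic activity classes (seeded independently from the
#' master seed, so results do not depend on execution order), the class is
#' generated, split into query/reference/test sets, and every query is run
#' through every configured engine against the test-plus-background
#' database; per-query metrics, per-class summaries and paired engine
#' comparisons are collected. The run is fully deterministic given the
#' config.
#'
#' @param config a [benchmark_config()].
#' @param out_dir optional directory; when given, `metrics.csv`,
#'   `summary.csv`, `comparison.csv` and a `manifest.json` (config, seed,
#'   package version) are written there.
#' @param progress print a line per class (default `FALSE`).
#' @return list with `metrics` (per query), `summary` (per class/engine),
#'   `comparison` (per class/engine-pair), `failed_classes` (count of
#'   classes skipped after an error).
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          progress = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  metrics <- list()
  failed <- 0L
  for (i in seq_len(config$n_classes)) {
    class_seed <- config$seed + i
    res <- tryCatch({
      prepared <- .prepare_synthetic_class(class_seed, config)
      do.call(rbind, lapply(config$engines, .run_class_engine,
                            prepared = prepared, config = config))
    }, error = function(e) {
      warning("class with seed ", class_seed, " failed and was skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failed <- failed + 1L; next }
    metrics[[length(metrics) + 1L]] <- res
    if (progress)
      message(sprintf("class %d/%d done (%d queries x %d engines)",
                      i, config$n_classes, length(unique(res$query_id)),
                      length(config$engines)))
  }
  if (length(metrics) == 0L) stop("every benchmark class failed")
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  summary <- class_metrics(metrics)
  comparison <- do.call(rbind, lapply(config$comparisons, function(pair) {
    if (all(pair %in% config$engines))
      compare_engines(metrics, pair[1], pair[2])
  }))
  if (!is.null(comparison)) rownames(comparison) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE, quote = FALSE)
    manifest <- list(
      config = unclass(config),
      package_version = as.character(utils::packageVersion("profsearch")),
      r_version = R.version.string,
      failed_classes = failed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(metrics = metrics, summary = summary, comparison = comparison,
       failed_classes = failed)
}

#' Materialize synthetic classes as plain-text files
#'
#' Writes each generated class as a fingerprint file (including the
#' background compounds) plus a split manifest, the on-disk inputs the
#' command-line `run` subcommand consumes.
#'
#' @param config a [benchmark_config()].
#' @param out_dir output directory; per class, `<class_id>_fps.tsv` and
#'   `<class_id>_split.csv` are created.
#' @return character vector of class ids, invisibly.
#' @export
materialize_synthetic_classes <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(0)
  for (i in seq_len(config$n_classes)) {
    prepared <- .prepare_synthetic_class(config$seed + i, config)
    cid <- prepared$class$class_id
    all_fps <- rbind(prepared$fps, prepared$db[setdiff(rownames(prepared$db),
                                                       rownames(prepared$fps)),
                                               , drop = FALSE])
    write_fingerprints(all_fps, file.path(out_dir, paste0(cid, "_fps.tsv")))
    write_split_manifest(prepared$split,
                         file.path(out_dir, paste0(cid, "_split.csv")))
    ids <- c(ids, cid)
  }
  invisible(ids)
}
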