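#' Read and validate a pipeline configuration
#'
#' The pipeline is driven by one YAML file (keys below, all overridable by
#' an `overrides` list, e.g. from command-line flags). Paths are resolved
#' relative to the configuration file.
#'
#' Keys: `annotation`, `family_table`, `sif`, `tf_list`, `id_map` (paths;
#' the last three optional), `cutoff_bp` (10000), `max_span_bp` (none),
#' `same_strand_only` (false), `steps` (list of step counts and/or
#' `"closure"`; default `[1, "closure"]`), `curve_max_steps` (6),
#' `universe` (`all`|`gene_only`), `mcode` (mapping of [mcode_params()]
#' fields), `B` (1000), `n_random_sets` (20), `seed` (required),
#' `out_dir` (required).
#'
#' @param path YAML file, or a list already parsed.
#' @param overrides named list merged over the file's keys.
#' @return list of class `pipeline_config` (with `config_hash` attached).
#' @export
read_pipeline_config <- function(path, overrides = NULL) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) config_error("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    for (key in c("annotation", "family_table", "sif", "tf_list", "id_map")) {
      if (!is.null(raw[[key]]) && !grepl("^/", raw[[key]])) {
        raw[[key]] <- file.path(base, raw[[key]])
      }
    }
    raw
  } else {
    path
  }
  for (key in names(overrides)) cfg[[key]] <- overrides[[key]]
  defaults <- list(
    family_table = NULL, tf_list = NULL, id_map = NULL,
    cutoff_bp = 10000L, max_span_bp = NULL, same_strand_only = FALSE,
    steps = list(1L, "closure"), curve_max_steps = 6L,
    universe = "all", mcode = list(), B = 1000L, n_random_sets = 20L
  )
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  for (key in c("annotation", "sif", "seed", "out_dir")) {
    if (is.null(cfg[[key]])) config_error("config key '", key, "' is required")
  }
  for (key in c("annotation", "sif", "family_table", "tf_list", "id_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      config_error("configured ", key, " file does not exist: ", cfg[[key]])
    }
  }
  if (!cfg$universe %in% c("all", "gene_only")) {
    config_error("universe must be 'all' or 'gene_only'")
  }
  cfg$steps <- lapply(cfg$steps, function(s) {
    if (identical(s, "closure")) s else as.integer(s)
  })
  cfg$seed <- as.integer(cfg$seed)
  cfg$B <- as.integer(cfg$B)
  cfg$mcode <- do.call(mcode_params, cfg$mcode)
  hash_input <- jsonlite::toJSON(cfg[sort(setdiff(names(cfg), "out_dir"))],
                                 auto_unbox = TRUE, force = TRUE)
  attr(cfg, "config_hash") <- sprintf("%08x", poly_hash(as.character(hash_input)))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

pipeline_meta <- function(cfg) {
  sprintf("# mircoord %s | seed=%d | config_hash=%s",
          as.character(packageVersion("mircoord")), cfg$seed,
          attr(cfg, "config_hash"))
}

write_stage_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pipeline_meta(cfg), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

write_stage_json <- function(x, path, cfg) {
  x <- c(list(mircoord = as.character(packageVersion("mircoord")),
              seed = cfg$seed, config_hash = attr(cfg, "config_hash")), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$out_dir
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "mircoord_stage_error")) stop(e)
    stage_error(stage, e)
  })
}

#' Pipeline stage: cluster calling
#'
#' @param cfg a `pipeline_config` (or path to one).
#' @return invisibly, a list with the `cluster_call` and annotation.
#' @export
pipeline_clusters <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  with_stage("clusters", {
    ensure_out_dir(cfg)
    ann <- read_mirna_annotations(cfg$annotation, family_table = cfg$family_table)
    cc <- detect_clusters(ann, cutoff_bp = cfg$cutoff_bp,
                          max_span_bp = cfg$max_span_bp,
                          same_strand_only = cfg$same_strand_only)
    write_stage_tsv(cc$clusters, file.path(cfg$out_dir, "clusters.tsv"), cfg)
    iso <- cc$isolated[, c("id", "chrom", "start", "end", "strand", "family")]
    write_stage_tsv(iso, file.path(cfg$out_dir, "isolated.tsv"), cfg)
    invisible(list(clusters = cc, annotation = ann))
  })
}

#' Pipeline stage: network validation
#' @inheritParams pipeline_clusters
#' @return invisibly, a list with the network and its validation report.
#' @export
pipeline_validate <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  with_stage("validate", {
    ensure_out_dir(cfg)
    network <- read_sif(cfg$sif, tf_list = cfg$tf_list)
    report <- validate_network(network)
    write_stage_json(unclass(report), file.path(cfg$out_dir, "network_validation.json"), cfg)
    invisible(list(network = network, validation = report))
  })
}

#' Pipeline stage: module detection
#' @inheritParams pipeline_clusters
#' @param state optional list with `network`, `clusters`, `annotation` from
#'   earlier stages (recomputed from the config when absent).
#' @return invisibly, the state extended with `modules` and
#'   `modules_report`.
#' @export
pipeline_modules <- function(cfg, state = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  state <- state %||% list()
  if (is.null(state$network)) state$network <- pipeline_validate(cfg)$network
  if (is.null(state$clusters)) state$clusters <- pipeline_clusters(cfg)$clusters
  with_stage("modules", {
    mods <- mcode(state$network, params = cfg$mcode)
    write_stage_tsv(mods$summary, file.path(cfg$out_dir, "modules.tsv"), cfg)
    rep <- modules_report(mods, state$clusters, state$network)
    write_stage_tsv(rep, file.path(cfg$out_dir, "modules_report.tsv"), cfg)
    state$modules <- mods
    state$modules_report <- rep
    invisible(state)
  })
}

#' Pipeline stage: target-overlap statistics
#' @inheritParams pipeline_modules
#' @return invisibly, the state extended with `pairs`, `to_tables`, `curve`.
#' @export
pipeline_overlap <- function(cfg, state = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  state <- state %||% list()
  if (is.null(state$network)) state$network <- pipeline_validate(cfg)$network
  if (is.null(state$clusters)) state$clusters <- pipeline_clusters(cfg)$clusters
  with_stage("overlap", {
    mirna_ids <- state$clusters$genes$id
    random_sets <- generate_random_clusters(
      mirna_ids, state$clusters, B = cfg$n_random_sets,
      seed = stage_seed(cfg$seed, "random_sets")
    )
    pairs <- category_pairs(state$clusters, state$network,
                            random_sets = random_sets, id_map = cfg$id_map)
    to_tables <- list()
    for (st in cfg$steps) {
      key <- as.character(st)
      tabs <- list()
      for (cat_name in c("homo", "hetero", "random")) {
        p <- pairs[[cat_name]]
        if (is.null(p) || !NROW(p)) next
        tab <- target_overlap_table(state$network,
                                    p[, c("mirna_i", "mirna_j"), drop = FALSE],
                                    steps = st, universe = cfg$universe)
        tab$category <- cat_name
        if (cat_name == "random") tab$replicate <- p$replicate
        tabs[[cat_name]] <- tab
      }
      to_tables[[key]] <- tabs
      flat <- do.call(rbind, lapply(tabs, function(t) {
        t$replicate <- NULL; t
      }))
      write_stage_tsv(flat, file.path(cfg$out_dir, sprintf("pairs_steps_%s.tsv", key)), cfg)
    }
    curve <- to_vs_steps_curve(pairs, state$network,
                               max_steps = cfg$curve_max_steps,
                               universe = cfg$universe)
    write_stage_tsv(as.data.frame(curve), file.path(cfg$out_dir, "to_curve.tsv"), cfg)
    state$random_sets <- random_sets
    state$pairs <- pairs
    state$to_tables <- to_tables
    state$curve <- curve
    invisible(state)
  })
}

#' Pipeline stage: permutation tests
#' @inheritParams pipeline_modules
#' @return invisibly, the state extended with `tests` (a named list of
#'   [empirical_test()] reports, also written as JSON).
#' @export
pipeline_permtest <- function(cfg, state = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  state <- state %||% list()
  if (is.null(state$network)) state$network <- pipeline_validate(cfg)$network
  if (is.null(state$clusters)) state$clusters <- pipeline_clusters(cfg)$clusters
  if (is.null(state$modules)) state <- pipeline_modules(cfg, state)
  if (is.null(state$to_tables)) state <- pipeline_overlap(cfg, state)
  with_stage("permtest", {
    tests <- list()
    enr <- clustered_mirna_enrichment(
      state$modules, state$clusters, state$network, B = cfg$B,
      seed = stage_seed(cfg$seed, "enrichment"), id_map = cfg$id_map
    )
    tests$enrichment_homo <- enr$homo
    tests$enrichment_hetero <- enr$hetero
    entropy_sets <- generate_random_clusters(
      state$clusters$genes$id, state$clusters, B = cfg$B,
      seed = stage_seed(cfg$seed, "entropy_null")
    )
    tests$module_entropy <- entropy_null_test(
      state$modules, state$clusters, state$network, entropy_sets,
      id_map = cfg$id_map
    )
    for (st in names(state$to_tables)) {
      tabs <- state$to_tables[[st]]
      if (is.null(tabs$random)) next
      for (cat_name in intersect(c("homo", "hetero"), names(tabs))) {
        tests[[sprintf("to_%s_vs_random_steps_%s", cat_name, st)]] <-
          to_contrast_test(tabs[[cat_name]], tabs$random, B = cfg$B,
                           seed = stage_seed(cfg$seed, paste0("to_", cat_name, "_", st)))
      }
    }
    write_stage_json(lapply(tests, empirical_test_report),
                     file.path(cfg$out_dir, "permutation_tests.json"), cfg)
    state$tests <- tests
    invisible(state)
  })
}

#' Run the full analysis pipeline
#'
#' Executes cluster calling, network validation, module detection,
#' target-overlap statistics and permutation tests, writing every stage
#' table plus a single `summary.json` and a `run_log.txt` under
#' `cfg$out_dir`. Every output embeds the seed and a configuration hash;
#' stage RNG streams are derived from the single seed, so stage-wise runs
#' reproduce the pipeline exactly.
#'
#' @param cfg a `pipeline_config`, a path to a YAML configuration, or a
#'   plain list of configuration keys.
#' @param overrides optional named list of keys overriding the file.
#' @return invisibly, the final pipeline state (clusters, network, modules,
#'   pairs, tests, summary).
#' @export
run_pipeline <- function(cfg, overrides = NULL) {
  if (!inherits(cfg, "pipeline_config")) {
    cfg <- read_pipeline_config(cfg, overrides = overrides)
  }
  t0 <- Sys.time()
  ensure_out_dir(cfg)
  state <- list()
  cl <- pipeline_clusters(cfg)
  state$clusters <- cl$clusters
  state$annotation <- cl$annotation
  val <- pipeline_validate(cfg)
  state$network <- val$network
  state$validation <- val$validation
  state <- pipeline_modules(cfg, state)
  state <- pipeline_overlap(cfg, state)
  state <- pipeline_permtest(cfg, state)

  categ <- mirna_categories(state$clusters)
  mean_tos <- list()
  for (st in names(state$to_tables)) {
    tabs <- state$to_tables[[st]]
    mean_tos[[st]] <- lapply(tabs, function(t) {
      if (!is.null(t$replicate)) mean(tapply(t$to, t$replicate, mean))
      else mean(t$to)
    })
  }
  summary <- list(
    n_mirna = nrow(state$clusters$genes),
    n_clusters = nrow(state$clusters$clusters),
    n_homo_clusters = sum(state$clusters$clusters$cluster_type == "homo"),
    n_hetero_clusters = sum(state$clusters$clusters$cluster_type == "hetero"),
    n_isolated = nrow(state$clusters$isolated),
    n_homo_clustered_mirna = sum(categ == "homo"),
    n_hetero_clustered_mirna = sum(categ == "hetero"),
    n_modules = length(state$modules$modules),
    n_modules_with_cluster_pair = sum(state$modules_report$has_cluster_pair),
    mean_to = mean_tos,
    curve_crossing = as.list(attr(state$curve, "crossing")),
    p_values = lapply(state$tests, `[[`, "p_value")
  )
  write_stage_json(summary, file.path(cfg$out_dir, "summary.json"), cfg)
  state$summary <- summary

  log_lines <- c(
    pipeline_meta(cfg),
    sprintf("R %s; igraph %s", as.character(getRversion()),
            as.character(packageVersion("igraph"))),
    sprintf("stages: clusters, validate, modules, overlap, permtest"),
    sprintf("elapsed_s: %.2f", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  )
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(state)
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' Writes a generated scenario (annotation, family table, SIF, TF list,
#' ground truth) into a directory, ready to be consumed by the other
#' stages.
#'
#' @param preset a [scenario_preset()] name, or a `scenario_config`.
#' @param out_dir destination directory.
#' @param seed RNG seed (ignored when a full config is given).
#' @return invisibly, the `mirna_scenario`.
#' @export
pipeline_simulate <- function(preset = "default", out_dir, seed = 1L) {
  config <- if (inherits(preset, "scenario_config")) preset else {
    scenario_preset(preset, seed = seed)
  }
  invisible(generate_scenario(config, out_dir = out_dir))
}
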