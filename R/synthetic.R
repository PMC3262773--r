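#' Synthetic scenario configuration
#'
#' Describes a desk-scale synthetic dataset with the statistical structure
#' the clustered-miRNA coordination analysis assumes: miRNA genes placed on
#' chromosomes so that distance chaining at the cluster cutoff recovers
#' exactly the planted clusters; homo-cluster members sharing a tunable
#' fraction of a common direct-target pool; hetero-cluster members with
#' disjoint direct targets whose member-specific TF chains converge on
#' shared terminal genes after `hetero_convergence_step` regulation steps;
#' dense planted modules (a TF clique regulating designated clusters); and
#' sparse random background edges.
#'
#' Planted modules use a fixed geometry derived from the MCODE vertex-weight
#' algebra: `n_tf` TFs forming a clique, with every module gene and every
#' attached miRNA regulated by `n_tf - 2` of them (incoming edges only), so
#' that attachment weights stay within the default expansion threshold of
#' the TF-core weights and the whole module is recovered as one complex.
#' `n_tf >= 7` is required for that guarantee.
#'
#' @param seed integer RNG seed; every random draw of the generator derives
#'   from it.
#' @param n_chromosomes chromosomes to spread loci over.
#' @param homo_clusters list of `list(size =, family =)`; each is one
#'   homo-cluster whose members all carry `family`.
#' @param hetero_clusters list of `list(size =, families =)`; `families`
#'   must have one (distinct) label per member.
#' @param n_isolated_mirna isolated miRNA genes, each its own family.
#' @param intra_cluster_gap_bp gap between consecutive cluster members
#'   (must stay below `cluster_cutoff_bp`).
#' @param inter_locus_gap_bp gap between loci (must exceed the cutoff).
#' @param mirna_length_bp precursor length.
#' @param cluster_cutoff_bp the chaining cutoff the layout is built for.
#' @param homo_target_pool size of each homo-cluster's shared target pool.
#' @param homo_shared_target_fraction fraction of the pool each member
#'   targets (each member draws `round(fraction * pool)` pool genes).
#' @param homo_private_targets private target genes per homo member.
#' @param hetero_convergence_step regulation step at which hetero members'
#'   chains converge (default 3: member -> TF -> TF -> shared terminals).
#' @param hetero_shared_terminal_targets shared terminal genes per
#'   hetero-cluster.
#' @param hetero_private_targets private direct targets per hetero member.
#' @param isolated_targets direct targets per isolated miRNA, drawn from the
#'   background gene pool.
#' @param planted_module_specs list of `list(n_tf =, n_gene =, clusters =)`;
#'   `clusters` holds labels like `"homo1"`, `"hetero2"`.
#' @param n_background_tf,n_background_gene background node pools.
#' @param background_edge_prob probability of each background TF -> node
#'   edge (targets: background genes/TFs and miRNAs only, so planted chains
#'   and modules are never short-circuited).
#' @param null_mode scramble the miRNA labels on the network (a uniform
#'   relabeling), severing every genomic-cluster/network association while
#'   preserving the degree structure.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            n_chromosomes = 3L,
                            homo_clusters = NULL,
                            hetero_clusters = NULL,
                            n_isolated_mirna = 30L,
                            intra_cluster_gap_bp = 2000L,
                            inter_locus_gap_bp = 50000L,
                            mirna_length_bp = 80L,
                            cluster_cutoff_bp = 10000L,
                            homo_target_pool = 20L,
                            homo_shared_target_fraction = 0.9,
                            homo_private_targets = 2L,
                            hetero_convergence_step = 3L,
                            hetero_shared_terminal_targets = 6L,
                            hetero_private_targets = 3L,
                            isolated_targets = 3L,
                            planted_module_specs = NULL,
                            n_background_tf = 15L,
                            n_background_gene = 100L,
                            background_edge_prob = 0.002,
                            null_mode = FALSE) {
  if (missing(seed)) stop("seed is required")
  if (is.null(homo_clusters)) {
    homo_clusters <- lapply(seq_len(5L), function(i) {
      list(size = c(3L, 3L, 3L, 2L, 2L)[i], family = sprintf("mirfam-H%d", i))
    })
  }
  if (is.null(hetero_clusters)) {
    hetero_clusters <- lapply(seq_len(5L), function(i) {
      size <- c(3L, 3L, 3L, 3L, 2L)[i]
      list(size = size, families = sprintf("mirfam-E%d.%d", i, seq_len(size)))
    })
  }
  if (is.null(planted_module_specs)) {
    planted_module_specs <- lapply(
      c(sprintf("homo%d", 1:4), sprintf("hetero%d", 1:4)),
      function(cl) list(n_tf = 7L, n_gene = 4L, clusters = cl)
    )
  }
  cfg <- structure(
    list(
      seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
      homo_clusters = homo_clusters, hetero_clusters = hetero_clusters,
      n_isolated_mirna = as.integer(n_isolated_mirna),
      intra_cluster_gap_bp = as.integer(intra_cluster_gap_bp),
      inter_locus_gap_bp = as.integer(inter_locus_gap_bp),
      mirna_length_bp = as.integer(mirna_length_bp),
      cluster_cutoff_bp = as.integer(cluster_cutoff_bp),
      homo_target_pool = as.integer(homo_target_pool),
      homo_shared_target_fraction = homo_shared_target_fraction,
      homo_private_targets = as.integer(homo_private_targets),
      hetero_convergence_step = as.integer(hetero_convergence_step),
      hetero_shared_terminal_targets = as.integer(hetero_shared_terminal_targets),
      hetero_private_targets = as.integer(hetero_private_targets),
      isolated_targets = as.integer(isolated_targets),
      planted_module_specs = planted_module_specs,
      n_background_tf = as.integer(n_background_tf),
      n_background_gene = as.integer(n_background_gene),
      background_edge_prob = background_edge_prob,
      null_mode = isTRUE(null_mode)
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (n_chromosomes < 1L) config_error("need at least one chromosome")
    if (!(intra_cluster_gap_bp < cluster_cutoff_bp &&
          cluster_cutoff_bp < inter_locus_gap_bp)) {
      config_error("gaps must satisfy intra_cluster_gap_bp < cluster_cutoff_bp ",
                   "< inter_locus_gap_bp")
    }
    if (homo_shared_target_fraction < 0 || homo_shared_target_fraction > 1) {
      config_error("homo_shared_target_fraction must be in [0, 1]")
    }
    if (background_edge_prob < 0 || background_edge_prob > 1) {
      config_error("background_edge_prob must be in [0, 1]")
    }
    if (length(homo_clusters) && homo_shared_target_fraction > 0 &&
        homo_target_pool == 0L) {
      config_error("homo_shared_target_fraction > 0 with an empty target pool")
    }
    if (hetero_convergence_step < 1L) {
      config_error("hetero_convergence_step must be >= 1")
    }
    if (isolated_targets > n_background_gene) {
      config_error("isolated_targets exceeds the background gene pool")
    }
    for (cl in homo_clusters) {
      if (cl$size < 2L) config_error("cluster sizes must be >= 2")
    }
    for (cl in hetero_clusters) {
      if (cl$size < 2L) config_error("cluster sizes must be >= 2")
      if (length(cl$families) != cl$size) {
        config_error("hetero cluster needs one family per member")
      }
      if (anyDuplicated(cl$families)) {
        config_error("hetero cluster families must be distinct")
      }
    }
    labels <- c(sprintf("homo%d", seq_along(homo_clusters)),
                sprintf("hetero%d", seq_along(hetero_clusters)))
    seen <- character(0)
    for (m in planted_module_specs) {
      if (m$n_tf < 7L) {
        config_error("planted modules need n_tf >= 7 (weight-threshold geometry)")
      }
      if (m$n_gene < 1L) config_error("planted modules need n_gene >= 1")
      bad <- setdiff(m$clusters, labels)
      if (length(bad)) config_error("unknown cluster label(s): ",
                                    paste(bad, collapse = ", "))
      if (any(m$clusters %in% seen)) {
        config_error("a cluster may be attached to at most one module")
      }
      seen <- c(seen, m$clusters)
    }
  })
  invisible(cfg)
}

#' Canned scenario configurations
#'
#' * `"default"`: the standard study conditions (see [scenario_config()]
#'   defaults).
#' * `"minimal"`: a 30-node, hand-checkable scenario (one homo pair with a
#'   fully shared pool, one hetero pair, two isolated miRNAs, one planted
#'   module).
#' * `"figure_motif"`: the minimal 3-step convergence motif: one hetero
#'   miRNA pair whose two 2-TF chains converge on a single shared gene, so
#'   TO is 0 at steps 1-2 and positive from step 3.
#' * `"null_calibration"`: a large null-mode scenario (1200 miRNAs, 40
#'   planted modules) sized so that the discrete enrichment count statistic
#'   is fine-grained enough for p-value uniformity checks.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = c("default", "minimal", "figure_motif",
                                     "null_calibration"),
                            seed) {
  name <- match.arg(name)
  switch(name,
    default = scenario_config(seed = seed),
    minimal = scenario_config(
      seed = seed, n_chromosomes = 2L,
      homo_clusters = list(list(size = 2L, family = "mirfam-H1")),
      hetero_clusters = list(list(size = 2L,
                                  families = c("mirfam-E1.1", "mirfam-E1.2"))),
      n_isolated_mirna = 2L,
      homo_target_pool = 4L, homo_shared_target_fraction = 1,
      homo_private_targets = 0L,
      hetero_shared_terminal_targets = 1L, hetero_private_targets = 1L,
      isolated_targets = 2L,
      planted_module_specs = list(list(n_tf = 7L, n_gene = 2L,
                                       clusters = "homo1")),
      n_background_tf = 0L, n_background_gene = 4L,
      background_edge_prob = 0
    ),
    figure_motif = scenario_config(
      seed = seed, n_chromosomes = 1L,
      homo_clusters = list(),
      hetero_clusters = list(list(size = 2L,
                                  families = c("mirfam-E1.1", "mirfam-E1.2"))),
      n_isolated_mirna = 0L,
      hetero_convergence_step = 3L,
      hetero_shared_terminal_targets = 1L, hetero_private_targets = 0L,
      isolated_targets = 0L,
      planted_module_specs = list(),
      n_background_tf = 0L, n_background_gene = 0L,
      background_edge_prob = 0
    ),
    null_calibration = scenario_config(
      seed = seed, n_chromosomes = 8L,
      homo_clusters = lapply(seq_len(150L), function(i) {
        list(size = 4L, family = sprintf("mirfam-H%d", i))
      }),
      hetero_clusters = lapply(seq_len(90L), function(i) {
        list(size = 4L, families = sprintf("mirfam-E%d.%d", i, 1:4))
      }),
      n_isolated_mirna = 240L,
      homo_target_pool = 4L, homo_shared_target_fraction = 0.75,
      homo_private_targets = 0L,
      hetero_shared_terminal_targets = 3L, hetero_private_targets = 1L,
      isolated_targets = 3L,
      planted_module_specs = c(
        lapply(seq_len(20L), function(j) {
          list(n_tf = 7L, n_gene = 4L,
               clusters = sprintf("homo%d", c(2L * j - 1L, 2L * j)))
        }),
        lapply(seq_len(20L), function(j) {
          list(n_tf = 7L, n_gene = 4L,
               clusters = sprintf("hetero%d", c(2L * j - 1L, 2L * j)))
        })
      ),
      n_background_tf = 20L, n_background_gene = 120L,
      background_edge_prob = 0.001,
      null_mode = TRUE
    )
  )
}

#' Generate a synthetic scenario
#'
#' Builds the annotation, family table, regulatory network, TF list and
#' ground-truth record described by a [scenario_config()], optionally
#' writing them to disk (GFF3 + TSV + SIF + TF list + JSON manifest). The
#' generator is deterministic given `config$seed`.
#'
#' @param config a `scenario_config`.
#' @param out_dir optional directory; created if needed.
#' @return object of class `mirna_scenario`: list with `config`,
#'   `annotation` (a `mirna_annotation`), `network`
#'   (a `regulatory_network`), `tf_ids`, `ground_truth` and (when written)
#'   `paths`.
#' @export
generate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  scen <- withr::with_seed(config$seed, build_scenario(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      annotation = file.path(out_dir, "annotation.gff3"),
      family_table = file.path(out_dir, "families.tsv"),
      sif = file.path(out_dir, "network.sif"),
      tf_list = file.path(out_dir, "tf_list.txt"),
      ground_truth = file.path(out_dir, "ground_truth.json")
    )
    write_mirna_gff3(scen$annotation, paths$annotation)
    write_family_table(scen$annotation, paths$family_table)
    write_sif(scen$network, paths$sif)
    writeLines(sort(scen$tf_ids), paths$tf_list)
    jsonlite::write_json(scen$ground_truth, paths$ground_truth,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    scen$paths <- paths
  }
  scen
}

build_scenario <- function(config) {
  clusters <- c(
    lapply(seq_along(config$homo_clusters), function(i) {
      cl <- config$homo_clusters[[i]]
      list(label = sprintf("homo%d", i), type = "homo", size = cl$size,
           families = rep(cl$family, cl$size))
    }),
    lapply(seq_along(config$hetero_clusters), function(i) {
      cl <- config$hetero_clusters[[i]]
      list(label = sprintf("hetero%d", i), type = "hetero", size = cl$size,
           families = cl$families)
    })
  )
  n_clustered <- sum(vapply(clusters, `[[`, 0L, "size"))
  n_mirna <- n_clustered + config$n_isolated_mirna
  mirna_ids <- sprintf("hsa-mir-SYN%04d", seq_len(n_mirna))

  # --- genomic layout ------------------------------------------------------
  # loci (clusters, then isolated genes) round-robin over chromosomes;
  # intra-locus gaps sit below the cutoff, inter-locus gaps above it, so the
  # chaining caller recovers exactly the planted partition
  ann <- data.frame(id = mirna_ids, chrom = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = "+", family = NA_character_,
                    stringsAsFactors = FALSE)
  locus_sizes <- c(vapply(clusters, `[[`, 0L, "size"),
                   rep(1L, config$n_isolated_mirna))
  cursor <- rep(10000L, config$n_chromosomes)
  gene_idx <- 1L
  for (j in seq_along(locus_sizes)) {
    chrom <- ((j - 1L) %% config$n_chromosomes) + 1L
    pos <- cursor[chrom]
    for (k in seq_len(locus_sizes[j])) {
      ann$chrom[gene_idx] <- sprintf("chr%d", chrom)
      ann$start[gene_idx] <- pos
      ann$end[gene_idx] <- pos + config$mirna_length_bp
      pos <- pos + config$mirna_length_bp + config$intra_cluster_gap_bp
      gene_idx <- gene_idx + 1L
    }
    cursor[chrom] <- pos - config$intra_cluster_gap_bp + config$inter_locus_gap_bp
  }
  member_ids <- list()
  offset <- 0L
  for (cl in clusters) {
    idx <- offset + seq_len(cl$size)
    member_ids[[cl$label]] <- mirna_ids[idx]
    ann$family[idx] <- cl$families
    offset <- offset + cl$size
  }
  isolated_ids <- mirna_ids[offset + seq_len(config$n_isolated_mirna)]
  ann$family[ann$id %in% isolated_ids] <-
    sprintf("mirfam-I%04d", seq_len(config$n_isolated_mirna))

  # --- nodes and edges -----------------------------------------------------
  src <- list(); dst <- list()
  add_edges <- function(s, t) {
    src[[length(src) + 1L]] <<- s
    dst[[length(dst) + 1L]] <<- t
  }
  tf_ids <- character(0)
  gene_ids <- character(0)

  # homo clusters: members draw round(f * pool) genes from a shared pool,
  # plus dedicated private targets
  for (i in seq_along(config$homo_clusters)) {
    lab <- sprintf("homo%d", i)
    members <- member_ids[[lab]]
    pool <- sprintf("GP-H%d-%03d", i, seq_len(config$homo_target_pool))
    gene_ids <- c(gene_ids, pool)
    m <- round(config$homo_shared_target_fraction * config$homo_target_pool)
    for (mm in members) {
      if (m > 0L) add_edges(rep(mm, m), sample(pool, m))
      if (config$homo_private_targets > 0L) {
        priv <- sprintf("GV-%s-%d", sub("^hsa-mir-", "", mm),
                        seq_len(config$homo_private_targets))
        gene_ids <- c(gene_ids, priv)
        add_edges(rep(mm, length(priv)), priv)
      }
    }
  }

  # hetero clusters: member-specific TF chains of length step-1 converging
  # on shared terminal genes, plus disjoint private direct targets
  s <- config$hetero_convergence_step
  for (i in seq_along(config$hetero_clusters)) {
    lab <- sprintf("hetero%d", i)
    members <- member_ids[[lab]]
    terminals <- if (config$hetero_shared_terminal_targets > 0L) {
      sprintf("GT-E%d-%02d", i, seq_len(config$hetero_shared_terminal_targets))
    } else character(0)
    gene_ids <- c(gene_ids, terminals)
    for (mm in members) {
      suffix <- sub("^hsa-mir-", "", mm)
      if (s == 1L) {
        if (length(terminals)) add_edges(rep(mm, length(terminals)), terminals)
      } else {
        chain <- sprintf("TFC-%s-%d", suffix, seq_len(s - 1L))
        tf_ids <- c(tf_ids, chain)
        add_edges(c(mm, chain[-length(chain)]), chain)
        if (length(terminals)) {
          add_edges(rep(chain[length(chain)], length(terminals)), terminals)
        }
      }
      if (config$hetero_private_targets > 0L) {
        priv <- sprintf("GV-%s-%d", suffix,
                        seq_len(config$hetero_private_targets))
        gene_ids <- c(gene_ids, priv)
        add_edges(rep(mm, length(priv)), priv)
      }
    }
  }

  # background pools; isolated miRNAs target background genes
  bg_genes <- if (config$n_background_gene > 0L) {
    sprintf("GB%04d", seq_len(config$n_background_gene))
  } else character(0)
  bg_tfs <- if (config$n_background_tf > 0L) {
    sprintf("TFB%03d", seq_len(config$n_background_tf))
  } else character(0)
  gene_ids <- c(gene_ids, bg_genes)
  tf_ids <- c(tf_ids, bg_tfs)
  for (mm in isolated_ids) {
    if (config$isolated_targets > 0L) {
      add_edges(rep(mm, config$isolated_targets),
                sample(bg_genes, config$isolated_targets))
    }
  }

  # planted modules: K(n_tf) TF clique; each module gene and each attached
  # cluster miRNA regulated by n_tf-2 of the TFs (incoming edges only)
  true_modules <- list()
  for (mi in seq_along(config$planted_module_specs)) {
    spec <- config$planted_module_specs[[mi]]
    tfs <- sprintf("TFM%02d-%d", mi, seq_len(spec$n_tf))
    genes <- sprintf("GM%02d-%d", mi, seq_len(spec$n_gene))
    tf_ids <- c(tf_ids, tfs)
    gene_ids <- c(gene_ids, genes)
    pairs <- combn(spec$n_tf, 2L)
    add_edges(tfs[pairs[1L, ]], tfs[pairs[2L, ]])
    attach_deg <- spec$n_tf - 2L
    attached <- unlist(member_ids[spec$clusters], use.names = FALSE)
    nodes <- c(genes, attached)
    for (j in seq_along(nodes)) {
      reg <- tfs[((j - 1L + seq_len(attach_deg) - 1L) %% spec$n_tf) + 1L]
      add_edges(reg, rep(nodes[j], attach_deg))
    }
    true_modules[[mi]] <- list(module = mi, clusters = spec$clusters,
                               nodes = c(tfs, genes, attached))
  }

  # background regulation: background TFs -> {background genes/TFs, miRNAs};
  # planted chain TFs, terminals, pools and module nodes are excluded from
  # the candidate set so planted path lengths are never short-circuited
  if (length(bg_tfs) && config$background_edge_prob > 0) {
    candidates <- c(bg_genes, bg_tfs, mirna_ids)
    for (tf in bg_tfs) {
      pick <- candidates[stats::runif(length(candidates)) < config$background_edge_prob]
      pick <- setdiff(pick, tf)
      if (length(pick)) add_edges(rep(tf, length(pick)), pick)
    }
  }

  edges <- data.frame(source = unlist(src, use.names = FALSE) %||% character(0),
                      target = unlist(dst, use.names = FALSE) %||% character(0),
                      stringsAsFactors = FALSE)

  # null mode: uniform relabeling of miRNA ids on the network only
  relabel <- setNames(mirna_ids, mirna_ids)
  if (config$null_mode && n_mirna > 1L) {
    relabel <- setNames(sample(mirna_ids), mirna_ids)
    hit_s <- edges$source %in% mirna_ids
    hit_t <- edges$target %in% mirna_ids
    edges$source[hit_s] <- unname(relabel[edges$source[hit_s]])
    edges$target[hit_t] <- unname(relabel[edges$target[hit_t]])
    for (mi in seq_along(true_modules)) {
      nd <- true_modules[[mi]]$nodes
      hit <- nd %in% mirna_ids
      nd[hit] <- unname(relabel[nd[hit]])
      true_modules[[mi]]$nodes <- nd
    }
  }

  node_types <- c(
    setNames(rep("TF", length(tf_ids)), tf_ids),
    setNames(rep("miRNA", n_mirna), mirna_ids),
    setNames(rep("gene", length(gene_ids)), gene_ids)
  )
  network <- regulatory_network(edges, node_types = node_types)

  m_shared <- round(config$homo_shared_target_fraction * config$homo_target_pool)
  expected_direct_overlap <- if (length(config$homo_clusters)) {
    # E[shared] of two independent m-subsets of a P pool is m^2/P
    (m_shared^2 / max(config$homo_target_pool, 1L)) /
      (m_shared + config$homo_private_targets + 1)
  } else NA_real_

  ground_truth <- list(
    seed = config$seed,
    null_mode = config$null_mode,
    n_mirna = n_mirna,
    true_clusters = lapply(clusters, function(cl) {
      list(cluster = cl$label, type = cl$type,
           members = member_ids[[cl$label]], families = cl$families)
    }),
    isolated = isolated_ids,
    true_module_members = true_modules,
    hetero_convergence_step = config$hetero_convergence_step,
    expected_direct_overlap = expected_direct_overlap,
    mirna_relabeling = if (config$null_mode) as.list(relabel) else NULL
  )

  structure(
    list(config = config, annotation = as_mirna_annotation(ann),
         network = network, tf_ids = sort(tf_ids),
         ground_truth = ground_truth, paths = NULL),
    class = "mirna_scenario"
  )
}

#' @export
print.mirna_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic scenario (seed %d%s): %d miRNA genes (%d clusters planted), %d-node network\n",
    x$config$seed, if (x$config$null_mode) ", null mode" else "",
    nrow(x$annotation), length(x$ground_truth$true_clusters),
    igraph::vcount(x$network$graph)
  ))
  invisible(x)
}

#' Write a suite of canned fixtures
#'
#' Emits the `minimal`, `figure_motif` and `null` scenarios under `out_dir`
#' (one subdirectory each) together with a `manifest.json` listing the seeds
#' and the summary values the constructions guarantee.
#'
#' @param out_dir destination directory.
#' @param seed base seed; the three scenarios use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return invisibly, the manifest as a list.
#' @export
fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scens <- list(
    minimal = scenario_preset("minimal", seed = seed),
    figure_motif = scenario_preset("figure_motif", seed = seed + 1L),
    null = scenario_config(seed = seed + 2L, null_mode = TRUE)
  )
  manifest <- list()
  for (nm in names(scens)) {
    scen <- generate_scenario(scens[[nm]], out_dir = file.path(out_dir, nm))
    manifest[[nm]] <- list(
      seed = scen$config$seed,
      null_mode = scen$config$null_mode,
      n_mirna = nrow(scen$annotation),
      n_clusters_expected = length(scen$ground_truth$true_clusters),
      n_isolated_expected = length(scen$ground_truth$isolated),
      hetero_convergence_step = scen$config$hetero_convergence_step,
      expected_direct_overlap = scen$ground_truth$expected_direct_overlap
    )
  }
  # the figure motif guarantees TO = 0 below the convergence step and
  # 1 / (steps - 1 + terminals + 1) at it: two 2-TF chains + 1 shared gene
  manifest$figure_motif$expected_to_by_step <- list(
    step1 = 0, step2 = 0,
    step3 = 1 / ((scens$figure_motif$hetero_convergence_step - 1L) +
                   scens$figure_motif$hetero_shared_terminal_targets + 1L)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
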