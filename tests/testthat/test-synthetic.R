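test_that("cluster calling recovers the planted partition exactly, across configs", {
  withr::with_seed(51, {
    for (rep in 1:12) {
      n_homo <- sample(0:4, 1)
      n_het <- sample(1:4, 1)
      cfg <- scenario_config(
        seed = 600 + rep,
        n_chromosomes = sample(1:4, 1),
        homo_clusters = lapply(seq_len(n_homo), function(i) {
          list(size = sample(2:5, 1), family = sprintf("mirfam-H%d", i))
        }),
        hetero_clusters = lapply(seq_len(n_het), function(i) {
          size <- sample(2:5, 1)
          list(size = size, families = sprintf("mirfam-E%d.%d", i, seq_len(size)))
        }),
        n_isolated_mirna = sample(0:10, 1),
        intra_cluster_gap_bp = sample(c(500L, 2000L, 9000L), 1),
        inter_locus_gap_bp = sample(c(20000L, 50000L), 1),
        planted_module_specs = list()
      )
      scen <- generate_scenario(cfg)
      cc <- detect_clusters(scen$annotation, cutoff_bp = cfg$cluster_cutoff_bp)
      truth <- scen$ground_truth$true_clusters
      expect_equal(nrow(cc$clusters), length(truth))
      got <- lapply(cc$members, sort)
      want <- lapply(truth, function(x) sort(x$members))
      key <- function(sets) sort(unname(vapply(sets, paste, "", collapse = "|")))
      expect_equal(key(got), key(want))
      types <- setNames(cc$clusters$cluster_type,
                        vapply(cc$members, `[[`, "", 1))
      for (tr in truth) {
        expect_equal(unname(types[tr$members[1]]), tr$type)
      }
      expect_setequal(cc$isolated$id, scen$ground_truth$isolated)
    }
  })
})

test_that("the 3-step convergence motif yields zero overlap before step 3", {
  scen <- generate_scenario(scenario_preset("figure_motif", seed = 77))
  cc <- detect_clusters(scen$annotation)
  pairs <- category_pairs(cc, scen$network)
  expect_equal(nrow(pairs$hetero), 1L)
  to_at <- function(k) {
    target_overlap_table(scen$network, pairs$hetero, steps = k)$to
  }
  expect_equal(to_at(1), 0)
  expect_equal(to_at(2), 0)
  expect_equal(to_at(3), 0.25)  # 1 shared terminal / (2 chain TFs + 1 + 1)
  expect_equal(target_overlap_table(scen$network, pairs$hetero,
                                    steps = "closure")$to, 0.25)
})

test_that("hetero members share nothing below the convergence step and plenty at it", {
  scen <- generate_scenario(scenario_config(seed = 88))
  cc <- detect_clusters(scen$annotation)
  pairs <- category_pairs(cc, scen$network)
  s <- scen$config$hetero_convergence_step
  below <- target_overlap_table(scen$network, pairs$hetero, steps = s - 1)
  at <- target_overlap_table(scen$network, pairs$hetero, steps = s)
  expect_true(all(below$shared == 0))
  expect_true(all(at$shared >= scen$config$hetero_shared_terminal_targets))
})

test_that("planted homo overlap matches its analytic expectation across seeds", {
  means <- vapply(1:20, function(i) {
    scen <- generate_scenario(scenario_config(seed = 700 + i))
    cc <- detect_clusters(scen$annotation)
    pairs <- category_pairs(cc, scen$network)
    mean(target_overlap_table(scen$network, pairs$homo, steps = 1)$to)
  }, numeric(1))
  expected <- generate_scenario(
    scenario_config(seed = 1)
  )$ground_truth$expected_direct_overlap
  expect_lt(abs(mean(means) - expected), 0.05)
})

test_that("scenario files are byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_scenario(scenario_config(seed = 5), out_dir = d1)
  generate_scenario(scenario_config(seed = 5), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  generate_scenario(scenario_config(seed = 6), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "network.sif")),
                         readLines(file.path(d3, "network.sif"))))
})

test_that("emitted files round-trip through the readers", {
  dir <- withr::local_tempdir()
  scen <- generate_scenario(scenario_preset("minimal", seed = 11),
                            out_dir = dir)
  ann <- read_mirna_annotations(file.path(dir, "annotation.gff3"),
                                family_table = file.path(dir, "families.tsv"))
  expect_equal(nrow(ann), nrow(scen$annotation))
  expect_false(anyNA(ann$family))
  net <- read_sif(file.path(dir, "network.sif"),
                  tf_list = file.path(dir, "tf_list.txt"))
  expect_equal(igraph::ecount(net$graph), igraph::ecount(scen$network$graph))
  expect_setequal(mircoord:::network_node_ids(net, "TF"), scen$tf_ids)
  # in-memory and re-read networks agree on a target profile
  m <- mircoord:::network_node_ids(net, "miRNA")[1]
  expect_setequal(k_step_targets(net, m, "closure")$targets,
                  k_step_targets(scen$network, m, "closure")$targets)
})

test_that("null mode scrambles cluster/network associations but keeps structure", {
  plain <- generate_scenario(scenario_config(seed = 12))
  null <- generate_scenario(scenario_config(seed = 12, null_mode = TRUE))
  expect_equal(igraph::ecount(null$network$graph),
               igraph::ecount(plain$network$graph))
  expect_identical(null$annotation, plain$annotation)
  # degree multiset of miRNA nodes is preserved by the relabeling
  deg <- function(s) sort(igraph::degree(
    s$network$graph, mircoord:::network_node_ids(s$network, "miRNA")
  ))
  expect_equal(unname(deg(null)), unname(deg(plain)))
  expect_false(is.null(null$ground_truth$mirna_relabeling))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(scenario_config(seed = 1, intra_cluster_gap_bp = 20000L),
               "intra_cluster_gap_bp")
  expect_error(scenario_config(seed = 1, homo_target_pool = 0L),
               "empty target pool")
  expect_error(scenario_config(seed = 1, hetero_clusters = list(
    list(size = 3L, families = c("a", "b"))
  )), "one family per member")
  expect_error(scenario_config(seed = 1, planted_module_specs = list(
    list(n_tf = 4L, n_gene = 2L, clusters = "homo1")
  )), "n_tf >= 7")
  expect_error(scenario_config(seed = 1, planted_module_specs = list(
    list(n_tf = 7L, n_gene = 2L, clusters = "homo9")
  )), "unknown cluster")
})

test_that("the fixture suite writes manifests consistent with its scenarios", {
  dir <- withr::local_tempdir()
  manifest <- fixture_suite(dir, seed = 31)
  expect_setequal(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                  c("minimal", "figure_motif", "null"))
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(m$figure_motif$expected_to_by_step$step3, 0.25)
  ann <- read_mirna_annotations(file.path(dir, "minimal", "annotation.gff3"))
  expect_equal(nrow(ann), m$minimal$n_mirna)
  cc <- detect_clusters(ann)
  expect_equal(nrow(cc$clusters), m$minimal$n_clusters_expected)
})
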