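test_that("SIF typing precedence: TF list, then miRNA prefix, then gene", {
  path <- write_tmp_sif(c(
    "TP53 regulates hsa-mir-34a",
    "hsa-mir-17 represses E2F1",
    "E2F1 regulates CCNE1"
  ))
  net <- read_sif(path, tf_list = c("TP53", "E2F1"))
  g <- net$graph
  types <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_equal(types[["TP53"]], "TF")
  expect_equal(types[["E2F1"]], "TF")
  expect_equal(types[["hsa-mir-34a"]], "miRNA")
  expect_equal(types[["hsa-mir-17"]], "miRNA")
  expect_equal(types[["CCNE1"]], "gene")
})

test_that("duplicate SIF lines collapse and self-loops are dropped with counts", {
  path <- write_tmp_sif(c(
    "t1 regulates g1",
    "t1 regulates g1",
    "t1\tregulates\tt1"
  ))
  net <- read_sif(path, tf_list = "t1")
  expect_equal(igraph::ecount(net$graph), 1L)
  expect_equal(net$n_duplicate_edges, 1L)
  expect_equal(net$n_self_loops, 1L)
})

test_that("SIF parsing reports the offending line and expands multi-target lines", {
  path <- write_tmp_sif(c("a regulates b", "broken_line_with two"))
  expect_error(read_sif(path), "line 2")
  multi <- write_tmp_sif("t1\tregulates\tg1\tg2\tg3")
  net <- read_sif(multi, tf_list = "t1")
  expect_equal(igraph::ecount(net$graph), 3L)
  # a gene source triggers a validation warning, escalatable to error
  bad <- write_tmp_sif("g1 regulates g2")
  expect_warning(read_sif(bad), "outgoing")
  expect_error(read_sif(bad, strict = TRUE), "outgoing")
})

test_that("SIF writing is deterministic and round-trips nodes and edges", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      edges <- random_edge_list(12, 0.15, seed = rep)
      net <- regulatory_network(edges, node_types = setNames(
        rep("TF", 12), sprintf("n%02d", 1:12)
      ))
      dir <- withr::local_tempdir()
      p1 <- file.path(dir, "a.sif"); p2 <- file.path(dir, "b.sif")
      write_sif(net, p1)
      back <- read_sif(p1, tf_list = sprintf("n%02d", 1:12))
      write_sif(back, p2)
      expect_identical(readLines(p1), readLines(p2))
      ed <- function(n) {
        df <- igraph::as_data_frame(n$graph)
        df[order(df$from, df$to), c("from", "to")]
      }
      expect_equal(ed(back), ed(net), ignore_attr = TRUE)
    }
  })
  # isolated nodes come back as single-field lines
  net <- regulatory_network(edge_df("t1", "g1"),
                            node_types = c(t1 = "TF", lonely = "gene"))
  dir <- withr::local_tempdir()
  write_sif(net, file.path(dir, "iso.sif"))
  expect_true("lonely" %in% readLines(file.path(dir, "iso.sif")))
  back <- read_sif(file.path(dir, "iso.sif"), tf_list = "t1")
  expect_true("lonely" %in% igraph::V(back$graph)$name)
  # empty network writes an empty file
  empty <- regulatory_network(edge_df()[0, ])
  write_sif(empty, file.path(dir, "empty.sif"))
  expect_length(readLines(file.path(dir, "empty.sif")), 0L)
})

test_that("k-step targets follow the worked chain and cycle examples", {
  net <- toy_network(edge_df(
    "hsa-mir-m", "t1", "t1", "t2", "t2", "g1"
  ))
  expect_setequal(k_step_targets(net, "hsa-mir-m", 1)$targets, "t1")
  expect_setequal(k_step_targets(net, "hsa-mir-m", 3)$targets,
                  c("t1", "t2", "g1"))
  # no outgoing edges: empty profile with l = 0
  net2 <- toy_network(edge_df("t1", "hsa-mir-m"))
  p <- k_step_targets(net2, "hsa-mir-m", 2)
  expect_equal(p$l, 0L)
  # cycle: closure terminates and excludes the source
  net3 <- toy_network(edge_df("hsa-mir-m", "t1", "t1", "hsa-mir-m", "t1", "g1"))
  pc <- k_step_targets(net3, "hsa-mir-m", "closure")
  expect_setequal(pc$targets, c("t1", "g1"))
})

test_that("reachable sets nest in k and closure equals deep k", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      edges <- random_edge_list(15, 0.12, seed = 100 + rep)
      ids <- sprintf("n%02d", 1:15)
      net <- regulatory_network(edges, node_types = setNames(
        rep(c("miRNA", "TF"), c(5, 10)), ids
      ))
      for (m in intersect(ids[1:5], igraph::V(net$graph)$name)) {
        prev <- character(0)
        for (k in 1:6) {
          cur <- target_profiles(net, m, steps = k)[[1]]$targets
          expect_true(all(prev %in% cur))
          prev <- cur
        }
        clo <- target_profiles(net, m, steps = "closure")[[1]]$targets
        deep <- target_profiles(net, m, steps = 20)[[1]]$targets
        expect_setequal(clo, deep)
      }
    }
  })
})

test_that("k-step targets agree with the matrix-power oracle on random graphs", {
  withr::with_seed(23, {
    for (rep in 1:30) {
      n <- sample(5:25, 1)
      edges <- random_edge_list(n, runif(1, 0.05, 0.25), seed = 300 + rep)
      ids <- sprintf("n%02d", 1:n)
      net <- regulatory_network(edges,
                                node_types = setNames(rep("miRNA", n), ids))
      m <- sample(ids, 1)
      k <- sample(1:6, 1)
      got <- sort(target_profiles(net, m, steps = k)[[1]]$targets)
      ref <- oracle_reachable(
        igraph::as_data_frame(net$graph)[, c("from", "to")] |>
          setNames(c("source", "target")),
        igraph::V(net$graph)$name, m, k
      )
      expect_identical(got, ref)
    }
  })
})

test_that("duplicate edges and self-loops do not change reachability", {
  base <- edge_df("hsa-mir-m", "t1", "t1", "g1")
  noisy <- rbind(base, edge_df("hsa-mir-m", "t1", "t1", "t1"))
  a <- k_step_targets(toy_network(base), "hsa-mir-m", "closure")
  b <- k_step_targets(toy_network(noisy), "hsa-mir-m", "closure")
  expect_setequal(a$targets, b$targets)
})

test_that("profile requests validate ids, types and the universe switch", {
  net <- toy_network(edge_df("hsa-mir-m", "t1", "t1", "g1", "t1", "t2"))
  expect_error(k_step_targets(net, "nope", 1), "unknown")
  expect_error(k_step_targets(net, "t1", 1), "not miRNA")
  expect_error(k_step_targets(net, "hsa-mir-m", 0), "steps")
  all_t <- k_step_targets(net, "hsa-mir-m", "closure")
  gene_t <- k_step_targets(net, "hsa-mir-m", "closure", universe = "gene_only")
  expect_setequal(all_t$targets, c("t1", "t2", "g1"))
  expect_setequal(gene_t$targets, "g1")
  # universe size: nodes with incoming edges, source excluded
  expect_equal(all_t$universe_size, 3L)
})

test_that("network validation reports counts and gene-source violations", {
  net <- toy_network(edge_df("t1", "g1", "t2", "hsa-mir-a", "hsa-mir-a", "g2",
                             "t1", "t2", "t3", "g3"))
  rep <- validate_network(net)
  expect_equal(rep$n_tf, 3L)
  expect_equal(rep$n_mirna, 1L)
  expect_equal(rep$n_gene, 3L)
  expect_equal(rep$n_violations, 0L)
  bad <- regulatory_network(edge_df("g1", "g2"),
                            node_types = c(g1 = "gene", g2 = "gene"))
  expect_equal(validate_network(bad)$genes_with_out_edges, "g1")
})

test_that("the id heuristic strips arm suffixes and case-folds miR", {
  expect_equal(map_mirna_ids(c("hsa-miR-17-5p", "hsa-mir-18a", "hsa-miR-19b-3p")),
               c("hsa-mir-17", "hsa-mir-18a", "hsa-mir-19b"))
  map <- data.frame(from = "weird-id", to = "hsa-mir-1")
  expect_equal(map_mirna_ids(c("weird-id", "other"), map = map),
               c("hsa-mir-1", "other"))
})
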