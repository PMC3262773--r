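test_that("random clusters preserve the size multiset and each miRNA exactly once", {
  ids <- sprintf("hsa-mir-%02d", 1:6)
  rs <- generate_random_clusters(ids, c(3L, 2L, 1L), B = 25, seed = 9)
  for (b in 1:25) {
    groups <- random_cluster_set(rs, b)
    expect_equal(lengths(groups), c(3L, 2L, 1L))
    expect_setequal(unlist(groups), ids)
  }
  # identical seeds give identical replicates
  rs2 <- generate_random_clusters(ids, c(3L, 2L, 1L), B = 25, seed = 9)
  expect_identical(rs$perms, rs2$perms)
  expect_error(generate_random_clusters(ids[1:4], c(3L, 2L, 1L), B = 2, seed = 1),
               "size mismatch")
})

test_that("random-cluster membership frequencies match the exact expectation", {
  ids <- sprintf("hsa-mir-%02d", 1:6)
  rs <- generate_random_clusters(ids, c(3L, 2L, 1L), B = 1000, seed = 21)
  in_big <- sapply(ids, function(id) {
    mean(vapply(1:1000, function(b) id %in% random_cluster_set(rs, b)[[1]],
                logical(1)))
  })
  # hypergeometric expectation: 3 of 6 slots
  expect_true(all(abs(in_big - 0.5) < 0.05))
})

test_that("module membership permutation draws the right counts without reuse", {
  ids <- sprintf("hsa-mir-%02d", 1:5)
  mp <- module_membership_permutation(c(2L, 1L), ids, B = 50, seed = 4)
  for (b in 1:50) {
    draw <- mp$draws[[b]]
    expect_equal(lengths(draw), c(2L, 1L))
    expect_equal(anyDuplicated(unlist(draw)), 0L)
  }
  # zero counts give empty draws
  mp0 <- module_membership_permutation(c(0L, 0L), ids, B = 2, seed = 4)
  expect_equal(lengths(mp0$draws[[1]]), c(0L, 0L))
  # inclusion frequency matches the without-replacement expectation 3/5
  mp2 <- module_membership_permutation(c(2L, 1L), ids, B = 1000, seed = 6)
  freq <- sapply(ids, function(id) {
    mean(vapply(mp2$draws, function(d) id %in% unlist(d), logical(1)))
  })
  expect_true(all(abs(freq - 3 / 5) < 0.05))
  expect_error(module_membership_permutation(c(4L, 3L), ids, B = 1, seed = 1),
               "exceed")
})

test_that("the empirical estimator is never zero and hits its boundary", {
  et <- empirical_test(10, rep(0, 1000), direction = "greater")
  expect_equal(et$p_value, 1 / 1001)
  et2 <- empirical_test(-5, rnorm(200), direction = "greater", seed = 1)
  expect_gt(et2$p_value, 0.5)
  expect_true(et$p_value > 0)
  expect_error(empirical_test(1, numeric(0)), "empty")
})

test_that("module cluster entropy follows its closed form and edge rules", {
  assign <- c(m1 = "c1", m2 = "c1", m3 = "c1", m4 = "c2", m5 = "c3",
              iso = NA)
  expect_equal(module_cluster_entropy(c("m1", "m2", "m3"), assign)$e_c, 0)
  expect_equal(module_cluster_entropy(c("m1", "m4", "m5"), assign)$e_c, 1)
  e <- module_cluster_entropy(c("m1", "m2", "m4"), assign)
  expect_equal(e$e_c, 0.9182958, tolerance = 1e-6)
  expect_equal(e$n_c, 2L)
  expect_equal(sum(e$cluster_probs), 1)
  # isolated members do not enter the composition
  expect_equal(module_cluster_entropy(c("m1", "m2", "iso"), assign)$e_c, 0)
  expect_error(module_cluster_entropy(c("iso"), assign), "no clustered")
})

test_that("enrichment and entropy tests recover planted module structure", {
  scen <- generate_scenario(scenario_config(seed = 314))
  cc <- detect_clusters(scen$annotation)
  mods <- mcode(scen$network)
  enr <- clustered_mirna_enrichment(mods, cc, scen$network, B = 199, seed = 41)
  expect_lt(enr$homo$p_value, 0.05)
  expect_lt(enr$hetero$p_value, 0.05)
  expect_equal(enr$homo$B, 199L)
  # determinism
  enr2 <- clustered_mirna_enrichment(mods, cc, scen$network, B = 199, seed = 41)
  expect_identical(enr$homo$p_value, enr2$homo$p_value)

  rs <- generate_random_clusters(cc$genes$id, cc, B = 199, seed = 42)
  ent <- entropy_null_test(mods, cc, scen$network, rs)
  expect_equal(ent$observed, 0)  # planted modules draw on single clusters
  expect_lt(ent$p_value, 0.05)
  # fast path equals the reference per-module average on a subsample
  mm <- mircoord:::module_mirnas(mods, scen$network)
  ref <- vapply(1:20, function(b) {
    mircoord:::avg_module_entropy(mm, mircoord:::random_set_assignment(rs, b))
  }, numeric(1))
  expect_equal(ent$null_values[1:20], ref, tolerance = 1e-12)
})

test_that("the TO label-permutation contrast behaves at its boundaries", {
  tc <- to_contrast_test(rep(0.9, 10), rep(0, 10), B = 1000, seed = 5)
  expect_equal(tc$p_value, 1 / 1001)
  # same seed, same p
  tc2 <- to_contrast_test(rep(0.9, 10), rep(0, 10), B = 1000, seed = 5)
  expect_identical(tc$p_value, tc2$p_value)
  # no separation: p well above any significance floor
  withr::with_seed(8, {
    x <- runif(40, 0, 0.5)
    tc3 <- to_contrast_test(x[1:20], x[21:40], B = 500, seed = 6)
    expect_gt(tc3$p_value, 0.05)
  })
  df <- data.frame(mirna_i = c("a", "b"), mirna_j = c("c", "d"),
                   to = c(0.1, 0.2))
  expect_error(to_contrast_test(df, df), "identical")
  expect_error(to_contrast_test(numeric(0), 1, B = 10, seed = 1), "non-empty")
})

test_that("null-mode scenarios leave all three tests non-significant", {
  n_sig <- c(enr_homo = 0L, enr_hetero = 0L, entropy = 0L, to = 0L)
  n_seeds <- 20L
  for (i in seq_len(n_seeds)) {
    s <- 9000L + i
    scen <- generate_scenario(scenario_config(seed = s, null_mode = TRUE))
    cc <- detect_clusters(scen$annotation)
    mods <- mcode(scen$network)
    enr <- clustered_mirna_enrichment(mods, cc, scen$network, B = 199,
                                      seed = s + 1L)
    rs <- generate_random_clusters(cc$genes$id, cc, B = 199, seed = s + 2L)
    ent <- entropy_null_test(mods, cc, scen$network, rs)
    rs1 <- generate_random_clusters(cc$genes$id, cc, B = 5, seed = s + 3L)
    pairs <- category_pairs(cc, scen$network, random_sets = rs1)
    het <- target_overlap_table(scen$network, pairs$hetero, steps = "closure")
    rnd <- target_overlap_table(scen$network,
                                pairs$random[, c("mirna_i", "mirna_j")],
                                steps = "closure")
    tc <- to_contrast_test(het, rnd, B = 199, seed = s + 4L)
    n_sig <- n_sig + c(enr$homo$p_value <= 0.01, enr$hetero$p_value <= 0.01,
                       ent$p_value <= 0.01, tc$p_value <= 0.01)
  }
  # scrambled labels: significant calls at the 1% level stay rare
  expect_true(all(n_sig <= 2L))
})
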