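#' Empirical permutation test result
#'
#' Wraps an observed statistic and its permutation null into the positively
#' biased, never-zero empirical p-value
#' `p = (1 + #\{null beats-or-ties observed\}) / (1 + B)`.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of B null statistics (`NA`s dropped with
#'   their count recorded).
#' @param direction `"greater"` (null >= observed counts against) or
#'   `"less"`.
#' @param seed the seed that generated the null, recorded for provenance.
#' @return list of class `empirical_test` with `observed`, `null_values`,
#'   `p_value`, `direction`, `B`, `seed`, `n_null_dropped`.
#' @export
empirical_test <- function(observed, null_values,
                           direction = c("greater", "less"),
                           seed = NA_integer_) {
  direction <- match.arg(direction)
  dropped <- sum(is.na(null_values))
  null_values <- null_values[!is.na(null_values)]
  B <- length(null_values)
  if (!B) stop("empty null distribution")
  exceed <- if (direction == "greater") {
    sum(null_values >= observed)
  } else {
    sum(null_values <= observed)
  }
  structure(
    list(observed = observed, null_values = null_values,
         p_value = (1 + exceed) / (1 + B), direction = direction,
         B = B, seed = seed, n_null_dropped = dropped),
    class = "empirical_test"
  )
}

#' @export
print.empirical_test <- function(x, ...) {
  cat(sprintf(
    "empirical test (%s): observed=%.4g, B=%d, p=%.4g\n  null quantiles: %s\n",
    x$direction, x$observed, x$B, x$p_value,
    paste(sprintf("%s=%.3g", c("5%", "50%", "95%"),
                  stats::quantile(x$null_values, c(.05, .5, .95))),
          collapse = ", ")
  ))
  invisible(x)
}

empirical_test_report <- function(x) {
  list(
    observed = x$observed, B = x$B, seed = x$seed, p_value = x$p_value,
    direction = x$direction,
    null_quantiles = as.list(stats::quantile(
      x$null_values, c(0.05, 0.25, 0.5, 0.75, 0.95)
    ))
  )
}

#' Size-preserving random miRNA clusters
#'
#' The null model for cluster composition: miRNA ids are randomly permuted
#' and re-partitioned into groups with exactly the observed cluster size
#' multiset, isolated miRNAs counting as size-1 pseudo-clusters, so that
#' every miRNA is used exactly once per replicate.
#'
#' @param mirna_ids character vector of all miRNA ids (clustered and
#'   isolated); its length must match the observed total.
#' @param observed a `cluster_call`, or an integer vector of cluster sizes
#'   (size-1 entries for isolated miRNAs included).
#' @param B number of replicates (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @return object of class `random_cluster_sets`: list with `sets` (length-B
#'   list; each replicate is a list of member id vectors, one per cluster of
#'   size >= 2 first, then the size-1 pseudo-clusters), `sizes`, `B`, `seed`.
#' @export
generate_random_clusters <- function(mirna_ids, observed, B = 1000L, seed) {
  stopifnot(is_count(B, 1L))
  sizes <- if (inherits(observed, "cluster_call")) {
    c(observed$clusters$n_members, rep(1L, nrow(observed$isolated)))
  } else {
    as.integer(observed)
  }
  if (any(sizes < 1L)) stop("cluster sizes must be >= 1")
  if (length(mirna_ids) != sum(sizes)) {
    stop("size mismatch: ", length(mirna_ids), " miRNAs vs size multiset total ",
         sum(sizes))
  }
  perms <- withr::with_seed(seed, lapply(seq_len(B), function(b) {
    sample(mirna_ids)
  }))
  structure(list(perms = perms, sizes = sizes, B = as.integer(B),
                 seed = seed),
            class = "random_cluster_sets")
}

#' Extract one random cluster replicate
#'
#' @param random_sets a `random_cluster_sets`.
#' @param b replicate index in `1..B`.
#' @return list of member id vectors, one per cluster (in the order of the
#'   observed size multiset; size-1 entries are the isolated
#'   pseudo-clusters).
#' @export
random_cluster_set <- function(random_sets, b) {
  stopifnot(inherits(random_sets, "random_cluster_sets"))
  f <- factor(rep(seq_along(random_sets$sizes), random_sets$sizes),
              levels = seq_along(random_sets$sizes))
  unname(split(random_sets$perms[[b]], f))
}

# cluster assignment (id -> pseudo cluster label, NA for size-1 groups)
# for one replicate of a random_cluster_sets object
random_set_assignment <- function(random_sets, b) {
  sizes <- random_sets$sizes
  lab <- rep(ifelse(sizes >= 2L, sprintf("RC%03d", seq_along(sizes)),
                    NA_character_), sizes)
  setNames(lab, random_sets$perms[[b]])
}

#' Random module membership
#'
#' The null model for module composition: each replicate redraws, for every
#' module, as many miRNAs as it actually contains, uniformly without
#' replacement from the full set of network miRNAs; modules are disjoint
#' within a replicate (set `allow_reuse = TRUE` for independent per-module
#' draws that may share miRNAs across modules).
#'
#' @param module_counts named integer vector: miRNA count per module (or an
#'   `mcode_result`, counted against `network_mirnas`).
#' @param network_mirnas character vector of all network miRNA ids.
#' @param B number of replicates.
#' @param seed RNG seed.
#' @param allow_reuse allow the same miRNA in several modules of one
#'   replicate.
#' @return object of class `module_permutations`: list with `draws`
#'   (length-B list of lists of id vectors), `counts`, `B`, `seed`.
#' @export
module_membership_permutation <- function(module_counts, network_mirnas,
                                          B = 1000L, seed,
                                          allow_reuse = FALSE) {
  stopifnot(is_count(B, 1L))
  if (inherits(module_counts, "mcode_result")) {
    stop("pass per-module miRNA counts (use module_mirna_counts())")
  }
  counts <- as.integer(module_counts)
  total <- sum(counts)
  if (!allow_reuse && total > length(network_mirnas)) {
    stop("module miRNA slots (", total, ") exceed network miRNA count (",
         length(network_mirnas), ")")
  }
  raw <- module_permutation_raw(counts, length(network_mirnas), B, seed,
                                allow_reuse)
  f <- factor(rep(seq_along(counts), counts), levels = seq_along(counts))
  draws <- lapply(raw, function(idx) {
    unname(split(network_mirnas[idx], f))
  })
  structure(list(draws = draws, counts = counts, B = as.integer(B),
                 seed = seed, allow_reuse = allow_reuse),
            class = "module_permutations")
}

# replicate draws as concatenated integer indices into the miRNA id vector
# (per-module slices given by the counts vector)
module_permutation_raw <- function(counts, n_mirnas, B, seed, allow_reuse) {
  withr::with_seed(seed, lapply(seq_len(B), function(b) {
    if (allow_reuse) {
      unlist(lapply(counts, function(k) sample.int(n_mirnas, k)),
             use.names = FALSE)
    } else {
      sample.int(n_mirnas, sum(counts))
    }
  }))
}

#' Per-miRNA cluster category
#'
#' @param clusters a `cluster_call`.
#' @param ids optional ids to look up; ids absent from the annotation are
#'   returned as `"isolated"`.
#' @return named character vector with values `"homo"`, `"hetero"`,
#'   `"isolated"`.
#' @export
mirna_categories <- function(clusters, ids = NULL) {
  stopifnot(inherits(clusters, "cluster_call"))
  type_of <- setNames(clusters$clusters$cluster_type,
                      clusters$clusters$cluster_id)
  categ <- ifelse(is.na(clusters$genes$cluster_id), "isolated",
                  unname(type_of[clusters$genes$cluster_id]))
  categ <- setNames(categ, clusters$genes$id)
  if (is.null(ids)) return(categ)
  out <- categ[ids]
  out[is.na(out)] <- "isolated"
  setNames(out, ids)
}

module_mirna_counts <- function(modules, network) {
  lengths(module_mirnas(modules, network))
}

#' Enrichment of clustered miRNAs in modules
#'
#' Tests whether homo-clustered and hetero-clustered miRNAs occur in the
#' detected modules more often than random module membership would produce.
#' The statistic is the average count per module of miRNAs of the category;
#' the null redraws module memberships with
#' [module_membership_permutation()]; p is one-sided (greater).
#'
#' @param modules an `mcode_result` (or list of module member id vectors).
#' @param clusters a `cluster_call`.
#' @param network a `regulatory_network`.
#' @param B permutation count (default 1000).
#' @param seed RNG seed.
#' @param id_map optional mapping from annotation to network ids
#'   ([map_mirna_ids()]).
#' @return list with elements `homo` and `hetero`, each an
#'   [empirical_test()].
#' @export
clustered_mirna_enrichment <- function(modules, clusters, network, B = 1000L,
                                       seed, id_map = NULL) {
  mod_mirnas <- module_mirnas(modules, network)
  if (!length(mod_mirnas)) stop("no modules given")
  net_mirnas <- network_node_ids(network, "miRNA")
  categ_ann <- mirna_categories(clusters)
  net_names <- if (is.null(id_map)) names(categ_ann) else {
    map_mirna_ids(names(categ_ann), map = id_map)
  }
  categ <- setNames(rep("isolated", length(net_mirnas)), net_mirnas)
  hit <- match(net_names, net_mirnas)
  categ[hit[!is.na(hit)]] <- categ_ann[!is.na(hit)]

  # the average count per module equals (total hits across modules) / M,
  # which stays valid for allow_reuse draws (hits counted with multiplicity)
  M <- length(mod_mirnas)
  counts <- lengths(mod_mirnas)
  raw <- module_permutation_raw(counts, length(net_mirnas), B, seed,
                                allow_reuse = FALSE)
  obs_idx <- match(unlist(mod_mirnas, use.names = FALSE), net_mirnas)
  res <- lapply(c(homo = "homo", hetero = "hetero"), function(what) {
    is_cat <- categ == what
    observed <- sum(is_cat[obs_idx], na.rm = TRUE) / M
    null_values <- vapply(raw, function(idx) sum(is_cat[idx]) / M, numeric(1))
    empirical_test(observed, null_values, direction = "greater", seed = seed)
  })
  res
}

#' Cluster entropy of a network module
#'
#' The miRNA cluster entropy of a module,
#' \deqn{E_c = -\frac{1}{\ln N_c} \sum_i p^c_i \ln p^c_i,}
#' is the normalized entropy of the genomic-cluster composition of the
#' module's clustered miRNAs: \eqn{N_c} clusters are represented and
#' \eqn{p^c_i} is the fraction of the module's clustered miRNAs coming from
#' cluster i. 0 means all from one cluster; 1 means all from distinct
#' clusters. Isolated miRNAs do not enter the composition.
#'
#' @param module_mirna_ids miRNA ids of one module.
#' @param cluster_of named vector mapping miRNA id to cluster id (`NA` for
#'   isolated), e.g. from a `cluster_call`'s genes table, or a
#'   `cluster_call` itself.
#' @return list of class `module_entropy` with `e_c`, `n_c`,
#'   `cluster_probs`, `n_clustered`.
#' @export
module_cluster_entropy <- function(module_mirna_ids, cluster_of) {
  if (inherits(cluster_of, "cluster_call")) {
    cluster_of <- cluster_assignment(cluster_of)
  }
  cl <- cluster_of[module_mirna_ids]
  cl <- cl[!is.na(cl)]
  if (!length(cl)) {
    stop("module contains no clustered miRNAs; cluster entropy undefined")
  }
  tab <- table(cl)
  structure(
    list(e_c = norm_entropy(cl), n_c = length(tab),
         cluster_probs = setNames(as.numeric(tab) / sum(tab), names(tab)),
         n_clustered = length(cl)),
    class = "module_entropy"
  )
}

# average E_c over modules with >= min_clustered clustered miRNAs under a
# given assignment; NA when no module is eligible
avg_module_entropy <- function(mod_mirnas, cluster_of, min_clustered = 2L) {
  vals <- vapply(mod_mirnas, function(m) {
    cl <- cluster_of[m]
    cl <- cl[!is.na(cl)]
    if (length(cl) < min_clustered) NA_real_ else norm_entropy(cl)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Module cluster-entropy null test
#'
#' Tests whether the average cluster entropy over modules (restricted to
#' modules with at least two clustered miRNAs) is lower than expected when
#' miRNAs are randomly re-assigned to clusters of the observed sizes. Low
#' entropy means module miRNAs concentrate in few genomic clusters.
#'
#' @param modules an `mcode_result` or list of module member vectors.
#' @param clusters a `cluster_call`.
#' @param network a `regulatory_network`.
#' @param random_sets a `random_cluster_sets` built over the same miRNA
#'   universe as `clusters`.
#' @param id_map optional annotation-to-network id mapping.
#' @return an [empirical_test()] (direction `"less"`).
#' @export
entropy_null_test <- function(modules, clusters, network, random_sets,
                              id_map = NULL) {
  stopifnot(inherits(random_sets, "random_cluster_sets"))
  mod_mirnas <- module_mirnas(modules, network)
  translate <- function(assign) {
    if (is.null(id_map)) return(assign)
    setNames(unname(assign), map_mirna_ids(names(assign), map = id_map))
  }
  observed_assign <- translate(cluster_assignment(clusters))
  observed <- avg_module_entropy(mod_mirnas, observed_assign)
  if (is.na(observed)) {
    stop("no module with >= 2 clustered miRNAs; entropy test undefined")
  }
  # vectorized null loop: integer cluster codes per replicate, entropies by
  # module via tabulate (same statistic as avg_module_entropy)
  concat <- unlist(mod_mirnas, use.names = FALSE)
  mod_grp <- rep(seq_along(mod_mirnas), lengths(mod_mirnas))
  M <- length(mod_mirnas)
  group_sizes <- random_sets$sizes
  n_groups <- length(group_sizes)
  grp_code <- rep(ifelse(group_sizes >= 2L, seq_along(group_sizes), NA_integer_),
                  group_sizes)
  null_values <- vapply(seq_len(random_sets$B), function(b) {
    u <- random_sets$perms[[b]]
    if (!is.null(id_map)) u <- map_mirna_ids(u, map = id_map)
    codes <- grp_code[match(concat, u)]
    ok <- !is.na(codes)
    if (!any(ok)) return(NA_real_)  # no clustered miRNA in any module
    g <- mod_grp[ok]
    key <- (g - 1L) * (n_groups + 1L) + codes[ok]
    uk <- !duplicated(key)
    n_gc <- tabulate(match(key, key[uk]))       # count per (module, cluster)
    g_uk <- g[uk]
    m_g <- tabulate(g, nbins = M)               # clustered miRNAs per module
    N_g <- tabulate(g_uk, nbins = M)            # clusters per module
    s_g <- numeric(M)
    tmp <- rowsum(n_gc * log(n_gc), g_uk)
    s_g[as.integer(rownames(tmp))] <- tmp[, 1L]
    # normalized entropy from counts: (log m - (1/m) sum n log n) / log N
    ent <- ifelse(N_g <= 1L, 0,
                  (log(m_g) - s_g / m_g) / log(N_g))
    eligible <- m_g >= 2L
    if (!any(eligible)) NA_real_ else mean(ent[eligible])
  }, numeric(1))
  empirical_test(observed, null_values, direction = "less",
                 seed = random_sets$seed)
}

#' Permutation contrast of mean target overlap between two pair categories
#'
#' Tests whether category a's mean TO exceeds category b's by permuting the
#' category labels over the pooled pair TO values.
#'
#' @param to_a,to_b numeric TO vectors, or data.frames with a `to` column
#'   (e.g. from [target_overlap_table()]). Identical pair lists are
#'   rejected.
#' @param B number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return an [empirical_test()] on the mean difference a - b (direction
#'   `"greater"`).
#' @export
to_contrast_test <- function(to_a, to_b, B = 1000L, seed) {
  key <- function(x) {
    if (is.data.frame(x) && all(c("mirna_i", "mirna_j") %in% names(x))) {
      sort(paste(x$mirna_i, x$mirna_j))
    } else NULL
  }
  if (!is.null(key(to_a)) && identical(key(to_a), key(to_b))) {
    stop("the two pair lists are identical; contrast undefined")
  }
  if (is.data.frame(to_a)) to_a <- to_a$to
  if (is.data.frame(to_b)) to_b <- to_b$to
  if (!length(to_a) || !length(to_b)) stop("both pair lists must be non-empty")
  stopifnot(is_count(B, 1L))
  observed <- mean(to_a) - mean(to_b)
  pooled <- c(to_a, to_b)
  n_a <- length(to_a)
  null_values <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample.int(length(pooled), n_a)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  empirical_test(observed, null_values, direction = "greater", seed = seed)
}
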