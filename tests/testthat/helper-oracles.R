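# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: reachability by boolean adjacency-matrix powers,
# MCODE vertex weights via igraph::coreness on neighborhood subgraphs, and
# entropy evaluated term by term.

# nodes reachable from `from` by directed paths of length <= k (source
# excluded, matching the package's shortest-distance semantics)
oracle_reachable <- function(edges, nodes, from, k) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) A[cbind(edges$source, edges$target)] <- TRUE
  cur <- A[from, ]
  acc <- cur
  if (k > 1) {
    for (i in 2:k) {
      cur <- as.vector(cur %*% A) > 0
      acc <- acc | cur
    }
  }
  acc[from] <- FALSE
  sort(nodes[acc])
}

# normalized Shannon entropy, evaluated term by term over the categories
oracle_entropy <- function(labels) {
  cats <- unique(labels)
  if (length(cats) == 1) return(0)
  total <- 0
  for (cat in cats) {
    p <- sum(labels == cat) / length(labels)
    total <- total + p * log(p)
  }
  -total / log(length(cats))
}

# MCODE stage-1 weights computed through igraph (the package implementation
# uses its own peeling-based core decomposition)
oracle_mcode_weights <- function(ug, degree_cutoff = 2) {
  n <- igraph::vcount(ug)
  w <- setNames(numeric(n), igraph::V(ug)$name)
  deg <- igraph::degree(ug)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff || deg[v] == 0) next
    closed <- c(v, as.integer(igraph::neighbors(ug, v)))
    sub <- igraph::induced_subgraph(ug, closed)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    ns <- igraph::vcount(core_sub)
    dens <- if (ns < 2) 0 else 2 * igraph::ecount(core_sub) / (ns * (ns - 1))
    w[v] <- kmax * dens
  }
  w
}

# re-derivation of the seeded expansion rule for the TOP module only (no
# vertex consumed beforehand): fixpoint inclusion of neighbors with weight
# >= (1 - cutoff) * seed weight, then 2-core filter and haircut via igraph
oracle_top_module <- function(ug, seed_name, params) {
  w <- oracle_mcode_weights(ug, params$degree_cutoff)
  nm <- igraph::V(ug)$name
  thr <- (1 - params$node_score_cutoff) * w[seed_name]
  members <- seed_name
  repeat {
    nb <- unique(unlist(lapply(members, function(v) {
      nm[as.integer(igraph::neighbors(ug, match(v, nm)))]
    })))
    add <- setdiff(nb[w[nb] >= thr], members)
    if (!length(add)) break
    members <- c(members, add)
  }
  if (length(members) < 2) return(NULL)
  sub <- igraph::induced_subgraph(ug, match(members, nm))
  if (max(igraph::coreness(sub)) < params$k_core) return(NULL)
  if (params$haircut) {
    repeat {
      drop <- which(igraph::degree(sub) < 2)
      if (!length(drop) || igraph::vcount(sub) - length(drop) < 2) break
      sub <- igraph::induced_subgraph(sub, setdiff(seq_len(igraph::vcount(sub)), drop))
    }
    if (igraph::vcount(sub) < 2) return(NULL)
  }
  ns <- igraph::vcount(sub)
  dens <- if (ns < 2) 0 else 2 * igraph::ecount(sub) / (ns * (ns - 1))
  list(members = sort(igraph::V(sub)$name), score = dens * ns, size = ns)
}

random_undirected_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    g
  })
}

random_edge_list <- function(n, p, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  withr::with_seed(seed, {
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs[runif(nrow(pairs)) < p, ]
  })
}
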