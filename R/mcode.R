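#' MCODE parameters
#'
#' Parameters of the MCODE dense-module detection algorithm (Bader & Hogue).
#' Defaults follow the canonical reference implementation.
#'
#' @param degree_cutoff vertices with degree below this get weight 0
#'   (default 2).
#' @param node_score_cutoff fraction of the seed weight a neighbor may fall
#'   short of and still join the module (default 0.2): a vertex is included
#'   when its weight is at least `(1 - node_score_cutoff)` times the seed's.
#' @param k_core modules lacking a k-core of this order are discarded
#'   (default 2).
#' @param haircut iteratively remove degree-1 members (default `TRUE`).
#' @param fluff add neighbors whose closed-neighborhood density exceeds
#'   `fluff_density` (default `FALSE`; fluffed modules may overlap).
#' @param fluff_density density threshold for fluff (default 0.1).
#' @param max_depth breadth-first expansion depth limit from the seed
#'   (default 100).
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1, max_depth = 100L) {
  stopifnot(
    is_count(degree_cutoff, 0L), is_count(k_core, 1L), is_count(max_depth, 1L),
    is.numeric(node_score_cutoff), node_score_cutoff >= 0, node_score_cutoff <= 1,
    is.logical(haircut), is.logical(fluff),
    is.numeric(fluff_density), fluff_density >= 0
  )
  structure(
    list(degree_cutoff = as.integer(degree_cutoff),
         node_score_cutoff = node_score_cutoff,
         k_core = as.integer(k_core),
         haircut = isTRUE(haircut), fluff = isTRUE(fluff),
         fluff_density = fluff_density, max_depth = as.integer(max_depth)),
    class = "mcode_params"
  )
}

#' Undirected projection of a regulatory network
#'
#' MCODE operates on simple undirected graphs: every unordered node pair
#' connected by at least one directed edge yields one undirected edge;
#' self-loops are discarded.
#'
#' @param network a `regulatory_network` or an `igraph` graph.
#' @return a simple undirected `igraph` graph (vertex attributes preserved).
#' @export
undirected_projection <- function(network) {
  g <- if (inherits(network, "regulatory_network")) network$graph else network
  stopifnot(igraph::is_igraph(g))
  ug <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(ug, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

simple_density <- function(n, m) if (n < 2L) 0 else 2 * m / (n * (n - 1))

#' MCODE vertex weights
#'
#' Stage 1 of MCODE: the weight of a vertex is `k * density` of the highest
#' k-core of its closed neighborhood, where density is the simple-graph
#' density `2E / (n (n - 1))`. Vertices with degree below
#' `params$degree_cutoff` get weight 0.
#'
#' @param graph simple undirected `igraph` graph (see
#'   [undirected_projection()]).
#' @param params an [mcode_params()] list.
#' @return named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(graph, params = mcode_params()) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  weights_from_adj(adj, igraph::V(graph)$name, params)
}

weights_from_adj <- function(adj, names, params) {
  n <- length(adj)
  w <- numeric(n)
  names(w) <- names
  if (!n) return(w)
  deg <- lengths(adj)
  eligible <- which(deg >= params$degree_cutoff & deg > 0)
  pos <- integer(n)  # shared position buffer, reset after each vertex
  for (v in eligible) {
    closed <- c(v, adj[[v]])
    m <- length(closed)
    pos[closed] <- seq_len(m)
    # adjacency restricted to the closed neighborhood, in local indices
    local <- vector("list", m)
    n_edges <- 0L
    for (i in seq_len(m)) {
      p <- pos[adj[[closed[i]]]]
      local[[i]] <- p[p > 0L]
      n_edges <- n_edges + length(local[[i]])
    }
    n_edges <- n_edges %/% 2L
    if (n_edges == m - 1L) {
      # tree neighborhood (stars, paths): the highest core is the whole
      # closed neighborhood at k = 1
      w[v] <- simple_density(m, n_edges)
    } else {
      hc <- highest_core(local)
      if (hc$k > 0L) {
        w[v] <- hc$k * simple_density(length(hc$members), hc$n_edges)
      }
    }
    pos[closed] <- 0L
  }
  w
}

# highest k-core of a small graph given as a local adjacency list:
# peel vertices of degree < k for k = 1, 2, ... until the graph empties;
# the last non-empty survivor set is the highest core
# members of the k-core (possibly empty) of a small local-adjacency graph
k_core_members <- function(local, k) {
  degl <- lengths(local)
  alive <- rep(TRUE, length(local))
  repeat {
    drop <- which(alive & degl < k)
    if (!length(drop)) break
    alive[drop] <- FALSE
    for (v in drop) {
      for (u in local[[v]]) if (alive[u]) degl[u] <- degl[u] - 1L
    }
  }
  which(alive)
}

highest_core <- function(local) {
  m <- length(local)
  degl <- lengths(local)
  alive <- rep(TRUE, m)
  best <- list(k = 0L, members = integer(0), n_edges = 0L)
  k <- 1L
  repeat {
    repeat {
      drop <- which(alive & degl < k)
      if (!length(drop)) break
      alive[drop] <- FALSE
      for (v in drop) {
        for (u in local[[v]]) if (alive[u]) degl[u] <- degl[u] - 1L
      }
    }
    if (!any(alive)) break
    best <- list(k = k, members = which(alive),
                 n_edges = sum(degl[alive]) %/% 2L)
    k <- k + 1L
  }
  best
}

#' Detect dense modules with MCODE
#'
#' Stage 2 and 3 of MCODE. Seeds are taken in decreasing weight order (ties
#' broken lexicographically by vertex name); from each seed a breadth-first
#' expansion includes unassigned neighbors whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight, up to `max_depth` steps;
#' each vertex joins at most one module. Modules lacking a `k_core`-core are
#' dropped; `haircut` then prunes degree-1 members iteratively; `fluff`
#' optionally adds dense-neighborhood boundary vertices. Module score is
#' `density * size`, and output is sorted by score, then size, then seed
#' name.
#'
#' @param network a `regulatory_network` or undirected `igraph` graph.
#' @param params an [mcode_params()] list.
#' @return object of class `mcode_result`: list with `modules` (list of
#'   per-module lists: `module_id`, `seed`, `members`, `size`, `score`),
#'   `summary` (data.frame), `weights` and `params`.
#' @export
mcode <- function(network, params = mcode_params()) {
  ug <- if (igraph::is_igraph(network) && !igraph::is_directed(network)) {
    network
  } else {
    undirected_projection(network)
  }
  nm <- igraph::V(ug)$name
  adj <- lapply(igraph::as_adj_list(ug, mode = "all"), as.integer)
  w <- weights_from_adj(adj, nm, params)
  assigned <- logical(length(nm))

  seed_order <- order(-w, nm, method = "radix")
  raw <- list()
  for (s in seed_order) {
    if (assigned[s] || w[s] <= 0) next
    thr <- (1 - params$node_score_cutoff) * w[s]
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!assigned[u] && w[u] >= thr) {
            assigned[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) >= 2L) raw[[length(raw) + 1L]] <- list(seed = s, members = members)
  }

  modules <- list()
  pos <- integer(length(nm))  # shared local-index buffer
  intadj <- adj
  local_graph <- function(vset) {
    pos[vset] <<- seq_along(vset)
    local <- lapply(vset, function(u) {
      p <- pos[intadj[[u]]]
      p[p > 0L]
    })
    pos[vset] <<- 0L
    local
  }
  for (cand in raw) {
    vset <- cand$members
    local <- local_graph(vset)
    if (highest_core(local)$k < params$k_core) next
    keep <- seq_along(vset)
    if (params$haircut) {
      # iterative removal of degree < 2 members == restriction to the 2-core
      keep <- k_core_members(local, 2L)
      if (length(keep) < 2L) next
      vset <- vset[keep]
      local <- local_graph(vset)
    }
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(intadj[vset])), vset)
      add <- boundary[vapply(boundary, function(u) {
        closed <- c(u, intadj[[u]])
        lu <- local_graph(closed)
        simple_density(length(closed), sum(lengths(lu)) %/% 2L) >
          params$fluff_density
      }, logical(1))]
      if (length(add)) {
        vset <- c(vset, add)
        local <- local_graph(vset)
      }
    }
    size <- length(vset)
    score <- simple_density(size, sum(lengths(local)) %/% 2L) * size
    modules[[length(modules) + 1L]] <- list(
      seed = nm[cand$seed],
      members = sort(nm[vset]),
      size = size,
      score = score
    )
  }

  if (length(modules)) {
    ord <- order(-vapply(modules, `[[`, 0, "score"),
                 -vapply(modules, `[[`, 0L, "size"),
                 vapply(modules, `[[`, "", "seed"),
                 method = "radix")
    modules <- modules[ord]
    for (i in seq_along(modules)) modules[[i]]$module_id <- i
  }
  summary <- if (length(modules)) {
    data.frame(
      module_id = vapply(modules, `[[`, 0L, "module_id"),
      seed = vapply(modules, `[[`, "", "seed"),
      size = vapply(modules, `[[`, 0L, "size"),
      score = vapply(modules, `[[`, 0, "score"),
      members = vapply(modules, function(m) paste(m$members, collapse = ";"), ""),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(module_id = integer(0), seed = character(0), size = integer(0),
               score = numeric(0), members = character(0))
  }
  structure(list(modules = modules, summary = summary, weights = w,
                 params = params),
            class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("MCODE: %d modules\n", length(x$modules)))
  if (length(x$modules)) {
    print(head(x$summary[, c("module_id", "seed", "size", "score")], 10L))
  }
  invisible(x)
}

module_members <- function(modules) {
  if (inherits(modules, "mcode_result")) {
    lapply(modules$modules, `[[`, "members")
  } else {
    stopifnot(is.list(modules))
    modules
  }
}

# miRNA members per module, in network id space
module_mirnas <- function(modules, network) {
  mirnas <- network_node_ids(network, "miRNA")
  lapply(module_members(modules), function(m) intersect(m, mirnas))
}

#' Cross-tabulate modules against genomic clusters
#'
#' For every detected module, counts members by node type and by genomic
#' cluster category (homo-clustered, hetero-clustered, isolated), and lists
#' the genomic clusters contributing at least one intra-cluster miRNA pair
#' to the module.
#'
#' @param modules an `mcode_result` (or list of member id vectors).
#' @param clusters a `cluster_call`.
#' @param network the `regulatory_network` the modules were detected on.
#' @return data.frame with one row per module: `module_id`, `size`, `n_tf`,
#'   `n_mirna`, `n_gene`, `n_homo_clustered`, `n_hetero_clustered`,
#'   `n_isolated_mirna`, `n_clusters_with_pair`, `clusters_with_pair`
#'   (";"-joined), `has_cluster_pair`.
#' @export
modules_report <- function(modules, clusters, network) {
  stopifnot(inherits(clusters, "cluster_call"),
            inherits(network, "regulatory_network"))
  members <- module_members(modules)
  g <- network$graph
  node_type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  categ <- mirna_categories(clusters)
  assign <- cluster_assignment(clusters)
  rows <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    tp <- node_type[m]
    mir <- m[!is.na(tp) & tp == "miRNA"]
    cat_i <- categ[mir]
    cat_i[is.na(cat_i)] <- "isolated"   # network miRNAs absent from annotation
    cl <- assign[mir]
    cl_tab <- table(cl[!is.na(cl)])
    with_pair <- names(cl_tab)[cl_tab >= 2L]
    data.frame(
      module_id = i,
      size = length(m),
      n_tf = sum(tp == "TF", na.rm = TRUE),
      n_mirna = length(mir),
      n_gene = sum(tp == "gene", na.rm = TRUE),
      n_homo_clustered = sum(cat_i == "homo"),
      n_hetero_clustered = sum(cat_i == "hetero"),
      n_isolated_mirna = sum(cat_i == "isolated"),
      n_clusters_with_pair = length(with_pair),
      clusters_with_pair = paste(with_pair, collapse = ";"),
      has_cluster_pair = length(with_pair) > 0L,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      module_id = integer(0), size = integer(0), n_tf = integer(0),
      n_mirna = integer(0), n_gene = integer(0), n_homo_clustered = integer(0),
      n_hetero_clustered = integer(0), n_isolated_mirna = integer(0),
      n_clusters_with_pair = integer(0), clusters_with_pair = character(0),
      has_cluster_pair = logical(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Write the module table
#' @param result an `mcode_result`.
#' @param path TSV destination.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(result, path) {
  stopifnot(inherits(result, "mcode_result"))
  write.table(result$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
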