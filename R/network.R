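#' Construct a typed regulatory network
#'
#' A regulatory network is a simple directed graph whose nodes are typed as
#' `TF`, `miRNA` or `gene` (non-TF protein-coding gene). Edges point from a
#' regulator (TF or miRNA) to the node it regulates. Self-loops are dropped
#' and duplicate directed edges collapsed; both counts are kept on the
#' object.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `relation` (default `"regulates"`).
#' @param node_types named character vector mapping node ids to
#'   `"TF"`, `"miRNA"` or `"gene"`. Nodes absent from it default to `"gene"`.
#'   Names that do not occur in any edge become isolated nodes.
#' @return object of class `regulatory_network` wrapping an `igraph` graph
#'   with vertex attributes `name` and `type` and edge attribute `relation`.
#' @export
regulatory_network <- function(edges, node_types = NULL) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$relation)) {
    edges$relation <- rep_len("regulates", nrow(edges))
  }
  loops <- edges$source == edges$target
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]
  dup <- duplicated(edges[, c("source", "target")])
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]

  ids <- unique(c(edges$source, edges$target, names(node_types)))
  type <- rep("gene", length(ids))
  names(type) <- ids
  if (!is.null(node_types)) {
    bad <- setdiff(unique(node_types), c("TF", "miRNA", "gene"))
    if (length(bad)) stop("unknown node types: ", paste(bad, collapse = ", "))
    type[names(node_types)] <- node_types
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "relation")],
    directed = TRUE,
    vertices = data.frame(name = ids, type = unname(type),
                          stringsAsFactors = FALSE)
  )
  structure(
    list(graph = g, n_self_loops = n_loops, n_duplicate_edges = n_dup),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  tp <- table(factor(igraph::V(x$graph)$type, levels = c("TF", "miRNA", "gene")))
  cat(sprintf(
    "regulatory network: %d nodes (%d TF, %d miRNA, %d gene), %d edges\n",
    igraph::vcount(x$graph), tp[["TF"]], tp[["miRNA"]], tp[["gene"]],
    igraph::ecount(x$graph)
  ))
  if (x$n_self_loops || x$n_duplicate_edges) {
    cat(sprintf("  dropped on construction: %d self-loops, %d duplicate edges\n",
                x$n_self_loops, x$n_duplicate_edges))
  }
  invisible(x)
}

network_node_ids <- function(network, type = NULL) {
  g <- network$graph
  ids <- igraph::V(g)$name
  if (is.null(type)) ids else ids[igraph::V(g)$type == type]
}

#' Read a network from SIF
#'
#' Parses Cytoscape simple interaction format: each line is
#' `source <relation> target [target2 ...]` separated by tabs or runs of
#' spaces; a line with a single field declares an isolated node. Node types
#' are assigned by precedence: explicit TF list, then miRNA id prefix rules,
#' then `gene`.
#'
#' @param path SIF file.
#' @param tf_list character vector of TF ids, or a path to a one-id-per-line
#'   text file.
#' @param mirna_prefixes id prefixes (matched case-insensitively) that mark
#'   miRNA nodes.
#' @param strict if `TRUE`, a typed `gene` node with outgoing edges is an
#'   error instead of a warning.
#' @return a `regulatory_network`.
#' @export
read_sif <- function(path, tf_list = NULL,
                     mirna_prefixes = c("hsa-mir", "hsa-let", "hsa-miR"),
                     strict = FALSE) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  n_fields <- lengths(fields)
  if (any(n_fields == 2L)) {
    stop("SIF parse error at line ", lineno[which(n_fields == 2L)[1L]],
         ": expected 1 or >= 3 fields")
  }
  singles <- vapply(fields[n_fields == 1L], `[[`, "", 1L)
  triples <- fields[n_fields >= 3L]
  edges <- if (length(triples)) {
    do.call(rbind, lapply(triples, function(f) {
      data.frame(source = f[1L], relation = f[2L], target = f[-(1:2)],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(source = character(0), relation = character(0),
               target = character(0))
  }
  if (length(tf_list) == 1L && file.exists(tf_list)) {
    tf_list <- readLines(tf_list)
    tf_list <- trimws(tf_list[nzchar(trimws(tf_list))])
  }
  ids <- unique(c(edges$source, edges$target, singles))
  type <- ifelse(
    ids %in% tf_list, "TF",
    ifelse(has_mirna_prefix(ids, mirna_prefixes), "miRNA", "gene")
  )
  net <- regulatory_network(edges[, c("source", "target", "relation")],
                            node_types = setNames(type, ids))
  offenders <- genes_with_out_edges(net)
  if (length(offenders)) {
    msg <- paste0("gene node(s) with outgoing edges: ",
                  paste(head(offenders, 5L), collapse = ", "),
                  if (length(offenders) > 5L) ", ...")
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  net
}

has_mirna_prefix <- function(ids, prefixes) {
  low <- tolower(ids)
  out <- rep(FALSE, length(ids))
  for (p in tolower(prefixes)) out <- out | startsWith(low, p)
  out
}

genes_with_out_edges <- function(network) {
  g <- network$graph
  odeg <- igraph::degree(g, mode = "out")
  igraph::V(g)$name[igraph::V(g)$type == "gene" & odeg > 0]
}

#' Write a network as SIF
#'
#' Emits one `source relation target` line per edge, lexicographically
#' sorted, plus single-field lines for isolated nodes, so output is
#' deterministic and `read_sif(write_sif(x))` reproduces the same node and
#' edge sets.
#'
#' @param network a `regulatory_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  g <- network$graph
  el <- igraph::as_data_frame(g, what = "edges")
  lines <- character(0)
  if (nrow(el)) {
    el <- el[order(el$from, el$relation %||% "", el$to, method = "radix"), ]
    lines <- sprintf("%s\t%s\t%s", el$from, el$relation, el$to)
  }
  iso <- sort(igraph::V(g)$name[igraph::degree(g) == 0])
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write the TF list of a network
#' @param network a `regulatory_network`.
#' @param path output file, one TF id per line (sorted).
#' @return `path`, invisibly.
#' @export
write_tf_list <- function(network, path) {
  writeLines(sort(network_node_ids(network, "TF")), path)
  invisible(path)
}

#' Validate a regulatory network
#'
#' @param network a `regulatory_network`.
#' @return list of class `network_validation` with node/edge counts by type,
#'   the list of gene nodes carrying outgoing edges (an invariant violation),
#'   a weakly-connected-component summary and the total violation count.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  g <- network$graph
  tp <- table(factor(igraph::V(g)$type, levels = c("TF", "miRNA", "gene")))
  comp <- igraph::components(g, mode = "weak")
  offenders <- genes_with_out_edges(network)
  structure(
    list(
      n_nodes = igraph::vcount(g),
      n_edges = igraph::ecount(g),
      n_tf = as.integer(tp[["TF"]]),
      n_mirna = as.integer(tp[["miRNA"]]),
      n_gene = as.integer(tp[["gene"]]),
      n_self_loops_dropped = network$n_self_loops,
      n_duplicate_edges_dropped = network$n_duplicate_edges,
      n_dangling_edges = 0L,  # unrepresentable: edges are built over the node set
      genes_with_out_edges = offenders,
      n_components = comp$no,
      largest_component = if (comp$no) max(comp$csize) else 0L,
      n_violations = length(offenders)
    ),
    class = "network_validation"
  )
}

#' @export
print.network_validation <- function(x, ...) {
  cat(sprintf("network validation: %d nodes (%d TF / %d miRNA / %d gene), %d edges\n",
              x$n_nodes, x$n_tf, x$n_mirna, x$n_gene, x$n_edges))
  cat(sprintf("  components: %d (largest %d); violations: %d\n",
              x$n_components, x$largest_component, x$n_violations))
  if (x$n_violations) {
    cat("  gene nodes with outgoing edges: ",
        paste(head(x$genes_with_out_edges, 10L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Targets reachable within k regulation steps
#'
#' The k-step target set of a miRNA is every node (TF, gene or miRNA, the
#' source itself excluded) reachable from it by a directed path of length at
#' most `steps`. `steps = "closure"` gives unbounded reachability, which is
#' cycle-safe. Intermediate regulators reached on the way count as targets;
#' set `universe = "gene_only"` to count only non-TF gene nodes.
#'
#' @param network a `regulatory_network`.
#' @param mirna_id a miRNA node id.
#' @param steps positive integer number of regulation steps, or `"closure"`.
#' @param universe `"all"` (default) or `"gene_only"`.
#' @return object of class `target_profile`: list with `mirna_id`, `steps`,
#'   `targets` (character vector), `l` (their count) and `universe_size`
#'   (number of non-source nodes that are the target of at least one edge;
#'   recorded for reporting, not used by the overlap statistic).
#' @export
k_step_targets <- function(network, mirna_id, steps = 1L,
                           universe = c("all", "gene_only")) {
  universe <- match.arg(universe)
  profiles <- target_profiles(network, mirna_id, steps = steps,
                              universe = universe)
  profiles[[1L]]
}

#' Batch k-step target profiles
#'
#' @inheritParams k_step_targets
#' @param mirna_ids character vector of miRNA node ids.
#' @return named list of `target_profile` objects.
#' @export
target_profiles <- function(network, mirna_ids, steps = 1L,
                            universe = c("all", "gene_only")) {
  stopifnot(inherits(network, "regulatory_network"))
  universe <- match.arg(universe)
  g <- network$graph
  idx <- match(mirna_ids, igraph::V(g)$name)
  if (anyNA(idx)) {
    stop("unknown node id(s): ", paste(mirna_ids[is.na(idx)], collapse = ", "))
  }
  types <- igraph::V(g)$type[idx]
  if (any(types != "miRNA")) {
    stop("not miRNA node(s): ",
         paste(mirna_ids[types != "miRNA"], collapse = ", "))
  }
  order <- if (identical(steps, "closure")) {
    igraph::vcount(g)
  } else {
    if (!is_count(steps, min = 1L)) stop("steps must be >= 1 or \"closure\"")
    as.integer(steps)
  }
  # universe size: nodes with at least one incoming edge, source excluded
  indeg <- igraph::degree(g, mode = "in")
  regulated <- igraph::V(g)$name[indeg > 0]
  nb <- igraph::ego(g, order = order, nodes = idx, mode = "out", mindist = 1)
  node_type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  profiles <- lapply(seq_along(mirna_ids), function(i) {
    targets <- nb[[i]]$name
    if (universe == "gene_only") targets <- targets[node_type[targets] == "gene"]
    structure(
      list(
        mirna_id = mirna_ids[i],
        steps = steps,
        universe = universe,
        targets = targets,
        l = length(targets),
        universe_size = sum(regulated != mirna_ids[i])
      ),
      class = "target_profile"
    )
  })
  setNames(profiles, mirna_ids)
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("target profile of %s at steps=%s: l=%d (universe %s, N=%d)\n",
              x$mirna_id, as.character(x$steps), x$l, x$universe,
              x$universe_size))
  invisible(x)
}

#' Map annotation miRNA ids onto network ids
#'
#' Naming often differs between genomic annotation (precursor ids) and
#' network node ids (mature ids). With an explicit two-column mapping
#' (`from`, `to`) ids are translated by lookup; otherwise a heuristic strips
#' `-5p`/`-3p` suffixes and lower-cases `miR` to `mir`.
#'
#' @param ids character vector of ids to translate.
#' @param map optional data.frame with columns `from` and `to`, or a path to
#'   such a TSV.
#' @return character vector of translated ids (same length; untranslated ids
#'   pass through the heuristic unchanged when no map entry exists).
#' @export
map_mirna_ids <- function(ids, map = NULL) {
  if (!is.null(map)) {
    if (is.character(map) && length(map) == 1L) {
      map <- read.delim(map, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("from", "to") %in% names(map)))
    hit <- match(ids, map$from)
    out <- ifelse(is.na(hit), ids, map$to[hit])
    return(out)
  }
  out <- sub("-[35]p$", "", ids)
  gsub("miR", "mir", out, fixed = TRUE)
}
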