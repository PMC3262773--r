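#' Target overlap of a miRNA pair
#'
#' The target overlap of miRNAs i and j is
#' \deqn{TO_{ij} = \frac{|T_i \cap T_j|}{\min(|T_i|, |T_j|) + 1}}
#' where \eqn{T_i} is the target set of miRNA i (direct targets, or targets
#' reachable within a fixed number of regulation steps). The `+1` keeps the
#' ratio defined when a miRNA has no targets and bounds TO strictly below 1.
#'
#' @param profile_i,profile_j `target_profile` objects computed at the same
#'   `steps` on the same network.
#' @return list of class `pair_overlap` with `mirna_i`, `mirna_j`, `steps`,
#'   `shared`, `l_i`, `l_j`, `to`.
#' @export
pair_target_overlap <- function(profile_i, profile_j) {
  stopifnot(inherits(profile_i, "target_profile"),
            inherits(profile_j, "target_profile"))
  if (!identical(profile_i$steps, profile_j$steps)) {
    stop("profiles computed at different steps (",
         profile_i$steps, " vs ", profile_j$steps, ")")
  }
  shared <- length(intersect(profile_i$targets, profile_j$targets))
  structure(
    list(
      mirna_i = profile_i$mirna_id, mirna_j = profile_j$mirna_id,
      steps = profile_i$steps, shared = shared,
      l_i = profile_i$l, l_j = profile_j$l,
      to = shared / (min(profile_i$l, profile_j$l) + 1)
    ),
    class = "pair_overlap"
  )
}

#' Target-overlap table for a set of pairs
#'
#' @param network a `regulatory_network`.
#' @param pairs two-column matrix or data.frame of miRNA id pairs.
#' @param steps number of regulation steps (>= 1) or `"closure"`.
#' @param universe `"all"` or `"gene_only"` (see [k_step_targets()]).
#' @return data.frame with columns `mirna_i`, `mirna_j`, `steps`, `l_i`,
#'   `l_j`, `shared`, `to`.
#' @export
target_overlap_table <- function(network, pairs, steps = 1L,
                                 universe = c("all", "gene_only")) {
  universe <- match.arg(universe)
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) {
    return(data.frame(mirna_i = character(0), mirna_j = character(0),
                      steps = character(0), l_i = integer(0), l_j = integer(0),
                      shared = integer(0), to = numeric(0)))
  }
  stopifnot(ncol(pairs) == 2L)
  ids <- unique(as.vector(pairs))
  prof <- target_profiles(network, ids, steps = steps, universe = universe)
  tsets <- lapply(prof, `[[`, "targets")
  ls <- vapply(prof, `[[`, 0L, "l")
  shared <- vapply(seq_len(nrow(pairs)), function(r) {
    length(intersect(tsets[[pairs[r, 1L]]], tsets[[pairs[r, 2L]]]))
  }, integer(1))
  l_i <- ls[pairs[, 1L]]
  l_j <- ls[pairs[, 2L]]
  data.frame(
    mirna_i = pairs[, 1L], mirna_j = pairs[, 2L],
    steps = as.character(steps), l_i = unname(l_i), l_j = unname(l_j),
    shared = shared, to = shared / (pmin(l_i, l_j) + 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Intra-cluster miRNA pairs by category
#'
#' Builds the unordered miRNA pair lists compared throughout the analysis:
#' all intra-cluster pairs of homo-clusters, of hetero-clusters, and of
#' size-preserving random clusters. Cluster members absent from the network
#' are excluded (their count is attached as attribute `n_unmapped`).
#'
#' @param clusters a `cluster_call`.
#' @param network a `regulatory_network`.
#' @param random_sets optional `random_cluster_sets` from
#'   [generate_random_clusters()]; adds the `random` category.
#' @param id_map optional id mapping passed to [map_mirna_ids()] to translate
#'   annotation ids into network ids (`NULL` = use ids as they are).
#' @return named list with two-column character matrices `homo` and `hetero`,
#'   and (when `random_sets` is given) `random`: a data.frame with columns
#'   `mirna_i`, `mirna_j`, `replicate`.
#' @export
category_pairs <- function(clusters, network, random_sets = NULL,
                           id_map = NULL) {
  stopifnot(inherits(clusters, "cluster_call"),
            inherits(network, "regulatory_network"))
  net_mirnas <- network_node_ids(network, "miRNA")
  translate <- function(ids) {
    if (is.null(id_map)) ids else map_mirna_ids(ids, map = id_map)
  }
  n_unmapped <- 0L
  pairs_of <- function(member_ids) {
    mapped <- translate(member_ids)
    ok <- mapped %in% net_mirnas
    n_unmapped <<- n_unmapped + sum(!ok)
    mapped <- mapped[ok]
    if (length(mapped) < 2L) return(NULL)
    t(combn(sort(mapped), 2L))
  }
  collect <- function(type) {
    labs <- clusters$clusters$cluster_id[clusters$clusters$cluster_type %in% type]
    out <- do.call(rbind, lapply(clusters$members[labs], pairs_of))
    if (is.null(out)) out <- matrix(character(0), ncol = 2L)
    colnames(out) <- c("mirna_i", "mirna_j")
    out
  }
  res <- list(homo = collect("homo"), hetero = collect("hetero"))
  if (!is.null(random_sets)) {
    stopifnot(inherits(random_sets, "random_cluster_sets"))
    rnd <- lapply(seq_len(random_sets$B), function(b) {
      ps <- do.call(rbind, lapply(random_cluster_set(random_sets, b), pairs_of))
      if (is.null(ps)) return(NULL)
      data.frame(mirna_i = ps[, 1L], mirna_j = ps[, 2L], replicate = b,
                 stringsAsFactors = FALSE)
    })
    res$random <- do.call(rbind, rnd)
  }
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Target-overlap distribution
#'
#' Relative-frequency histogram of TO values over `[0, 1]` with right-closed
#' bins (`(0.8, 0.9]`, ..., first bin `[0, 0.1]`), plus the arithmetic mean.
#'
#' @param to numeric vector of TO values, or a data.frame with a `to` column
#'   (as returned by [target_overlap_table()]).
#' @param bins number of equal-width bins (default 10).
#' @return list of class `to_distribution` with `breaks`, `counts`,
#'   `rel_freq`, `mean`, `n`.
#' @export
to_distribution <- function(to, bins = 10L) {
  if (is.data.frame(to)) to <- to$to
  if (!length(to)) stop("empty pair list: no TO values to summarize")
  stopifnot(all(to >= 0), all(to < 1), is_count(bins, 1L))
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- findInterval(to, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L  # right-closed bins (a, b]; exact zeros fall in bin 1
  counts <- tabulate(idx, nbins = bins)
  structure(
    list(breaks = breaks, counts = counts, rel_freq = counts / length(to),
         mean = mean(to), n = length(to)),
    class = "to_distribution"
  )
}

#' @export
print.to_distribution <- function(x, ...) {
  cat(sprintf("TO distribution: n=%d, mean=%.4f\n", x$n, x$mean))
  lab <- sprintf("(%.1f,%.1f]", x$breaks[-length(x$breaks)], x$breaks[-1])
  lab[1] <- sub("^\\(", "[", lab[1])
  print(setNames(round(x$rel_freq, 3), lab))
  invisible(x)
}

#' Mean target overlap versus regulation steps
#'
#' Recomputes the mean TO of each pair category at every step count
#' `1..max_steps`. For the `random` category the statistic is the average of
#' per-replicate means, one per random cluster set. The smallest step count
#' at which a category's mean exceeds the random mean by `margin` is
#' attached as attribute `crossing`.
#'
#' @param pairs_by_category list as returned by [category_pairs()].
#' @param network a `regulatory_network`.
#' @param max_steps largest step count (default 8).
#' @param universe `"all"` or `"gene_only"`.
#' @param margin margin over the random mean used for the crossing report
#'   (default 0.05).
#' @return data.frame of class `category_curve` with columns `category`,
#'   `steps`, `mean_to`, `n_pairs`.
#' @export
to_vs_steps_curve <- function(pairs_by_category, network, max_steps = 8L,
                              universe = c("all", "gene_only"),
                              margin = 0.05) {
  stopifnot(is_count(max_steps, 1L))
  universe <- match.arg(universe)
  rows <- list()
  for (k in seq_len(max_steps)) {
    for (cat_name in names(pairs_by_category)) {
      p <- pairs_by_category[[cat_name]]
      if (is.null(p) || !NROW(p)) next
      if (cat_name == "random") {
        tab <- target_overlap_table(network, p[, c("mirna_i", "mirna_j"), drop = FALSE],
                                    steps = k, universe = universe)
        mean_to <- mean(tapply(tab$to, p$replicate, mean))
      } else {
        tab <- target_overlap_table(network, p, steps = k, universe = universe)
        mean_to <- mean(tab$to)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_name, steps = k, mean_to = mean_to, n_pairs = nrow(tab),
        stringsAsFactors = FALSE
      )
    }
  }
  curve <- do.call(rbind, rows)
  crossing <- NULL
  if ("random" %in% curve$category) {
    rnd <- curve$mean_to[curve$category == "random"][order(curve$steps[curve$category == "random"])]
    crossing <- sapply(setdiff(unique(curve$category), "random"), function(cat_name) {
      sel <- curve$category == cat_name
      mt <- curve$mean_to[sel][order(curve$steps[sel])]
      k <- which(mt > rnd + margin)
      if (length(k)) min(k) else NA_integer_
    })
  }
  structure(curve, class = c("category_curve", "data.frame"),
            crossing = crossing, margin = margin)
}
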