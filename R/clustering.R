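#' Call genomic miRNA clusters by distance chaining
#'
#' Two precursors located consecutively on a chromosome belong to the same
#' cluster when the gap between them (start of the downstream gene minus the
#' running maximum end of the chain, negative gaps treated as 0) is at most
#' `cutoff_bp`. Chaining is transitive, so a cluster may span far more than
#' the cutoff. Genes that end up alone are reported as isolated.
#'
#' @param genes a `mirna_annotation` data.frame (or any data.frame with
#'   columns `id`, `chrom`, `start`, `end`, `strand`, `family`).
#' @param cutoff_bp maximum inter-gene gap in base pairs (default 10000).
#' @param max_span_bp optional cap on the genomic span (max end - min start)
#'   of a cluster; chains are greedily split left-to-right so that no cluster
#'   exceeds it. Emulates a transcript-length constraint on clusters.
#' @param same_strand_only if `TRUE`, genes are chained only within the same
#'   strand; `"unknown"` strands form their own group.
#' @return an object of class `cluster_call`: a list with
#'   \describe{
#'     \item{genes}{the input genes (canonically sorted) plus a `cluster_id`
#'       column, `NA` for isolated genes;}
#'     \item{clusters}{one row per cluster: `cluster_id`, `chrom`, `start`,
#'       `end`, `span_bp`, `n_members`, `member_ids` (";"-joined),
#'       `n_families`, `family_entropy`, `cluster_type`;}
#'     \item{isolated}{the isolated genes;}
#'     \item{members}{named list of member id vectors per cluster;}
#'     \item{cutoff_bp, max_span_bp}{the parameters used.}
#'   }
#'   Entropy/type columns are `NA` for clusters containing unlabeled members.
#' @export
detect_clusters <- function(genes, cutoff_bp = 10000, max_span_bp = NULL,
                            same_strand_only = FALSE) {
  if (!is_count(cutoff_bp, min = 1L)) stop("cutoff_bp must be a positive integer")
  if (!is.null(max_span_bp) && !is_count(max_span_bp, min = 1L)) {
    stop("max_span_bp must be NULL or a positive integer")
  }
  genes <- as_mirna_annotation(as.data.frame(genes))
  if (nrow(genes) == 0L) {
    return(new_cluster_call(genes, integer(0), cutoff_bp, max_span_bp))
  }
  key <- if (same_strand_only) paste0(genes$chrom, "\r", genes$strand) else genes$chrom
  ord <- order(key, genes$start, genes$end, genes$id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  key <- key[ord]

  n <- nrow(genes)
  chain <- integer(n)          # provisional chain index per gene
  chain_id <- 0L
  chain_start <- NA_integer_   # first start of the open chain
  chain_maxend <- NA_integer_
  for (i in seq_len(n)) {
    new_chain <- i == 1L || key[i] != key[i - 1L]
    if (!new_chain) {
      gap <- genes$start[i] - chain_maxend          # negative => overlap
      span <- max(chain_maxend, genes$end[i]) - chain_start
      if (gap > cutoff_bp || (!is.null(max_span_bp) && span > max_span_bp)) {
        new_chain <- TRUE
      }
    }
    if (new_chain) {
      chain_id <- chain_id + 1L
      chain_start <- genes$start[i]
      chain_maxend <- genes$end[i]
    } else {
      chain_maxend <- max(chain_maxend, genes$end[i])
    }
    chain[i] <- chain_id
  }
  new_cluster_call(genes, chain, cutoff_bp, max_span_bp)
}

new_cluster_call <- function(genes, chain, cutoff_bp, max_span_bp) {
  cluster_id <- rep(NA_character_, nrow(genes))
  members <- list()
  clusters <- list()
  if (length(chain)) {
    sizes <- tabulate(chain)
    real <- which(sizes >= 2L)
    k <- 0L
    for (ch in real) {
      k <- k + 1L
      lab <- sprintf("MC%03d", k)
      idx <- which(chain == ch)
      cluster_id[idx] <- lab
      fam <- genes$family[idx]
      has_fam <- !anyNA(fam)
      members[[lab]] <- genes$id[idx]
      clusters[[lab]] <- data.frame(
        cluster_id = lab,
        chrom = genes$chrom[idx[1L]],
        start = min(genes$start[idx]),
        end = max(genes$end[idx]),
        span_bp = max(genes$end[idx]) - min(genes$start[idx]),
        n_members = length(idx),
        member_ids = paste(genes$id[idx], collapse = ";"),
        n_families = if (has_fam) length(unique(fam)) else NA_integer_,
        family_entropy = if (has_fam) family_entropy(fam) else NA_real_,
        cluster_type = if (has_fam) classify_cluster(fam) else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  genes$cluster_id <- cluster_id
  summary <- if (length(clusters)) {
    do.call(rbind, unname(clusters))
  } else {
    data.frame(
      cluster_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), span_bp = integer(0), n_members = integer(0),
      member_ids = character(0), n_families = integer(0),
      family_entropy = numeric(0), cluster_type = character(0),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      genes = genes,
      clusters = summary,
      isolated = genes[is.na(cluster_id), , drop = FALSE],
      members = members,
      cutoff_bp = as.integer(cutoff_bp),
      max_span_bp = if (is.null(max_span_bp)) NULL else as.integer(max_span_bp)
    ),
    class = "cluster_call"
  )
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf(
    "miRNA cluster call: %d clusters, %d isolated of %d genes (cutoff %d bp%s)\n",
    nrow(x$clusters), nrow(x$isolated), nrow(x$genes), x$cutoff_bp,
    if (is.null(x$max_span_bp)) "" else sprintf(", max span %d bp", x$max_span_bp)
  ))
  if (nrow(x$clusters)) {
    tp <- table(factor(x$clusters$cluster_type, levels = c("homo", "hetero")))
    cat(sprintf("  homo: %d  hetero: %d\n", tp[["homo"]], tp[["hetero"]]))
  }
  invisible(x)
}

# Normalized Shannon entropy of a label composition: -(1/ln N) sum p_i ln p_i,
# defined as 0 when a single category is present (the normalization 1/ln N is
# undefined at N = 1; 0 is the limit consistent with "all members alike").
norm_entropy <- function(labels) {
  counts <- as.numeric(table(labels))
  n_cat <- length(counts)
  if (n_cat <= 1L) return(0)
  # all-distinct compositions sit exactly at the upper boundary
  if (all(counts == 1)) return(1)
  p <- counts / sum(counts)
  # clamp away float dust so the [0, 1] range invariant holds exactly
  min(max(-sum(p * log(p)) / log(n_cat), 0), 1)
}

#' Family entropy of a miRNA cluster
#'
#' Computes the normalized family entropy
#' \deqn{E_{fam} = -\frac{1}{\ln N_{fam}} \sum_i p_i \ln p_i}
#' where \eqn{N_{fam}} is the number of distinct families among the cluster
#' members and \eqn{p_i} the fraction of members in family \eqn{i}.
#' \eqn{E_{fam} = 0} iff all members share one family, and 1 iff all members
#' come from pairwise distinct families.
#'
#' @param x character vector of family labels, one per cluster member
#'   (optionally named by member id), or a data.frame with `id` and `family`
#'   columns.
#' @return entropy in `[0, 1]`.
#' @export
family_entropy <- function(x) {
  x <- as_family_labels(x)
  norm_entropy(x)
}

#' Family composition of a cluster
#'
#' @inheritParams family_entropy
#' @return named numeric vector of family frequencies (sums to 1).
#' @export
family_probs <- function(x) {
  x <- as_family_labels(x)
  tab <- table(x)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Classify a cluster as homo or hetero
#'
#' A homo-cluster contains miRNAs of a single family (family entropy 0); a
#' hetero-cluster contains members of multiple families.
#'
#' @inheritParams family_entropy
#' @return `"homo"` or `"hetero"`.
#' @export
classify_cluster <- function(x) {
  x <- as_family_labels(x)
  if (length(unique(x)) == 1L) "homo" else "hetero"
}

as_family_labels <- function(x) {
  if (is.data.frame(x)) {
    x <- setNames(as.character(x$family), x$id)
  }
  x <- setNames(as.character(x), names(x))
  if (!length(x)) stop("no cluster members given")
  if (anyNA(x)) {
    who <- if (!is.null(names(x))) names(x)[is.na(x)] else which(is.na(x))
    stop("missing family label for member(s): ", paste(who, collapse = ", "))
  }
  x
}

#' Cluster counts across a range of distance cutoffs
#'
#' Re-runs [detect_clusters()] for each cutoff to show how stable the cluster
#' call is to the chaining distance.
#'
#' @inheritParams detect_clusters
#' @param cutoffs_bp vector of positive cutoffs in base pairs.
#' @return data.frame with columns `cutoff_bp`, `n_clusters`, `n_isolated`.
#' @export
cutoff_scan <- function(genes, cutoffs_bp, max_span_bp = NULL,
                        same_strand_only = FALSE) {
  if (!length(cutoffs_bp) || any(cutoffs_bp <= 0)) {
    stop("cutoffs_bp must be positive")
  }
  rows <- lapply(cutoffs_bp, function(cut) {
    cc <- detect_clusters(genes, cutoff_bp = cut, max_span_bp = max_span_bp,
                          same_strand_only = same_strand_only)
    data.frame(cutoff_bp = as.integer(cut), n_clusters = nrow(cc$clusters),
               n_isolated = nrow(cc$isolated))
  })
  do.call(rbind, rows)
}

#' Write cluster-call tables
#'
#' @param cc a `cluster_call`.
#' @param cluster_path TSV destination for the per-cluster table.
#' @param isolated_path TSV destination for the isolated miRNA list.
#' @return invisibly, the two paths.
#' @export
write_cluster_tables <- function(cc, cluster_path, isolated_path) {
  stopifnot(inherits(cc, "cluster_call"))
  write.table(cc$clusters, cluster_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  iso <- cc$isolated[, c("id", "chrom", "start", "end", "strand", "family")]
  write.table(iso, isolated_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(clusters = cluster_path, isolated = isolated_path))
}

# cluster assignment as a named vector id -> cluster_id (NA for isolated)
cluster_assignment <- function(cc) {
  stopifnot(inherits(cc, "cluster_call"))
  setNames(cc$genes$cluster_id, cc$genes$id)
}
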