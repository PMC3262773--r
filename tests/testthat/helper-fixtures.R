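# Small in-code fixture builders (the deliverable carries no binary data;
# everything is constructed at test time).

# annotation data.frame in the internal 0-based half-open convention
make_genes <- function(starts, chrom = "chr1", len = 80L,
                       families = NULL, strand = "+",
                       ids = sprintf("mir-%02d", seq_along(starts))) {
  data.frame(
    id = ids,
    chrom = rep_len(chrom, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts) + len,
    strand = rep_len(strand, length(starts)),
    family = rep_len(if (is.null(families)) NA_character_ else families,
                     length(starts)),
    stringsAsFactors = FALSE
  )
}

write_tmp_gff3 <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ann.gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_tmp_sif <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "net.sif")
  writeLines(lines, path)
  path
}

# a tiny typed network: TFs t1..t2, miRNAs hsa-mir-a/b, genes g1..
toy_network <- function(edges) {
  ids <- unique(c(edges$source, edges$target))
  types <- ifelse(startsWith(ids, "t"), "TF",
                  ifelse(startsWith(ids, "hsa-"), "miRNA", "gene"))
  regulatory_network(edges, node_types = setNames(types, ids))
}

edge_df <- function(...) {
  v <- c(...)
  if (!length(v)) {
    return(data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(source = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
}

# cluster_call built by running the caller on a constructed layout:
# sizes + families per cluster, isolated appended
make_cluster_call <- function(cluster_families, n_isolated = 0,
                              isolated_families = NULL,
                              ids_prefix = "hsa-mir-t") {
  starts <- integer(0)
  fams <- character(0)
  pos <- 0L
  for (f in cluster_families) {
    starts <- c(starts, pos + seq_along(f) * 1000L)
    fams <- c(fams, f)
    pos <- pos + length(f) * 1000L + 50000L
  }
  if (n_isolated > 0) {
    starts <- c(starts, pos + seq_len(n_isolated) * 50000L)
    fams <- c(fams, isolated_families %||%
                sprintf("iso-fam-%d", seq_len(n_isolated)))
  }
  genes <- make_genes(starts, families = fams,
                      ids = sprintf("%s%02d", ids_prefix, seq_along(starts)))
  detect_clusters(genes, cutoff_bp = 10000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
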