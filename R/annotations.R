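#' Read miRNA precursor annotations
#'
#' Reads precursor miRNA gene coordinates from a GFF3 or BED file and
#' optionally attaches family labels from a two-column TSV table. Coordinates
#' are normalized to the package's internal 0-based half-open convention:
#' GFF3 (1-based, closed) starts are shifted down by one, BED coordinates are
#' kept as-is.
#'
#' @param path path to a GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file. Each
#'   record is one precursor; the `ID` (or `Name`) attribute for GFF3, or the
#'   BED name column, supplies the precursor id.
#' @param family_table optional path to a TSV with header
#'   `mirna_id<TAB>family`. Precursors absent from the table get `NA` family.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return a `data.frame` of class `mirna_annotation` with columns
#'   `id`, `chrom`, `start`, `end` (0-based half-open), `strand`
#'   (`"+"`, `"-"` or `"unknown"`) and `family`.
#' @export
read_mirna_annotations <- function(path, family_table = NULL,
                                   format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      gff = , gff3 = "gff3",
      bed = "bed",
      stop("cannot guess annotation format from extension '.", ext,
           "'; pass format explicitly")
    )
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "GFF3" else "BED"),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  df <- as.data.frame(gr)
  id <- if (format == "gff3") {
    if (!is.null(df$ID) && !anyNA(df$ID)) as.character(df$ID)
    else if (!is.null(df$Name)) as.character(df$Name)
    else stop("GFF3 records carry neither ID nor Name attributes")
  } else {
    if (is.null(df$name)) stop("BED file lacks the name column")
    as.character(df$name)
  }
  strand <- as.character(df$strand)
  strand[!strand %in% c("+", "-")] <- "unknown"
  out <- data.frame(
    id = id,
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,  # rtracklayer presents 1-based starts
    end = as.integer(df$end),
    strand = strand,
    family = NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$id)) {
    stop("duplicate miRNA ids in annotation: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  if (!is.null(family_table)) {
    fam <- read_family_table(family_table)
    out$family <- fam$family[match(out$id, fam$mirna_id)]
  }
  as_mirna_annotation(out)
}

#' Read a miRNA family table
#'
#' @param path TSV file with header `mirna_id<TAB>family`.
#' @return data.frame with columns `mirna_id`, `family`.
#' @export
read_family_table <- function(path) {
  fam <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "family") %in% names(fam))) {
    stop("family table '", path, "' must have columns mirna_id and family")
  }
  if (anyDuplicated(fam$mirna_id)) {
    stop("duplicate mirna_id entries in family table '", path, "'")
  }
  fam[, c("mirna_id", "family")]
}

as_mirna_annotation <- function(df) {
  required <- c("id", "chrom", "start", "end", "strand", "family")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate miRNA ids in annotation: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("start >= end for: ", paste(df$id[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- unique(c("mirna_annotation", class(df)))
  df
}

#' Write annotations as GFF3
#'
#' Inverse of [read_mirna_annotations()]: internal 0-based half-open
#' coordinates are emitted as 1-based closed GFF3 records of type
#' `miRNA_primary_transcript` (the miRBase precursor feature type).
#'
#' @param annotation a `mirna_annotation` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(annotation, path) {
  annotation <- as_mirna_annotation(as.data.frame(annotation))
  strand <- ifelse(annotation$strand %in% c("+", "-"), annotation$strand, ".")
  lines <- sprintf(
    "%s\tmircoord\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    annotation$chrom, annotation$start + 1L, annotation$end, strand,
    annotation$id, annotation$id
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

write_family_table <- function(annotation, path) {
  df <- data.frame(mirna_id = annotation$id, family = annotation$family)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
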