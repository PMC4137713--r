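#' Read sequence records from a FASTA file
#'
#' Reads genome contigs, transcript sequences, or protein sequences.
#' Nucleotide records are normalized to uppercase DNA (U is mapped to T) so
#' that genome and transcript sequences share one comparison alphabet;
#' proteins are uppercased only.
#'
#' @param path Path to a FASTA file.
#' @param kind One of `"genome"`, `"transcript"`, `"protein"`.
#' @return A data frame with columns `id`, `sequence`, `description`
#'   (FASTA header text after the first whitespace), one row per record,
#'   in file order.
#' @export
read_sequences <- function(path, kind = c("genome", "transcript", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("no records in %s", path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  description <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(id)) {
    .stopf("duplicate identifier: %s", id[duplicated(id)][1L])
  }
  seqs <- toupper(as.character(set))
  if (kind %in% c("genome", "transcript")) {
    seqs <- chartr("U", "T", seqs)
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      .stopf("alphabet violation in record '%s' at position %d",
             id[i], bad[i])
    }
  } else {
    bad <- regexpr("[^A-Z*]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      .stopf("alphabet violation in record '%s' at position %d",
             id[i], bad[i])
    }
  }
  if (any(nchar(seqs) == 0L)) {
    .stopf("empty sequence in record '%s'", id[which(nchar(seqs) == 0L)[1L]])
  }
  data.frame(id = unname(id), sequence = unname(seqs),
             description = unname(description), stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_sequences()]; the round trip is lossless for id,
#' description and sequence.
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param rna If `TRUE`, render T as U (transcript-facing output).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, rna = FALSE) {
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  seqs <- records$sequence
  if (rna) seqs <- dna_to_rna(seqs)
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- seqs
  writeLines(out, path)
  invisible(path)
}

ANNOTATION_COLS <- c("gene_id", "genome_id", "start", "end", "strand",
                     "feature_class", "category", "pseudogene")

#' Read gene annotations
#'
#' Supports two dialects: GFF3 (1-based inclusive coordinates, converted to
#' the internal 0-based half-open convention) and a plain TSV with columns
#' `gene_id`, `genome_id`, `start`, `end`, `strand`, `feature_class`,
#' `category`, `pseudogene` (already 0-based half-open).
#'
#' @param path Annotation file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param genome Optional genome data frame (from [read_sequences()]) used
#'   to validate that every interval lies inside its contig.
#' @return Data frame with the eight columns above; `start`/`end` are
#'   0-based half-open on the forward strand.
#' @export
read_annotations <- function(path, dialect = c("tsv", "gff3"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (dialect == "tsv") {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    missing <- setdiff(ANNOTATION_COLS, names(ann))
    if (length(missing)) {
      .stopf("annotation TSV lacks columns: %s", paste(missing, collapse = ", "))
    }
    ann <- ann[ANNOTATION_COLS]
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
    ann$pseudogene <- as.logical(ann$pseudogene)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    gene_id <- if (!is.null(md$ID)) as.character(md$ID) else
      as.character(md$Name)
    category <- if (!is.null(md$category)) as.character(md$category) else
      rep("unknown", length(gr))
    pseud <- if (!is.null(md$pseudogene)) {
      tolower(as.character(md$pseudogene)) %in% c("true", "1", "yes")
    } else rep(FALSE, length(gr))
    conv <- interval_to_0based(BiocGenerics::start(gr), BiocGenerics::end(gr))
    ann <- data.frame(
      gene_id = gene_id,
      genome_id = as.character(GenomeInfoDb::seqnames(gr)),
      start = conv$start, end = conv$end,
      strand = as.character(BiocGenerics::strand(gr)),
      feature_class = as.character(md$type),
      category = ifelse(is.na(category), "unknown", category),
      pseudogene = pseud,
      stringsAsFactors = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    .stopf("bad strand symbol: %s",
           ann$strand[!ann$strand %in% c("+", "-")][1L])
  }
  if (any(is.na(ann$start)) || any(is.na(ann$end)) ||
      any(ann$start < 0L) || any(ann$start >= ann$end)) {
    .stopf("invalid interval for gene '%s'",
           ann$gene_id[which(is.na(ann$start) | is.na(ann$end) |
                               ann$start < 0L | ann$start >= ann$end)[1L]])
  }
  if (anyDuplicated(paste(ann$genome_id, ann$gene_id))) {
    .stopf("duplicate gene_id within a genome")
  }
  if (!is.null(genome)) {
    len <- stats::setNames(nchar(genome$sequence), genome$id)
    for (i in seq_len(nrow(ann))) {
      gl <- len[ann$genome_id[i]]
      if (is.na(gl) || ann$end[i] > gl) {
        .stopf("annotation outside contig: gene '%s'", ann$gene_id[i])
      }
    }
  }
  ann
}

#' Write gene annotations in the package TSV dialect
#' @param ann Annotation data frame (internal 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[ANNOTATION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# One TSV writer so every report shares formatting: tab-separated, header
# row, no quoting, deterministic column order as supplied.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write the report tables of an analysis run
#'
#' Emits one TSV per result table under `out_dir`.  All coordinates are
#' reported 1-based inclusive and transcript-side bases are rendered in RNA
#' notation (T as U).  Re-running on identical inputs produces
#' byte-identical files.
#'
#' @param results A named list of data frames, or a `plastid_run` object
#'   (see [run_analysis()]).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  if (inherits(results, "plastid_run")) results <- results$tables
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) .stopf("cannot create %s", out_dir)
  }
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_tsv(results[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Render an editing-event table for reporting: 1-based coordinates, RNA
# bases on both sides (the census is written in RNA notation throughout).
format_editing_events <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(gene_id = character(), genome_pos = integer(),
                      transcript_pos = integer(), from_base = character(),
                      to_base = character(), kind = character(),
                      gc_effect = character(), coding_effect = character(),
                      codon_index = integer(), codon_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- events
  out$genome_pos <- out$genome_pos + 1L
  out$transcript_pos <- out$transcript_pos + 1L
  out$from_base <- dna_to_rna(out$from_base)
  out$to_base <- dna_to_rna(out$to_base)
  out
}
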