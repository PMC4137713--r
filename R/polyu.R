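# 3' poly(U) tail detection and poly(U)-site annotation.  Tails are
# detected by provisionally stripping the maximal terminal U run, aligning
# the remaining body to the genomic locus, and asking whether the stripped
# run could be explained by a genomic T tract starting immediately after
# the last aligned base (the poly(U) site).

#' Detect a 3' poly(U) tail on a transcript
#'
#' The maximal terminal U(T) run is provisionally stripped (after trimming
#' any terminal A run left by oligo-d(A) priming), the body is aligned to
#' the gene's locus, and the genomic T run beginning immediately after the
#' poly(U) site is measured.  A run shorter than `min_tail` is restored to
#' the body and the call has `status = "none"`.
#'
#' @param transcript One-row data frame/list with `id`, `sequence`
#'   (mRNA sense, internal DNA alphabet).
#' @param gene Annotation row of the source gene (or a spanning row for a
#'   polycistronic transcript).
#' @param genome Contig record.
#' @param min_tail Minimum tail length called (default 5).
#' @param flank Genomic flank for the body alignment (default 400, sized
#'   to cover 3'-UTRs comfortably).
#' @return Object of class `polyu_call`: transcript/gene ids, `tail_length`,
#'   `site_genome_pos` (0-based coding-strand contig coordinate of the last
#'   aligned body base), `templated_run`, `status` (`"none"`,
#'   `"posttranscriptional"` or `"possibly_templated"`), plus the body
#'   alignment for downstream annotation.
#' @export
detect_poly_u_tail <- function(transcript, gene, genome, min_tail = 5L,
                               flank = 400L) {
  stopifnot(min_tail >= 1L)
  seq <- transcript$sequence
  a_run <- .terminal_run_length(seq, "A")
  if (a_run > 0L) seq <- substr(seq, 1L, nchar(seq) - a_run)
  run <- .terminal_run_length(seq, "T")
  tailed <- run >= min_tail
  body <- if (tailed) substr(seq, 1L, nchar(seq) - run) else seq
  if (nchar(body) == 0L) .stopf("transcript '%s' is all tail", transcript$id)

  alignment <- align_transcript_to_genome(
    list(id = transcript$id, sequence = body), gene, genome, flank = flank)
  cols <- alignment$columns
  aligned <- cols[cols$state %in% c("match", "mismatch"), , drop = FALSE]
  if (nrow(aligned) == 0L) .stopf("unalignable transcript '%s'",
                                  transcript$id)
  site <- max(aligned$gpos)
  cs <- .cs_seq(genome$sequence, gene$strand)
  templated_run <- .run_length_at(cs, site + 1L, "T")

  call <- structure(list(
    transcript_id = transcript$id,
    gene_id = gene$gene_id,
    genome_id = genome$id,
    strand = gene$strand,
    tail_length = run,
    site_genome_pos = site,
    templated_run = templated_run,
    status = "none",
    utr_length = NA_integer_,
    overlaps_downstream_cds = NA,
    internal_site = NA,
    cistron_gene_ids = character(0),
    cistron_class = NA_character_,
    alignment = alignment
  ), class = "polyu_call")
  if (tailed) call <- classify_tail_templating(call, min_tail = min_tail)
  call
}

#' Decide whether a called tail could be genomically templated
#'
#' A tail longer than the genomic T run at its site cannot have been
#' transcribed from the genome and is a post-transcriptional addition; a
#' tail no longer than the run is conservatively flagged as possibly
#' templated (such sites may arise through primer misannealing on a
#' genomic poly(T) tract).
#'
#' @param call A `polyu_call` with `tail_length >= min_tail`.
#' @param min_tail Minimum tail length (default 5).
#' @return The call with `status` filled.
#' @export
classify_tail_templating <- function(call, min_tail = 5L) {
  if (call$tail_length < min_tail) {
    call$status <- "none"
    return(call)
  }
  call$status <- if (call$tail_length > call$templated_run)
    "posttranscriptional" else "possibly_templated"
  call
}

#' Annotate a poly(U) site against the gene map
#'
#' Fills the site-context fields: `utr_length` (nucleotides from the end
#' of the source gene's stop codon to the site, 0 when the site is the
#' last base of the UTR immediately after the stop codon; negative when
#' the site lies inside the source CDS, flagged `internal_site`),
#' `overlaps_downstream_cds` (site inside a same-strand downstream CDS),
#' and the cistron content (same-strand genes whose CDS intersects the
#' aligned transcript body, in genomic order).
#'
#' @param call A `polyu_call` from [detect_poly_u_tail()].
#' @param annotations Annotation data frame for the contig.
#' @return The call with site fields filled.
#' @export
annotate_poly_u_site <- function(call, annotations) {
  ann <- annotations[annotations$genome_id == call$genome_id &
                       annotations$strand == call$strand, , drop = FALSE]
  if (nrow(ann) == 0L) .stopf("no same-strand annotations for contig '%s'",
                              call$genome_id)
  contig_len <- call$alignment$contig_length
  iv <- t(vapply(seq_len(nrow(ann)),
                 function(i) .cs_interval(ann[i, , drop = FALSE], contig_len),
                 numeric(2)))
  ord <- order(iv[, 1])
  ann <- ann[ord, , drop = FALSE]
  iv <- iv[ord, , drop = FALSE]

  src <- which(ann$gene_id == call$gene_id)
  if (length(src) != 1L) .stopf("source gene '%s' not in annotations",
                                call$gene_id)
  site <- call$site_genome_pos
  call$utr_length <- as.integer(site - iv[src, 2] + 1L)
  call$internal_site <- call$utr_length < 0L

  is_cds <- ann$feature_class == "CDS"
  downstream <- iv[, 1] > iv[src, 1]
  call$overlaps_downstream_cds <- any(
    is_cds & downstream & site >= iv[, 1] & site < iv[, 2])

  aligned <- call$alignment$columns
  aligned <- aligned[aligned$state %in% c("match", "mismatch"), , drop = FALSE]
  body_start <- min(aligned$gpos)
  hit <- iv[, 1] < site + 1L & iv[, 2] > body_start & is_cds
  call$cistron_gene_ids <- ann$gene_id[hit]
  k <- sum(hit)
  call$cistron_class <- if (k <= 0L) NA_character_
  else if (k <= 3L) c("monocistronic", "dicistronic", "tricistronic")[k]
  else sprintf("%d-cistronic", k)
  call
}

#' @export
print.polyu_call <- function(x, ...) {
  cat(sprintf("<polyu_call> %s (gene %s): tail %d nt, site %d (cs), T-run %d, %s\n",
              x$transcript_id, x$gene_id, x$tail_length,
              x$site_genome_pos + 1L, x$templated_run, x$status))
  if (!is.na(x$utr_length)) {
    cat(sprintf("  UTR %d nt%s; cistron: %s (%s)\n", x$utr_length,
                if (isTRUE(x$internal_site)) " [internal site]" else "",
                paste(x$cistron_gene_ids, collapse = ","), x$cistron_class))
  }
  invisible(x)
}

#' GC and purine composition of a sequence
#'
#' @param sequence Nucleotide string; N bases are excluded from the
#'   denominators.
#' @return List of class `composition_stats` with `gc_fraction`,
#'   `purine_fraction` and `length` (non-N length).
#' @export
composition_stats <- function(sequence) {
  if (nchar(sequence) == 0L) .stopf("empty sequence")
  s <- .norm_nt(sequence)
  n <- vapply(c(DNA_BASES, "N"), function(b) {
    lengths(regmatches(s, gregexpr(b, s, fixed = TRUE)))
  }, integer(1))
  tot <- sum(n[DNA_BASES])
  if (tot == 0L) .stopf("undefined composition: sequence is all N")
  structure(list(
    gc_fraction = (n[["G"]] + n[["C"]]) / tot,
    purine_fraction = (n[["A"]] + n[["G"]]) / tot,
    length = tot
  ), class = "composition_stats")
}
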