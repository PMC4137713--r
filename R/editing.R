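# Substitutional editing: event calling from transcript/genome alignments,
# per-event classification (transition/transversion, GC effect, coding
# consequence under genetic code 11), the census table, premature-stop
# detection/correction, and the paralog discrimination test.

#' Classify a substitution as transition or transversion
#' @param from,to Single bases (DNA alphabet, mRNA sense).
#' @return `"transition"` or `"transversion"`.
#' @export
substitution_kind <- function(from, to) {
  purine <- c("A", "G")
  ifelse((from %in% purine) == (to %in% purine), "transition", "transversion")
}

#' Classify the GC effect of a substitution
#' @param from,to Single bases (DNA alphabet).
#' @return `"enrich"`, `"deplete"` or `"neutral"`.
#' @export
gc_effect <- function(from, to) {
  at <- c("A", "T")
  ifelse(from %in% at & !(to %in% at), "enrich",
         ifelse(!(from %in% at) & to %in% at, "deplete", "neutral"))
}

#' Fill the classification fields of an editing event
#'
#' `kind` and `gc_effect` are pure functions of the base pair; the coding
#' effect comes from in-silico translation of the genomic versus edited
#' codon under the bacterial/plastid genetic code (table 11).
#'
#' @param event One-row data frame with at least `from_base`, `to_base`.
#' @param genomic_codon,edited_codon 3-mers for CDS events; pass `NULL`
#'   for noncoding (UTR) events.
#' @return The event row with `kind`, `gc_effect`, `coding_effect` filled.
#'   A codon containing N yields `coding_effect = "indeterminate"`.
#' @export
classify_editing_event <- function(event, genomic_codon = NULL,
                                   edited_codon = NULL) {
  event$kind <- substitution_kind(event$from_base, event$to_base)
  event$gc_effect <- gc_effect(event$from_base, event$to_base)
  if (is.null(genomic_codon) || is.null(edited_codon)) {
    event$coding_effect <- "noncoding"
    return(event)
  }
  aa_g <- translate_codon(genomic_codon)
  aa_e <- translate_codon(edited_codon)
  event$coding_effect <-
    if (is.na(aa_g) || is.na(aa_e)) "indeterminate"
    else if (.is_stop_codon(genomic_codon) && !.is_stop_codon(edited_codon))
      "stop_loss"
    else if (!.is_stop_codon(genomic_codon) && .is_stop_codon(edited_codon))
      "stop_gain"
    else if (aa_g == aa_e) "synonymous"
    else "nonsynonymous"
  event
}

.empty_events <- function() {
  data.frame(gene_id = character(), genome_pos = integer(),
             transcript_pos = integer(), from_base = character(),
             to_base = character(), kind = character(),
             gc_effect = character(), coding_effect = character(),
             codon_index = integer(), codon_pos = integer(),
             stringsAsFactors = FALSE)
}

#' Call substitutional editing events from an alignment
#'
#' One event per mismatch column whose bases are both in \{A,C,G,T\}.
#' Insertion/deletion columns are never events (editing is substitutional;
#' indels between transcript and genome are genomic features and are
#' reported separately via the alignment's column table).  Columns
#' involving N are skipped and counted in the `masked` attribute.
#'
#' @param alignment A `pairwise_alignment` from
#'   [align_transcript_to_genome()].
#' @param gene The gene annotation row the events belong to.  Events whose
#'   genomic position falls outside the gene's interval are classified
#'   `noncoding` (UTR); positions are reported 0-based relative to the
#'   gene's coding-strand start (negative in the 5' flank).
#' @return Data frame of classified events; attribute `masked` holds the
#'   number of N-involving mismatch columns skipped.
#' @export
call_editing_events <- function(alignment, gene) {
  cols <- alignment$columns
  mm <- cols[cols$state == "mismatch", , drop = FALSE]
  masked <- sum(!(mm$tbase %in% DNA_BASES) | !(mm$gbase %in% DNA_BASES))
  mm <- mm[mm$tbase %in% DNA_BASES & mm$gbase %in% DNA_BASES, , drop = FALSE]
  gi <- .cs_interval(gene, alignment$contig_length)
  gene_len <- gi[2] - gi[1]
  if (nrow(mm) == 0L) {
    ev <- .empty_events()
    attr(ev, "masked") <- masked
    return(ev)
  }
  rel <- mm$gpos - gi[1]
  in_cds <- gene$feature_class == "CDS" & rel >= 0L & rel < gene_len
  ev <- data.frame(
    gene_id = gene$gene_id,
    genome_pos = rel,
    transcript_pos = mm$tpos,
    from_base = mm$gbase,
    to_base = mm$tbase,
    kind = NA_character_, gc_effect = NA_character_,
    coding_effect = NA_character_,
    codon_index = ifelse(in_cds, rel %/% 3L, NA_integer_),
    codon_pos = ifelse(in_cds, rel %% 3L, NA_integer_),
    stringsAsFactors = FALSE)

  # Edited codon = genomic codon with *all* called events in that codon
  # applied, so co-edited codons (e.g. TGA -> CAA) translate correctly.
  for (i in seq_len(nrow(ev))) {
    if (!in_cds[i]) {
      ev[i, ] <- classify_editing_event(ev[i, , drop = FALSE])
      next
    }
    cstart <- gi[1] + ev$codon_index[i] * 3L          # contig cs coords
    woff <- cstart - alignment$window_start            # 0-based in window
    gcodon <- substr(alignment$window_seq, woff + 1L, woff + 3L)
    if (nchar(gcodon) < 3L) {
      ev[i, ] <- classify_editing_event(ev[i, , drop = FALSE])
      next
    }
    ecodon <- strsplit(gcodon, "")[[1]]
    peers <- which(in_cds & ev$codon_index == ev$codon_index[i])
    for (j in peers) ecodon[ev$codon_pos[j] + 1L] <- ev$to_base[j]
    ev[i, ] <- classify_editing_event(ev[i, , drop = FALSE], gcodon,
                                      paste(ecodon, collapse = ""))
  }
  attr(ev, "masked") <- masked
  ev
}

#' Tally editing events into a 12-type census
#'
#' Produces the census structure used to summarize an editing survey: the
#' 12 substitution-type counts (RNA notation, fixed order A-C ... U-G),
#' the editing rate over the surveyed length, and the percentage breakdown
#' by kind, GC effect and coding consequence.
#'
#' @param events Data frame of classified events (from
#'   [call_editing_events()]), or `NULL` when using `counts`.
#' @param surveyed_length Total transcript nucleotides surveyed (> 0).
#' @param counts Alternative input: a named or ordered 12-vector of
#'   per-type counts (order `A-C, A-G, A-U, C-A, C-G, C-U, G-A, G-C, G-U,
#'   U-A, U-C, U-G`).  Coding-consequence percentages are then `NA` since
#'   codon context is unavailable.
#' @param total_events Denominator for the category percentages; defaults
#'   to `sum(counts)` (or `nrow(events)`).  Published census tables
#'   sometimes print a curated total differing from the column sums; pass
#'   it here to reproduce such a table's percentage rows as printed.
#' @return An object of class `editing_summary`; percentages are stored at
#'   full precision, with a `rounded` element holding the half-away-from-
#'   zero rounding at 1 decimal (2 for the editing rate).
#' @export
summarize_editing <- function(events = NULL, surveyed_length,
                              counts = NULL, total_events = NULL) {
  if (surveyed_length <= 0) .stopf("surveyed_length must be > 0")
  pct_nonsyn <- pct_syn <- NA_real_
  if (is.null(counts)) {
    stopifnot(is.data.frame(events))
    type <- paste(dna_to_rna(events$from_base), dna_to_rna(events$to_base),
                  sep = "-")
    counts <- vapply(EDIT_TYPES, function(t) sum(type == t), integer(1))
    cds <- events$coding_effect %in%
      c("synonymous", "nonsynonymous", "stop_loss", "stop_gain")
    n_cds <- sum(cds)
    if (n_cds > 0L) {
      n_syn <- sum(events$coding_effect == "synonymous")
      pct_syn <- 100 * n_syn / n_cds
      pct_nonsyn <- 100 * (n_cds - n_syn) / n_cds
    }
  } else {
    if (length(counts) != 12L) .stopf("counts must have 12 elements")
    counts <- stats::setNames(as.integer(counts), EDIT_TYPES)
  }
  if (is.null(total_events)) total_events <- sum(counts)
  from <- substr(EDIT_TYPES, 1L, 1L)
  to <- substr(EDIT_TYPES, 3L, 3L)
  is_transition <- EDIT_TYPES %in% c("A-G", "G-A", "C-U", "U-C")
  at <- c("A", "U")
  enrich <- from %in% at & !(to %in% at)
  deplete <- !(from %in% at) & to %in% at
  pct <- function(k) if (total_events > 0) 100 * k / total_events else 0
  out <- list(
    counts = counts,
    total_events = total_events,
    surveyed_length = surveyed_length,
    pct_bases_edited = 100 * total_events / surveyed_length,
    pct_transitions = pct(sum(counts[is_transition])),
    pct_transversions = pct(sum(counts[!is_transition])),
    pct_gc_enrich = pct(sum(counts[enrich])),
    pct_gc_deplete = pct(sum(counts[deplete])),
    pct_gc_neutral = pct(sum(counts[!enrich & !deplete])),
    pct_nonsynonymous = pct_nonsyn,
    pct_synonymous = pct_syn)
  out$rounded <- c(
    pct_bases_edited = round_half_up(out$pct_bases_edited, 2),
    pct_transitions = round_half_up(out$pct_transitions, 1),
    pct_transversions = round_half_up(out$pct_transversions, 1),
    pct_gc_enrich = round_half_up(out$pct_gc_enrich, 1),
    pct_gc_deplete = round_half_up(out$pct_gc_deplete, 1),
    pct_gc_neutral = round_half_up(out$pct_gc_neutral, 1),
    pct_nonsynonymous = round_half_up(out$pct_nonsynonymous, 1),
    pct_synonymous = round_half_up(out$pct_synonymous, 1))
  class(out) <- "editing_summary"
  out
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("<editing_summary>\n")
  cat(sprintf("  %d events over %d nt (%.2f%% of bases edited)\n",
              x$total_events, x$surveyed_length, x$pct_bases_edited))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = " "), "\n")
  cat(sprintf("  transitions %.1f%% / transversions %.1f%%\n",
              x$pct_transitions, x$pct_transversions))
  cat(sprintf("  GC enrich %.1f%% / deplete %.1f%% / neutral %.1f%%\n",
              x$pct_gc_enrich, x$pct_gc_deplete, x$pct_gc_neutral))
  if (!is.na(x$pct_nonsynonymous)) {
    cat(sprintf("  nonsynonymous %.1f%% / synonymous %.1f%%\n",
                x$pct_nonsynonymous, x$pct_synonymous))
  }
  invisible(x)
}

#' Detect premature in-frame termination codons in a genomic CDS
#'
#' Scans the annotated reading frame for TAA/TAG/TGA strictly before the
#' final codon.  A CDS whose length is not a multiple of 3 is flagged with
#' a warning and scanned in the annotated frame.
#'
#' @param gene CDS annotation row.
#' @param genome Contig record (list/data frame row with `id`, `sequence`).
#' @return Data frame with `codon_index` (0-based) and `stop_codon`.
#' @export
detect_premature_stops <- function(gene, genome) {
  if (gene$feature_class != "CDS") .stopf("gene '%s' is not a CDS",
                                          gene$gene_id)
  contig_len <- nchar(genome$sequence)
  cs <- .cs_seq(genome$sequence, gene$strand)
  gi <- .cs_interval(gene, contig_len)
  cds <- substr(cs, gi[1] + 1L, gi[2])
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    .warnf("CDS length of '%s' not a multiple of 3; scanning annotated frame",
           gene$gene_id)
  }
  n_codon <- n %/% 3L
  idx <- integer(0); cdn <- character(0)
  for (k in seq_len(max(0L, n_codon - 1L)) - 1L) {
    codon <- substr(cds, 3L * k + 1L, 3L * k + 3L)
    if (.is_stop_codon(codon)) {
      idx <- c(idx, k); cdn <- c(cdn, codon)
    }
  }
  data.frame(codon_index = idx, stop_codon = cdn, stringsAsFactors = FALSE)
}

#' Check whether premature stops are corrected in the transcript
#'
#' For every premature genomic stop codon, reads the transcript bases
#' aligned to the three codon positions: `corrected` if they form a
#' non-stop codon, `uncorrected` if still a stop, `uncovered` if the
#' transcript does not span the codon (or an indel disrupts it).
#'
#' @param gene CDS annotation row.
#' @param genome Contig record.
#' @param alignment `pairwise_alignment` of the gene's transcript.
#' @return Data frame with `codon_index`, `stop_codon`, `transcript_codon`
#'   (RNA notation, `NA` if uncovered) and `status`.
#' @export
verify_stop_correction <- function(gene, genome, alignment) {
  stops <- detect_premature_stops(gene, genome)
  gi <- .cs_interval(gene, alignment$contig_length)
  cols <- alignment$columns
  aligned <- cols[cols$state %in% c("match", "mismatch"), , drop = FALSE]
  status <- character(nrow(stops))
  tcodon <- character(nrow(stops))
  for (i in seq_len(nrow(stops))) {
    gpos <- gi[1] + stops$codon_index[i] * 3L + 0:2
    hit <- match(gpos, aligned$gpos)
    if (anyNA(hit)) {
      status[i] <- "uncovered"; tcodon[i] <- NA_character_
    } else {
      codon <- paste(aligned$tbase[hit], collapse = "")
      tcodon[i] <- dna_to_rna(codon)
      status[i] <- if (.is_stop_codon(codon)) "uncorrected" else "corrected"
    }
  }
  stops$transcript_codon <- tcodon
  stops$status <- status
  stops
}

#' Paralog discrimination by editing depletion
#'
#' Tests whether a paralog's transcript shows significantly fewer editing
#' events than expected from a reference paralog's editing rate over a
#' comparable region: with null rate p0 = `k_ref / len_b`, returns the
#' exact one-sided binomial probability P(X <= `k_obs`) for
#' X ~ Binomial(`len_a`, p0).  Used to distinguish pseudogene transcripts
#' (near-zero editing) from their functional counterparts.
#'
#' @param k_obs Events observed on the tested paralog.
#' @param len_a Surveyed length of the tested paralog (nt).
#' @param k_ref Events observed on the reference paralog.
#' @param len_b Surveyed length of the reference paralog (nt).
#' @return One-sided p-value (lower tail).
#' @export
paralog_discrimination_test <- function(k_obs, len_a, k_ref, len_b) {
  if (len_a <= 0 || len_b <= 0) .stopf("lengths must be positive")
  if (k_ref < 0 || k_obs < 0) .stopf("counts must be non-negative")
  p0 <- k_ref / len_b
  if (p0 == 0) {
    if (k_obs > 0) {
      .warnf("reference editing rate is zero; depletion p-value is 0")
      return(0)
    }
    return(1)
  }
  stats::pbinom(k_obs, size = len_a, prob = p0)
}
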