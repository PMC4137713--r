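# Transcript-to-genome alignment.  Editing in these plastids is dense (up
# to ~24% of residues in the most divergent genes), so the scoring scheme
# keeps mismatches cheap relative to gaps: a run of edits must never be
# absorbed into an indel.  Biostrings does the dynamic programming; this
# module owns the windowing, strand handling and column bookkeeping.

# Substitution matrix over {A,C,G,T,N}: match +2, mismatch -1, N neutral.
.nt_matrix <- function() {
  m <- matrix(-1, 5, 5,
              dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align a transcript to its genomic locus
#'
#' Extracts the coding-strand genomic window of the gene (plus `flank`
#' nucleotides on each side, to capture UTRs) and aligns the transcript
#' globally against it with affine gap penalties and free end gaps on the
#' genomic side.  Any 3' poly(U) tail should be stripped beforehand (see
#' [detect_poly_u_tail()]), since a non-templated tail is not part of the
#' genomic locus.
#'
#' @param transcript One-row data frame (or list) with `id` and `sequence`.
#' @param gene One-row annotation data frame; for a polycistronic
#'   transcript pass a synthetic row spanning all member genes.
#' @param genome One-row data frame (or list) with `id` and `sequence` for
#'   the gene's contig.
#' @param flank Nucleotides of genomic context added on each side of the
#'   gene interval (default 200).
#' @param min_identity Identity floor (matches / transcript length) below
#'   which the transcript is rejected as unalignable (default 0.6, i.e. a
#'   transcript is allowed to differ at up to 40% of positions before it is
#'   treated as a wrong locus assignment).
#' @return An object of class `pairwise_alignment`: a list with the ids,
#'   strand, score, identity, the extracted window (coding-strand sequence
#'   and its coding-strand offset) and a `columns` data frame with one row
#'   per alignment column (`tpos`, `gpos` 0-based coding-strand contig
#'   coordinate, `tbase`, `gbase`, `state` in match/mismatch/insertion/
#'   deletion).
#' @export
align_transcript_to_genome <- function(transcript, gene, genome,
                                       flank = 200L, min_identity = 0.6) {
  stopifnot(flank >= 0L)
  contig_len <- nchar(genome$sequence)
  cs <- .cs_seq(genome$sequence, gene$strand)
  gi <- .cs_interval(gene, contig_len)
  w0 <- max(0L, gi[1] - as.integer(flank))
  w1 <- min(contig_len, gi[2] + as.integer(flank))
  window <- substr(cs, w0 + 1L, w1)

  aln <- Biostrings::pairwiseAlignment(
    pattern = transcript$sequence, subject = window,
    type = "global-local", substitutionMatrix = .nt_matrix(),
    gapOpening = 8, gapExtension = 2)

  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sub_start <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based in window

  n <- length(pat)
  tpos <- gpos <- rep(NA_integer_, n)
  ti <- -1L
  gi0 <- sub_start - 1L
  state <- character(n)
  for (i in seq_len(n)) {
    p_gap <- pat[i] == "-"
    s_gap <- sub[i] == "-"
    if (!p_gap) { ti <- ti + 1L; tpos[i] <- ti }
    if (!s_gap) { gi0 <- gi0 + 1L; gpos[i] <- w0 + gi0 }
    state[i] <- if (p_gap && s_gap) "empty"
    else if (p_gap) "deletion"
    else if (s_gap) "insertion"
    else if (pat[i] == sub[i]) "match" else "mismatch"
  }
  cols <- data.frame(tpos = tpos, gpos = gpos, tbase = pat, gbase = sub,
                     state = state, stringsAsFactors = FALSE)
  cols <- cols[cols$state != "empty", , drop = FALSE]

  identity <- sum(cols$state == "match") / nchar(transcript$sequence)
  if (identity < min_identity) {
    .stopf("unalignable transcript '%s' (identity %.2f < %.2f)",
           transcript$id, identity, min_identity)
  }
  structure(list(
    transcript_id = transcript$id,
    gene_id = gene$gene_id,
    genome_id = genome$id,
    strand = gene$strand,
    contig_length = contig_len,
    score = Biostrings::score(aln),
    identity = identity,
    window_start = w0,          # coding-strand offset of the window
    window_seq = window,
    columns = cols
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s (%s strand %s)\n",
              x$transcript_id, x$gene_id, x$genome_id, x$strand))
  tab <- table(x$columns$state)
  cat(sprintf("  score %.1f, identity %.3f; columns: %s\n", x$score,
              x$identity,
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}
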