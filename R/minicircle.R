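# Minicircle detection: an assembled contig represents a circular episomal
# element when its two ends share an identical sequence (the assembler
# walks around the circle and re-reads its own start).  The circle is the
# contig with the redundant suffix removed; restriction sites are mapped
# with wrap-around.

#' Detect terminal redundancy of a contig
#'
#' Finds the longest exact suffix-prefix self-match of length at least
#' `min_overlap`.  A match flags the contig as circular with circle length
#' `contig length - overlap`.
#'
#' @param contig One-row data frame/list with `id` and `sequence`.
#' @param min_overlap Minimum overlap accepted as evidence of circularity
#'   (default 20 nt, making chance end-identity negligible at plastid
#'   contig sizes).
#' @return Object of class `minicircle_call` with `contig_id`,
#'   `is_circular`, `terminal_overlap`, `circle_length`, the unrotated
#'   `circle_sequence`, and empty canonical fields (see
#'   [canonicalize_circle()]).
#' @export
detect_terminal_redundancy <- function(contig, min_overlap = 20L) {
  stopifnot(min_overlap >= 1L)
  s <- contig$sequence
  L <- nchar(s)
  overlap <- 0L
  for (len in seq.int(L - 1L, min_overlap)) {
    if (len < min_overlap) break
    if (substr(s, L - len + 1L, L) == substr(s, 1L, len)) {
      overlap <- len
      break
    }
  }
  if (overlap > 0L && 2L * overlap >= L) {
    .stopf("degenerate repeat: contig '%s' is a (near-)perfect duplication",
           contig$id)
  }
  is_circular <- overlap >= min_overlap
  structure(list(
    contig_id = contig$id,
    is_circular = is_circular,
    terminal_overlap = overlap,
    circle_length = if (is_circular) L - overlap else NA_integer_,
    circle_sequence = if (is_circular) substr(s, 1L, L - overlap) else
      NA_character_,
    canonical_sequence = NA_character_,
    rotation_anchor = NA_character_
  ), class = "minicircle_call")
}

#' @export
print.minicircle_call <- function(x, ...) {
  if (x$is_circular) {
    cat(sprintf(
      "<minicircle_call> %s: circular, %d nt circle (terminal overlap %d nt), anchor %s\n",
      x$contig_id, x$circle_length, x$terminal_overlap,
      x$rotation_anchor %||% "unset"))
  } else {
    cat(sprintf("<minicircle_call> %s: not circular\n", x$contig_id))
  }
  invisible(x)
}

.rotate <- function(s, k) {
  # rotation starting at 0-based position k
  n <- nchar(s)
  k <- k %% n
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

.min_rotation <- function(s) {
  n <- nchar(s)
  dbl <- paste0(s, s)
  best <- 1L
  for (i in 2L:n) {
    cand <- substr(dbl, i, i + n - 1L)
    if (cand < substr(dbl, best, best + n - 1L)) best <- i
  }
  list(sequence = substr(dbl, best, best + n - 1L), start = best - 1L)
}

#' Canonical rotation of a detected circle
#'
#' Rotates the circle so that it starts at the 5' end of an annotated core
#' gene when an annotation on the circle is supplied, and otherwise at the
#' lexicographically smallest rotation of the input strand.  The result is
#' invariant to the rotation of the input contig.
#'
#' @param call A circular `minicircle_call`.
#' @param annotations Optional annotation data frame; the first gene whose
#'   interval lies within the circle is used as the anchor.
#' @return The call with `canonical_sequence` and `rotation_anchor` filled.
#' @export
canonicalize_circle <- function(call, annotations = NULL) {
  if (!isTRUE(call$is_circular)) .stopf("contig '%s' is not circular",
                                        call$contig_id)
  s <- call$circle_sequence
  anchor <- NULL
  if (!is.null(annotations)) {
    ann <- annotations[annotations$genome_id == call$contig_id, , drop = FALSE]
    ann <- ann[ann$end <= call$circle_length, , drop = FALSE]
    if (nrow(ann) >= 1L) {
      anchor <- ann[1L, , drop = FALSE]
    } else {
      .warnf("no annotation on circle '%s'; using lexicographic rotation",
             call$contig_id)
    }
  }
  if (!is.null(anchor)) {
    k <- if (anchor$strand == "+") anchor$start else anchor$end - 1L
    call$canonical_sequence <- .rotate(s, k)
    call$rotation_anchor <- paste0("gene:", anchor$gene_id)
  } else {
    mr <- .min_rotation(s)
    call$canonical_sequence <- mr$sequence
    call$rotation_anchor <- "lexicographic"
  }
  call
}

#' Map restriction sites on a circle
#'
#' Scans the canonical circle (falling back to the unrotated circle) on
#' both strands, with wrap-around across the circular junction.
#' Palindromic motifs (e.g. the EcoRI site GAATTC) are reported once per
#' position on the forward strand.
#'
#' @param call A circular `minicircle_call`.
#' @param motif Recognition motif over \{A,C,G,T\} (default `"GAATTC"`).
#' @return Data frame with `motif`, `position` (0-based on the circle) and
#'   `strand`.
#' @export
find_restriction_sites <- function(call, motif = "GAATTC") {
  if (!isTRUE(call$is_circular)) .stopf("contig '%s' is not circular",
                                        call$contig_id)
  motif <- .norm_nt(motif)
  if (grepl("[^ACGT]", motif)) .stopf("motif must be over A,C,G,T")
  circ <- if (!is.na(call$canonical_sequence)) call$canonical_sequence else
    call$circle_sequence
  L <- nchar(circ)
  m <- nchar(motif)
  if (m > L) .stopf("motif longer than circle")
  dbl <- paste0(circ, substr(circ, 1L, m - 1L))
  scan <- function(pat) {
    hits <- Biostrings::start(
      Biostrings::matchPattern(pat, Biostrings::DNAString(dbl))) - 1L
    hits[hits < L]
  }
  fwd <- scan(motif)
  rc <- .revcomp(motif)
  out <- data.frame(motif = character(0), position = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  if (length(fwd)) {
    out <- rbind(out, data.frame(motif = motif, position = fwd,
                                 strand = "+", stringsAsFactors = FALSE))
  }
  if (rc != motif) {
    rev_hits <- scan(rc)
    if (length(rev_hits)) {
      out <- rbind(out, data.frame(motif = motif, position = rev_hits,
                                   strand = "-", stringsAsFactors = FALSE))
    }
  }
  out[order(out$position), , drop = FALSE]
}
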