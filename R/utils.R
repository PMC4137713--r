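# Internal helpers shared across modules: alphabet normalization, strand
# arithmetic, coordinate conversions, and the rounding convention used in
# all printed percentages.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# The 12 substitution types in fixed census order, mRNA (RNA) notation.
EDIT_TYPES <- c("A-C", "A-G", "A-U", "C-A", "C-G", "C-U",
                "G-A", "G-C", "G-U", "U-A", "U-C", "U-G")

#' @importFrom Biostrings DNAString reverseComplement getGeneticCode
NULL

.revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Normalize a nucleotide string: uppercase, RNA U -> internal DNA T.
.norm_nt <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Render internal DNA as RNA for transcript-facing output.
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# Round half away from zero at `digits` decimals.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 0-based half-open internal interval <-> 1-based inclusive reported.
interval_to_1based <- function(start0, end0) {
  stopifnot(all(start0 < end0))
  list(start = start0 + 1L, end = end0)
}

interval_to_0based <- function(start1, end1) {
  stopifnot(all(start1 <= end1), all(start1 >= 1L))
  list(start = start1 - 1L, end = end1)
}

# Coding-strand coordinate of a forward-strand position:
# "+" genes use forward coordinates; "-" genes count from the other end.
.cs_pos <- function(pos_fwd, strand, contig_len) {
  if (strand == "+") pos_fwd else contig_len - 1L - pos_fwd
}

# Coding-strand half-open interval of a gene annotation row.
.cs_interval <- function(gene, contig_len) {
  if (gene$strand == "+") {
    c(gene$start, gene$end)
  } else {
    c(contig_len - gene$end, contig_len - gene$start)
  }
}

# Full contig sequence in the coding-strand orientation of `strand`.
.cs_seq <- function(sequence, strand) {
  if (strand == "+") sequence else .revcomp(sequence)
}

# Translation table 11 (bacterial/plastid); codons with N -> NA.
translate_codon <- function(codon) {
  code <- Biostrings::getGeneticCode("11")
  vapply(toupper(codon), function(cd) {
    if (nchar(cd) != 3L || grepl("[^ACGT]", cd)) return(NA_character_)
    unname(code[cd])
  }, character(1), USE.NAMES = FALSE)
}

.is_stop_codon <- function(codon) toupper(codon) %in% STOP_CODONS

# Length of the run of `base` starting at 0-based position `from` in `s`.
.run_length_at <- function(s, from, base) {
  n <- nchar(s)
  if (from < 0L || from >= n) return(0L)
  k <- 0L
  while (from + k < n && substr(s, from + k + 1L, from + k + 1L) == base) {
    k <- k + 1L
  }
  k
}

# Length of the maximal terminal run of `base` in `s`.
.terminal_run_length <- function(s, base) {
  n <- nchar(s)
  k <- 0L
  while (k < n && substr(s, n - k, n - k) == base) k <- k + 1L
  k
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
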