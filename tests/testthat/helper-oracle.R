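# Test helpers: independent alignment oracle and tiny fixture builders.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent affine-gap global alignment score (Gotoh three-state DP,
# written from the recurrences; a gap of length L costs open + L * ext).
oracle_global_affine <- function(p, s, match = 2, mismatch = -1,
                                 open = 8, ext = 2) {
  pp <- strsplit(p, "")[[1]]
  ss <- strsplit(s, "")[[1]]
  n <- length(pp); m <- length(ss)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)  # gap in subject
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)  # gap in pattern
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (pp[i] == ss[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Pattern-global / subject-local score: best over all subject substrings.
oracle_global_local <- function(p, s, ...) {
  m <- nchar(s)
  best <- -Inf
  for (i in seq_len(m)) {
    for (j in seq.int(i, m)) {
      best <- max(best, oracle_global_affine(p, substr(s, i, j), ...))
    }
  }
  best
}

# One-gene fixture: genome with the CDS embedded mid-contig on `strand`,
# returning the pieces tests need.
toy_locus <- function(cds, strand = "+", left = 30L, right = 30L,
                      gene_id = "g1") {
  lf <- random_dna(left)
  rf <- random_dna(right)
  fwd <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genome <- data.frame(id = "chr", sequence = paste0(lf, fwd, rf),
                       description = "", stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = gene_id, genome_id = "chr",
                     start = left, end = left + nchar(cds), strand = strand,
                     feature_class = "CDS", category = "photosynthesis",
                     pseudogene = FALSE, stringsAsFactors = FALSE)
  list(genome = genome, gene = gene, cds = cds)
}

as_record <- function(id, sequence) {
  data.frame(id = id, sequence = sequence, description = "",
             stringsAsFactors = FALSE)
}

write_fasta_tmp <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# small synthetic data set shared by recovery tests (kept below default
# size for speed; acceptance tests use the full default configuration)
small_config <- function(seed = 11L) {
  synthetic_config(seed = seed, n_genes = 12L, n_premature_stops = 4L,
                   n_pseudogenes = 1L, n_polycistronic = 1L)
}
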