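# Classification rules, the census, stop-codon correction and the paralog
# discrimination test.

test_that("transition/transversion and GC-effect follow the substitution rules", {
  expect_equal(substitution_kind("A", "G"), "transition")
  expect_equal(substitution_kind("C", "T"), "transition")
  expect_equal(substitution_kind("G", "C"), "transversion")
  expect_equal(gc_effect("A", "G"), "enrich")
  expect_equal(gc_effect("G", "C"), "neutral")
  expect_equal(gc_effect("C", "T"), "deplete")
  # exhaustive check against the rule stated directly
  for (f in c("A", "C", "G", "T")) for (t in setdiff(c("A", "C", "G", "T"), f)) {
    pur <- c("A", "G")
    expect_equal(substitution_kind(f, t) == "transition",
                 (f %in% pur) == (t %in% pur))
    at <- c("A", "T")
    expected <- if (f %in% at && !(t %in% at)) "enrich"
    else if (!(f %in% at) && t %in% at) "deplete" else "neutral"
    expect_equal(gc_effect(f, t), expected)
  }
})

test_that("coding effects come from table-11 translation, including TGA->CAA stop loss", {
  ev <- function(f, t) data.frame(from_base = f, to_base = t,
                                  kind = NA, gc_effect = NA,
                                  coding_effect = NA,
                                  stringsAsFactors = FALSE)
  # TGA edited at codon positions 1 and 2 to CAA (glutamine): both events
  # are stop_loss
  e1 <- classify_editing_event(ev("T", "C"), "TGA", "CAA")
  e2 <- classify_editing_event(ev("G", "A"), "TGA", "CAA")
  expect_equal(e1$coding_effect, "stop_loss")
  expect_equal(e2$coding_effect, "stop_loss")
  expect_equal(plastidproc:::translate_codon("CAA"), "Q")

  expect_equal(classify_editing_event(ev("T", "C"), "TTA", "CTA")$coding_effect,
               "synonymous")  # Leu -> Leu
  expect_equal(classify_editing_event(ev("A", "G"), "AAA", "AGA")$coding_effect,
               "nonsynonymous")
  expect_equal(classify_editing_event(ev("C", "T"), "CGA", "TGA")$coding_effect,
               "stop_gain")
  expect_equal(classify_editing_event(ev("A", "G"))$coding_effect, "noncoding")
  expect_equal(classify_editing_event(ev("A", "G"), "ANA", "GNA")$coding_effect,
               "indeterminate")
})

test_that("event calling reports mismatches with codon arithmetic on both strands", {
  set.seed(31)
  for (strand in c("+", "-")) {
    cds <- paste0("ATG", strrep("ACT", 20), "TAA")  # Thr repeats
    tl <- toy_locus(cds, strand = strand)
    v <- strsplit(cds, "")[[1]]
    v[31] <- "G"  # plant coding-strand A->G at 0-based position 30
    stopifnot(cds != paste(v, collapse = ""))
    a <- align_transcript_to_genome(as_record("t", paste(v, collapse = "")),
                                    tl$gene, tl$genome)
    ev <- call_editing_events(a, tl$gene)
    expect_equal(nrow(ev), 1L)
    # mRNA-sense event regardless of genomic strand
    expect_equal(ev$from_base, "A")
    expect_equal(ev$to_base, "G")
    expect_equal(ev$genome_pos, 30L)
    expect_equal(ev$codon_index, 10L)
    expect_equal(ev$codon_pos, 0L)
    expect_equal(ev$kind, "transition")
  }
})

test_that("alignments without mismatches give no events; indels are not events", {
  set.seed(32)
  cds <- paste0("ATG", random_dna(60), "TAA")
  tl <- toy_locus(cds)
  a <- align_transcript_to_genome(as_record("t", cds), tl$gene, tl$genome)
  expect_equal(nrow(call_editing_events(a, tl$gene)), 0L)
  # 3-nt deletion in the transcript: alignment has deletion columns but
  # still zero editing events
  tr <- paste0(substr(cds, 1, 30), substr(cds, 34, nchar(cds)))
  a2 <- align_transcript_to_genome(as_record("t2", tr), tl$gene, tl$genome)
  expect_true(any(a2$columns$state == "deletion"))
  expect_equal(nrow(call_editing_events(a2, tl$gene)), 0L)
})

test_that("the census reproduces the published fucoxanthin survey column", {
  # counts for the Karenia column: A-C 26, A-G 59, A-U 0, C-A 1, C-G 0,
  # C-U 17, G-A 15, G-C 24, G-U 0, U-A 0, U-C 116, U-G 2 over 5,473 nt
  karenia <- c(26, 59, 0, 1, 0, 17, 15, 24, 0, 0, 116, 2)
  s <- summarize_editing(counts = karenia, surveyed_length = 5473)
  expect_equal(s$total_events, 260)
  expect_equal(unname(s$rounded["pct_bases_edited"]), 4.75)
  expect_equal(unname(s$rounded["pct_transitions"]), 79.6)
  expect_equal(unname(s$rounded["pct_transversions"]), 20.4)
  expect_equal(unname(s$rounded["pct_gc_enrich"]), 78.1)
  expect_equal(unname(s$rounded["pct_gc_deplete"]), 12.7)
  expect_equal(unname(s$rounded["pct_gc_neutral"]), 9.2)
  # invariants
  expect_equal(sum(s$counts), s$total_events)
  expect_equal(s$pct_transitions + s$pct_transversions, 100)
  expect_equal(s$pct_gc_enrich + s$pct_gc_deplete + s$pct_gc_neutral, 100)
})

test_that("census from events matches census from counts and is order-invariant", {
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  n <- 200
  from <- sample(bases, n, replace = TRUE)
  to <- vapply(from, function(b) sample(setdiff(bases, b), 1), "")
  ev <- data.frame(gene_id = "g", genome_pos = seq_len(n) - 1L,
                   transcript_pos = seq_len(n) - 1L,
                   from_base = from, to_base = to,
                   kind = NA, gc_effect = NA,
                   coding_effect = "nonsynonymous",
                   codon_index = NA, codon_pos = NA,
                   stringsAsFactors = FALSE)
  s1 <- summarize_editing(ev, 4000)
  s2 <- summarize_editing(ev[sample(n), ], 4000)
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$pct_gc_enrich, s2$pct_gc_enrich)
  expect_equal(sum(s1$counts), n)
  s3 <- summarize_editing(counts = s1$counts, surveyed_length = 4000)
  expect_equal(s3$pct_transitions, s1$pct_transitions)
  expect_error(summarize_editing(ev, 0), "surveyed_length")
})

test_that("premature stop detection scans the annotated frame", {
  tl <- toy_locus("ATGAAATAG")
  expect_equal(nrow(detect_premature_stops(tl$gene, tl$genome)), 0L)

  set.seed(34)
  codons <- rep("GCT", 20)
  codons[1] <- "ATG"; codons[6] <- "TGA"; codons[20] <- "TAA"
  tl2 <- toy_locus(paste(codons, collapse = ""), strand = "-")
  st <- detect_premature_stops(tl2$gene, tl2$genome)
  expect_equal(st$codon_index, 5L)
  expect_equal(st$stop_codon, "TGA")
})

test_that("stop-correction status distinguishes corrected, uncorrected and uncovered", {
  set.seed(35)
  codons <- c("ATG", rep("GAT", 8), "TGA", rep("GAT", 8), "TAA")
  cds <- paste(codons, collapse = "")
  tl <- toy_locus(cds)
  edit_at <- function(s, pos, base) {
    v <- strsplit(s, "")[[1]]; v[pos + 1L] <- base; paste(v, collapse = "")
  }
  # corrected: TGA -> CAA at codon 9 (positions 27, 28)
  tr <- edit_at(edit_at(cds, 27L, "C"), 28L, "A")
  a <- align_transcript_to_genome(as_record("t", tr), tl$gene, tl$genome)
  st <- verify_stop_correction(tl$gene, tl$genome, a)
  expect_equal(st$status, "corrected")
  expect_equal(st$transcript_codon, "CAA")
  # uncorrected: transcript identical to genome
  a2 <- align_transcript_to_genome(as_record("t2", cds), tl$gene, tl$genome)
  expect_equal(verify_stop_correction(tl$gene, tl$genome, a2)$status,
               "uncorrected")
  # uncovered: transcript starts downstream of the stop
  tr3 <- substr(cds, 31L, nchar(cds))
  a3 <- align_transcript_to_genome(as_record("t3", tr3), tl$gene, tl$genome)
  expect_equal(verify_stop_correction(tl$gene, tl$genome, a3)$status,
               "uncovered")
})

test_that("paralog discrimination p-values are exact binomial tail probabilities", {
  # no events over 10 nt when the null rate is 0.05: p = 0.95^10
  expect_equal(paralog_discrimination_test(0, 10, 5, 100), 0.95^10,
               tolerance = 1e-12)
  # one event where the reference shows 15 over the same length region
  p <- paralog_discrimination_test(1, 420, 15, 420)
  expect_lt(p, 1e-5)
  # observing exactly the expected count is unremarkable
  p_null <- paralog_discrimination_test(15, 420, 15, 420)
  expect_gt(p_null, 0.4)
  expect_lt(p_null, 0.7)
  expect_warning(p0 <- paralog_discrimination_test(2, 100, 0, 100),
                 "zero")
  expect_equal(p0, 0)
})

test_that("called events on synthetic transcripts recover the planted set exactly", {
  sp <- synth_plastome(small_config())
  genes <- sp$truth$genes
  contig <- sp$genomes[sp$genomes$id == "chr1", , drop = FALSE]
  called <- list()
  for (g in seq_len(nrow(genes))) {
    row <- genes[g, ]
    ann_row <- sp$annotations[sp$annotations$gene_id == row$gene_id, ]
    tr <- sp$transcripts[sp$transcripts$id == paste0(row$gene_id, "_t1"), ]
    call <- detect_poly_u_tail(tr, ann_row, contig)
    ev <- call_editing_events(call$alignment, ann_row)
    called[[row$gene_id]] <- ev
  }
  called <- do.call(rbind, called)
  key <- function(d, pos, from, to) {
    sort(paste(d, pos, from, to, sep = ":"))
  }
  truth <- sp$truth$events
  expect_identical(
    key(called$gene_id, called$genome_pos, called$from_base, called$to_base),
    key(truth$gene_id, truth$pos, truth$from_base, truth$to_base))
})
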