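# Poly(U) tail detection, templating classification, site annotation and
# composition statistics.

# fixture: gene + controlled downstream context on the coding strand
polyu_locus <- function(utr = "CCAGGTCAAGGTCCAAGGTCCACAAGGTCG", after = "G",
                        strand = "+") {
  set.seed(41)
  cds <- paste0("ATG", strrep("GAT", 25), "TAA")
  down <- paste0(utr, after, random_dna(60))
  lf <- random_dna(40)
  if (strand == "+") {
    genome_seq <- paste0(lf, cds, down)
    start <- 40L
  } else {
    genome_seq <- paste0(plastidproc:::.revcomp(paste0(cds, down)), lf)
    start <- nchar(down)
  }
  genome <- as_record("chr", genome_seq)
  gene <- data.frame(gene_id = "g1", genome_id = "chr", start = start,
                     end = start + nchar(cds), strand = strand,
                     feature_class = "CDS", category = "photosynthesis",
                     pseudogene = FALSE, stringsAsFactors = FALSE)
  list(genome = genome, gene = gene, cds = cds, utr = utr)
}

test_that("a transcript without a terminal U run gets status none", {
  tl <- polyu_locus()
  tr <- as_record("t", paste0(tl$cds, tl$utr))
  call <- detect_poly_u_tail(tr, tl$gene, tl$genome)
  expect_equal(call$status, "none")
  expect_equal(call$tail_length, 0L)
})

test_that("a non-templated tail is called post-transcriptional with correct length and site", {
  for (strand in c("+", "-")) {
    tl <- polyu_locus(strand = strand)
    tr <- as_record("t", paste0(tl$cds, tl$utr, strrep("T", 8)))
    call <- detect_poly_u_tail(tr, tl$gene, tl$genome)
    expect_equal(call$tail_length, 8L)
    expect_equal(call$templated_run, 0L)
    expect_equal(call$status, "posttranscriptional")
    # site is the coding-strand coordinate of the last UTR base
    cs_end <- if (strand == "+") tl$gene$end else
      nchar(tl$genome$sequence) - tl$gene$start
    expect_equal(call$site_genome_pos, cs_end + nchar(tl$utr) - 1L)
  }
})

test_that("a 19-nt tail over a genomic T12 tract is post-transcriptional; a tail within the tract is possibly templated", {
  # dnaK-1-like configuration: genomic T12 immediately after the site
  tl <- polyu_locus(after = paste0(strrep("T", 12), "G"))
  tr19 <- as_record("t", paste0(tl$cds, tl$utr, strrep("T", 19)))
  call <- detect_poly_u_tail(tr19, tl$gene, tl$genome)
  expect_equal(call$tail_length, 19L)
  expect_equal(call$templated_run, 12L)
  expect_equal(call$status, "posttranscriptional")

  tr6 <- as_record("t6", paste0(tl$cds, tl$utr, strrep("T", 6)))
  call6 <- detect_poly_u_tail(tr6, tl$gene, tl$genome)
  expect_equal(call6$tail_length, 6L)
  expect_equal(call6$status, "possibly_templated")

  # boundary of the rule: tail length equal to the run
  tr12 <- as_record("t12", paste0(tl$cds, tl$utr, strrep("T", 12)))
  expect_equal(detect_poly_u_tail(tr12, tl$gene, tl$genome)$status,
               "possibly_templated")
})

test_that("sub-threshold runs are restored to the body (non-destructive)", {
  tl <- polyu_locus()
  tr <- as_record("t", paste0(tl$cds, tl$utr, "TTT"))
  call <- detect_poly_u_tail(tr, tl$gene, tl$genome, min_tail = 5L)
  expect_equal(call$status, "none")
  expect_equal(call$tail_length, 3L)
  # the three T bases remain part of the aligned body: the site moves past
  # them (aligned as insertions or matches, not stripped)
  aligned <- call$alignment$columns
  expect_equal(max(aligned$tpos, na.rm = TRUE),
               nchar(tr$sequence) - 1L)
})

test_that("a terminal oligo-d(A) remnant is trimmed before tail calling", {
  tl <- polyu_locus()
  tr <- as_record("t", paste0(tl$cds, tl$utr, strrep("T", 9), "AAAA"))
  call <- detect_poly_u_tail(tr, tl$gene, tl$genome)
  expect_equal(call$tail_length, 9L)
  expect_equal(call$status, "posttranscriptional")
})

test_that("site annotation computes UTR length, internal sites and cistron class", {
  tl <- polyu_locus()
  ann <- tl$gene
  # tail right after the stop codon: zero-length UTR
  tr0 <- as_record("t0", paste0(tl$cds, strrep("T", 7)))
  c0 <- annotate_poly_u_site(detect_poly_u_tail(tr0, tl$gene, tl$genome), ann)
  expect_equal(c0$utr_length, 0L)
  expect_false(c0$internal_site)
  expect_equal(c0$cistron_class, "monocistronic")

  # 30-nt UTR
  tr <- as_record("t", paste0(tl$cds, tl$utr, strrep("T", 7)))
  c1 <- annotate_poly_u_site(detect_poly_u_tail(tr, tl$gene, tl$genome), ann)
  expect_equal(c1$utr_length, nchar(tl$utr))

  # transcript ending inside the CDS: negative UTR length, internal flag
  trunc <- substr(tl$cds, 1, nchar(tl$cds) - 13L)  # ends on a non-U base
  c2 <- annotate_poly_u_site(
    detect_poly_u_tail(as_record("t2", paste0(trunc, strrep("T", 7))),
                       tl$gene, tl$genome), ann)
  expect_equal(c2$utr_length, -13L)
  expect_true(c2$internal_site)
})

test_that("dicistronic transcripts list both member genes in genomic order", {
  set.seed(42)
  cdsA <- paste0("ATG", strrep("GAA", 20), "TAA")
  cdsB <- paste0("ATG", strrep("GGA", 22), "TAA")
  spacer <- random_dna(50)
  utr <- "CCAGGTCAAGGTCCAAGG"
  genome <- as_record("chr", paste0(random_dna(30), cdsA, spacer, cdsB,
                                    utr, "G", random_dna(40)))
  ann <- data.frame(
    gene_id = c("gA", "gB"), genome_id = "chr",
    start = c(30L, 30L + nchar(cdsA) + 50L),
    end = c(30L + nchar(cdsA), 30L + nchar(cdsA) + 50L + nchar(cdsB)),
    strand = "+", feature_class = "CDS",
    category = c("housekeeping", "housekeeping"), pseudogene = FALSE,
    stringsAsFactors = FALSE)
  span <- list(gene_id = "gA-gB", strand = "+", start = 30L,
               end = ann$end[2], feature_class = "CDS")
  tr <- as_record("t", paste0(cdsA, spacer, cdsB, utr, strrep("T", 10)))
  call <- detect_poly_u_tail(tr, span, genome)
  call$gene_id <- "gB"
  call <- annotate_poly_u_site(call, ann)
  expect_equal(call$cistron_gene_ids, c("gA", "gB"))
  expect_equal(call$cistron_class, "dicistronic")
  expect_equal(call$utr_length, nchar(utr))
  expect_false(call$overlaps_downstream_cds)
})

test_that("a poly(U) site inside the downstream CDS is flagged", {
  set.seed(43)
  cdsA <- paste0("ATG", strrep("GAA", 20), "TAA")
  cdsB <- paste0("ATG", strrep("GGC", 30), "TAA")
  spacer <- random_dna(20)
  genome <- as_record("chr", paste0(random_dna(30), cdsA, spacer, cdsB,
                                    random_dna(40)))
  ann <- data.frame(
    gene_id = c("gA", "gB"), genome_id = "chr",
    start = c(30L, 30L + nchar(cdsA) + 20L),
    end = c(30L + nchar(cdsA), 30L + nchar(cdsA) + 20L + nchar(cdsB)),
    strand = "+", feature_class = "CDS", category = "housekeeping",
    pseudogene = FALSE, stringsAsFactors = FALSE)
  # transcript of gA reads through the spacer and 30 nt into gB
  tr <- as_record("t", paste0(cdsA, spacer, substr(cdsB, 1, 30),
                              strrep("T", 8)))
  call <- detect_poly_u_tail(tr, ann[1, ], genome, flank = 120L)
  call <- annotate_poly_u_site(call, ann)
  expect_true(call$overlaps_downstream_cds)
  expect_equal(call$utr_length, 20L + 30L)
})

test_that("composition statistics equal direct letter counts", {
  g <- composition_stats("GGCC")
  expect_equal(g$gc_fraction, 1)
  expect_equal(g$purine_fraction, 0.5)
  a <- composition_stats("AAAA")
  expect_equal(a$gc_fraction, 0)
  expect_equal(a$purine_fraction, 1)
  set.seed(44)
  s <- random_dna(1000)
  v <- strsplit(s, "")[[1]]
  cs <- composition_stats(s)
  expect_equal(cs$gc_fraction, mean(v %in% c("G", "C")))
  expect_equal(cs$purine_fraction, mean(v %in% c("A", "G")))
  expect_equal(cs$length, 1000L)
  expect_error(composition_stats("NNNN"), "all N")
  expect_error(composition_stats(""), "empty")
})

test_that("planted UTR lengths average near the configured 30 nt mean", {
  sp <- synth_plastome(synthetic_config(seed = 5))
  u <- sp$truth$genes$utr_length
  se <- stats::sd(u) / sqrt(length(u))
  expect_lt(abs(mean(u) - 30), 3 * se + 1e-9)
})
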