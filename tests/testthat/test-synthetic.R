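# Generator invariants: determinism, truth-manifest reconstruction,
# editing rate and spectrum, and the planted structures.

test_that("generation is deterministic under a seed and varies across seeds", {
  a <- synth_plastome(small_config(seed = 71))
  b <- synth_plastome(small_config(seed = 71))
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth$events, b$truth$events)
  c <- synth_plastome(small_config(seed = 72))
  expect_false(identical(a$genomes$sequence[1], c$genomes$sequence[1]))
})

test_that("genome plus truth manifest reconstructs every transcript byte-identically", {
  sp <- synth_plastome(small_config(seed = 73))
  contig_len <- nchar(sp$genomes$sequence[1])
  cs <- list(`+` = sp$genomes$sequence[1],
             `-` = plastidproc:::.revcomp(sp$genomes$sequence[1]))
  genes <- sp$truth$genes
  for (tid in sp$transcripts$id) {
    gids <- sp$truth$transcript_genes[[tid]]
    if (all(gids %in% sp$truth$pseudogenes$gene_id)) {
      ann <- sp$annotations[sp$annotations$gene_id == gids, ]
      gi <- if (ann$strand == "+") c(ann$start, ann$end) else
        c(contig_len - ann$end, contig_len - ann$start)
      expect_identical(
        sp$transcripts$sequence[sp$transcripts$id == tid],
        substr(cs[[ann$strand]], gi[1] + 1L, gi[2]))
      next
    }
    rows <- genes[match(gids, genes$gene_id), ]
    strand <- rows$strand[1]
    gi <- t(vapply(seq_len(nrow(rows)), function(i) {
      if (strand == "+") c(rows$start[i], rows$end[i]) else
        c(contig_len - rows$end[i], contig_len - rows$start[i])
    }, numeric(2)))
    last <- nrow(rows)
    span0 <- gi[1, 1]
    body <- strsplit(substr(cs[[strand]], span0 + 1L,
                            gi[last, 2] + rows$utr_length[last]), "")[[1]]
    for (i in seq_len(nrow(rows))) {
      ev <- sp$truth$events[sp$truth$events$gene_id == rows$gene_id[i], ]
      if (i < last) ev <- ev[ev$region == "cds", ]
      body[gi[i, 1] - span0 + ev$pos + 1L] <- ev$to_base
    }
    built <- paste0(paste(body, collapse = ""),
                    if (rows$polyu[last]) strrep("T", rows$tail_length[last])
                    else "")
    expect_identical(sp$transcripts$sequence[sp$transcripts$id == tid],
                     built)
  }
})

test_that("exactly the configured premature stops are planted and recoverable by scanning", {
  sp <- synth_plastome(synthetic_config(seed = 74))
  expect_equal(nrow(sp$truth$premature_stops), 11L)
  chr <- sp$genomes[1, , drop = FALSE]
  found <- list()
  for (g in sp$truth$genes$gene_id) {
    ann <- sp$annotations[sp$annotations$gene_id == g, ]
    st <- detect_premature_stops(ann, chr)
    if (nrow(st)) found[[g]] <- cbind(gene_id = g, st)
  }
  found <- do.call(rbind, found)
  expect_equal(nrow(found), 11L)
  o1 <- found[order(found$gene_id, found$codon_index),
              c("gene_id", "codon_index", "stop_codon")]
  o2 <- sp$truth$premature_stops[order(sp$truth$premature_stops$gene_id),
                                 c("gene_id", "codon_index", "stop_codon")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("realized editing rate stays within 3 binomial standard errors of the target", {
  for (seed in c(75, 76)) {
    sp <- synth_plastome(synthetic_config(seed = seed))
    k <- sum(sp$truth$events$region == "cds" & !sp$truth$events$forced)
    n <- sp$truth$n_editable_sites
    p <- sp$config$edit_rate
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(k / n - p), 3 * se)
  }
})

test_that("realized substitution-type spectrum matches the configured weights", {
  # enough events for a goodness-of-fit comparison
  sp <- synth_plastome(synthetic_config(seed = 77, n_genes = 70L))
  ev <- sp$truth$events[!sp$truth$events$forced, ]
  expect_gt(nrow(ev), 2000L)
  type <- paste(chartr("T", "U", ev$from_base), chartr("T", "U", ev$to_base),
                sep = "-")
  counts <- vapply(plastidproc:::EDIT_TYPES, function(t) sum(type == t),
                   integer(1))
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = sp$config$type_weights))
  expect_gt(gof$p.value, 0.05)
})

test_that("pseudogene transcripts are unedited, untailed genomic copies", {
  sp <- synth_plastome(small_config(seed = 78))
  ps <- sp$truth$pseudogenes$gene_id
  expect_false(any(sp$truth$events$gene_id %in% ps))
  for (p in ps) {
    tr <- sp$transcripts[sp$transcripts$id == paste0(p, "_t1"), ]
    expect_lt(plastidproc:::.terminal_run_length(tr$sequence, "T"), 5L)
  }
  # pseudogene CDS is one base shorter than its source (frameshift)
  for (i in seq_len(nrow(sp$truth$pseudogenes))) {
    psa <- sp$annotations[sp$annotations$gene_id ==
                            sp$truth$pseudogenes$gene_id[i], ]
    src <- sp$annotations[sp$annotations$gene_id ==
                            sp$truth$pseudogenes$source_gene_id[i], ]
    expect_equal(psa$end - psa$start, src$end - src$start - 1L)
    expect_true(psa$pseudogene)
  }
})

test_that("zero editing rate yields transcripts identical to the genome plus tails", {
  cfg <- synthetic_config(seed = 79, n_genes = 6L, edit_rate = 0,
                          utr_edit_rate = 0, n_premature_stops = 0L,
                          n_pseudogenes = 0L, n_polycistronic = 0L)
  sp <- synth_plastome(cfg)
  expect_equal(nrow(sp$truth$events), 0L)
  contig_len <- nchar(sp$genomes$sequence[1])
  cs <- list(`+` = sp$genomes$sequence[1],
             `-` = plastidproc:::.revcomp(sp$genomes$sequence[1]))
  for (g in seq_len(nrow(sp$truth$genes))) {
    row <- sp$truth$genes[g, ]
    gi1 <- if (row$strand == "+") row$start else contig_len - row$end
    gi2 <- if (row$strand == "+") row$end else contig_len - row$start
    expected <- paste0(
      substr(cs[[row$strand]], gi1 + 1L, gi2 + row$utr_length),
      if (row$polyu) strrep("T", row$tail_length) else "")
    expect_identical(
      sp$transcripts$sequence[sp$transcripts$id == paste0(row$gene_id, "_t1")],
      expected)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(n_genes = 0L), "n_genes")
  expect_error(synthetic_config(n_genes = 5L, n_premature_stops = 11L),
               "more premature stops")
  expect_error(synthetic_config(circle_length = 100L,
                                circle_redundancy = 150L))
})

test_that("ortholog divergence is concentrated in hotspot codons", {
  sp <- synth_plastome(synthetic_config(seed = 80))
  hs <- sp$truth$hotspots
  ident_in <- c(); ident_out <- c()
  for (i in seq_len(nrow(hs))) {
    g <- hs$gene_id[i]
    q <- strsplit(sp$queries[[g]], "")[[1]]
    o <- strsplit(sp$orthologs$sequence[sp$orthologs$id == g], "")[[1]]
    stopifnot(length(q) == length(o))
    cod <- seq.int(hs$start[i] %/% 3L + 1L, hs$end[i] %/% 3L)
    cod <- cod[cod <= length(q)]
    ident_in <- c(ident_in, q[cod] == o[cod])
    ident_out <- c(ident_out, (q == o)[-cod])
  }
  expect_lt(mean(ident_in), mean(ident_out))
})

test_that("the minicircle contig embeds the planted circle and redundancy", {
  mc <- generate_minicircle_contig(synthetic_config(seed = 81))
  expect_equal(nchar(mc$contig$sequence), 2323L + 150L)
  expect_equal(substr(mc$contig$sequence, 2324L, 2473L),
               substr(mc$contig$sequence, 1L, 150L))
  expect_equal(mc$truth$circle_length, 2323L)
})
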