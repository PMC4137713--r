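# Synthetic plastid genome/transcriptome generator with a ground-truth
# manifest.  The generator emulates the statistical structure the analysis
# assumes: a multi-gene genome on both strands, transcripts with ~4.3%
# substitutional editing following the observed 12-type spectrum, editing
# hotspots in short divergent regions, premature in-frame stops corrected
# by editing, 3' poly(U) tails of 5-19 nt with ~30 bp UTRs (a small
# fraction of sites adjacent to genomic T tracts), unedited/untailed
# pseudogene paralogs, hotspot-coupled ortholog divergence, and a
# minicircle contig assembled with terminal redundancy.

NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

# Default 12-type editing weights: proportional to a genome-wide census of
# a fucoxanthin plastid transcriptome (transitions dominant, transversions
# rare), order A-C, A-G, A-U, C-A, C-G, C-U, G-A, G-C, G-U, U-A, U-C, U-G.
DEFAULT_TYPE_WEIGHTS <- c(15, 789, 16, 8, 4, 49, 99, 8, 1, 11, 540, 11)

#' Configuration for the synthetic plastome generator
#'
#' Defaults encode the study conditions the generator emulates: 30 genes
#' of 300-1,500 nt, a genome-wide per-site editing probability of 0.043
#' with the 12-type spectrum above, 30% of genes carrying an 84-nt hotspot
#' edited at 4x the background rate, 11 premature in-frame stops (all
#' corrected by editing in the transcripts), 70% of genes polyuridylylated
#' with tails of 5-19 nt and geometric UTR lengths of mean 30 nt, 7% of
#' poly(U) sites adjacent to a genomic T run long enough to explain the
#' tail, two pseudogene paralogs (frameshifted, unedited, untailed), and a
#' 2,323-nt minicircle assembled with 150 nt of terminal redundancy and a
#' single EcoRI site.
#'
#' @param seed Integer seed; every generator stage derives its RNG stream
#'   from it, so output is fully reproducible.
#' @param n_genes Number of functional genes (>= 1).
#' @param gene_length Range of gene lengths in nt (rounded to codons).
#' @param intergenic Range of intergenic spacer lengths in nt.
#' @param edit_rate Genome-wide per-site editing probability over CDS.
#' @param type_weights 12-vector of substitution-type weights.
#' @param hotspot_gene_fraction Fraction of genes given a hotspot.
#' @param hotspot_length Hotspot length in nt.
#' @param hotspot_multiplier Editing-rate multiplier inside hotspots.
#' @param n_premature_stops Genes carrying one premature stop each.
#' @param polyu_fraction Fraction of genes whose transcript gets a tail.
#' @param tail_length Tail length range (nt).
#' @param templated_fraction Fraction of tailed genes whose site adjoins a
#'   genomic T run at least as long as the tail.
#' @param templated_run Genomic T-run length range for those sites.
#' @param utr_mean Mean of the geometric 3'-UTR length distribution (nt).
#' @param utr_edit_rate Editing probability per UTR site.
#' @param n_pseudogenes Number of frameshifted paralog copies appended.
#' @param ortholog_sub_rate Per-residue substitution probability between
#'   the query translation and its ortholog.
#' @param hotspot_ortholog_extra Additional per-residue substitution
#'   probability for ortholog residues in hotspot codons (couples low
#'   conservation to high editing).
#' @param n_polycistronic Number of adjacent same-strand gene pairs also
#'   emitted as dicistronic transcripts.
#' @param circle_length,circle_redundancy,circle_motif Minicircle
#'   parameters.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 30L,
                             gene_length = c(300L, 1500L),
                             intergenic = c(50L, 300L),
                             edit_rate = 0.043,
                             type_weights = DEFAULT_TYPE_WEIGHTS,
                             hotspot_gene_fraction = 0.3,
                             hotspot_length = 84L,
                             hotspot_multiplier = 4,
                             n_premature_stops = 11L,
                             polyu_fraction = 0.7,
                             tail_length = c(5L, 19L),
                             templated_fraction = 0.07,
                             templated_run = c(8L, 12L),
                             utr_mean = 30,
                             utr_edit_rate = 0.016,
                             n_pseudogenes = 2L,
                             ortholog_sub_rate = 0.15,
                             hotspot_ortholog_extra = 0.5,
                             n_polycistronic = 2L,
                             circle_length = 2323L,
                             circle_redundancy = 150L,
                             circle_motif = "GAATTC") {
  if (n_genes < 1L) .stopf("n_genes must be >= 1")
  if (n_premature_stops > n_genes) {
    .stopf("more premature stops than genes")
  }
  stopifnot(edit_rate >= 0, edit_rate <= 1,
            polyu_fraction >= 0, polyu_fraction <= 1,
            templated_fraction >= 0, templated_fraction <= 1,
            length(type_weights) == 12L, all(type_weights >= 0),
            sum(type_weights) > 0,
            gene_length[1] >= 150L, gene_length[2] >= gene_length[1],
            circle_redundancy < circle_length)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    intergenic = as.integer(intergenic),
    edit_rate = edit_rate,
    type_weights = stats::setNames(type_weights / sum(type_weights),
                                   EDIT_TYPES),
    hotspot_gene_fraction = hotspot_gene_fraction,
    hotspot_length = as.integer(hotspot_length),
    hotspot_multiplier = hotspot_multiplier,
    n_premature_stops = as.integer(n_premature_stops),
    polyu_fraction = polyu_fraction,
    tail_length = as.integer(tail_length),
    templated_fraction = templated_fraction,
    templated_run = as.integer(templated_run),
    utr_mean = utr_mean,
    utr_edit_rate = utr_edit_rate,
    n_pseudogenes = as.integer(n_pseudogenes),
    ortholog_sub_rate = ortholog_sub_rate,
    hotspot_ortholog_extra = hotspot_ortholog_extra,
    n_polycistronic = as.integer(n_polycistronic),
    circle_length = as.integer(circle_length),
    circle_redundancy = as.integer(circle_redundancy),
    circle_motif = circle_motif
  ), class = "synthetic_config")
}

.rand_seq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.rand_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# replace the 0-based position `pos` of string `s` with `base`
.set_base <- function(s, pos, base) {
  substr(s, pos + 1L, pos + 1L) <- base
  s
}

.sample_not <- function(exclude) sample(setdiff(DNA_BASES, exclude), 1L)

#' Generate the synthetic genome and its annotations
#'
#' Lays out `n_genes` genes on alternating random strands separated by
#' random intergenic spacers, plants one premature in-frame stop codon in
#' each of `n_premature_stops` genes, selects hotspot intervals, plans the
#' poly(U) architecture (UTR lengths, tail lengths, genomic T runs for the
#' templated fraction -- these constrain intergenic sequence, so they are
#' decided here and recorded in the truth manifest), and appends
#' frameshifted pseudogene paralogs.
#'
#' @param config A `synthetic_config`.
#' @return List with `genome` (one-row data frame), `annotations`, and the
#'   partial `truth` manifest.
#' @export
generate_genome_and_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ncod <- sample(seq.int(config$gene_length[1] %/% 3L,
                         config$gene_length[2] %/% 3L), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  region_len <- sample(seq.int(config$intergenic[1], config$intergenic[2]),
                       n + 1L, replace = TRUE)

  cds <- vapply(ncod, .rand_cds, character(1))

  # premature stops: one per selected gene, interior codon
  stop_genes <- sort(sample.int(n, config$n_premature_stops))
  stops <- data.frame(gene_id = character(0), codon_index = integer(0),
                      stop_codon = character(0), corrected_codon = character(0),
                      stringsAsFactors = FALSE)
  for (g in stop_genes) {
    k <- sample(seq.int(2L, ncod[g] - 3L), 1L)
    sc <- sample(STOP_CODONS, 1L)
    cds[g] <- paste0(substr(cds[g], 1L, 3L * k),
                     sc,
                     substr(cds[g], 3L * k + 4L, nchar(cds[g])))
    corrected <- switch(sc, TAA = "CAA", TAG = "CAG", TGA = "CAA")
    stops <- rbind(stops, data.frame(
      gene_id = sprintf("g%02d", g), codon_index = k, stop_codon = sc,
      corrected_codon = corrected, stringsAsFactors = FALSE))
  }

  # hotspots: codon-aligned window strictly inside the CDS, avoiding the
  # planted stop codon
  n_hs <- round(config$hotspot_gene_fraction * n)
  hs_genes <- sort(sample.int(n, n_hs))
  hs_codons <- config$hotspot_length %/% 3L
  hotspots <- data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  for (g in hs_genes) {
    repeat {
      c0 <- sample(seq.int(1L, ncod[g] - 1L - hs_codons), 1L)
      stop_here <- stops$codon_index[stops$gene_id == sprintf("g%02d", g)]
      if (!length(stop_here) ||
          stop_here < c0 || stop_here >= c0 + hs_codons) break
    }
    hotspots <- rbind(hotspots, data.frame(
      gene_id = sprintf("g%02d", g), start = 3L * c0,
      end = 3L * (c0 + hs_codons), stringsAsFactors = FALSE))
  }

  # poly(U) architecture
  n_pu <- round(config$polyu_fraction * n)
  pu_genes <- sort(sample.int(n, n_pu))
  polyu <- seq_len(n) %in% pu_genes
  n_tmpl <- round(config$templated_fraction * n_pu)
  tmpl_genes <- if (n_tmpl > 0L) sample(pu_genes, n_tmpl) else integer(0)
  run_len <- integer(n)
  tail_len <- integer(n)
  for (g in pu_genes) {
    if (g %in% tmpl_genes) {
      run_len[g] <- sample(seq.int(config$templated_run[1],
                                   config$templated_run[2]), 1L)
      tail_len[g] <- sample(seq.int(config$tail_length[1],
                                    min(run_len[g], config$tail_length[2])),
                            1L)
    } else {
      tail_len[g] <- sample(seq.int(config$tail_length[1],
                                    config$tail_length[2]), 1L)
    }
  }
  utr_len <- stats::rgeom(n, prob = 1 / (config$utr_mean + 1))

  # cap UTRs so that the structures forced into each intergenic region
  # (UTR + T run + one sentinel base per side) never collide
  need <- function(g) utr_len[g] + run_len[g] + 1L
  for (r in seq.int(0L, n)) {
    left_g <- if (r >= 1L && strand[r] == "+") r else 0L       # uses region r
    right_g <- if (r < n && strand[r + 1L] == "-") r + 1L else 0L
    total <- (if (left_g) need(left_g) else 0L) +
      (if (right_g) need(right_g) else 0L)
    if (total > region_len[r + 1L]) {
      avail <- region_len[r + 1L]
      if (left_g && right_g) {
        half <- (avail - run_len[left_g] - run_len[right_g] - 2L) %/% 2L
        utr_len[left_g] <- max(0L, min(utr_len[left_g], half))
        utr_len[right_g] <- max(0L, min(utr_len[right_g], half))
      } else if (left_g) {
        utr_len[left_g] <- max(0L, avail - run_len[left_g] - 1L)
      } else if (right_g) {
        utr_len[right_g] <- max(0L, avail - run_len[right_g] - 1L)
      }
    }
  }

  # intergenic sequences with the planned structures stamped in
  regions <- vapply(region_len, .rand_seq, character(1))
  force_left <- function(reg, utr, run) {
    # "+" gene on the left: UTR occupies offsets [0, utr), forward==coding
    if (utr > 0L) {
      off <- utr - 1L
      if (substr(reg, off + 1L, off + 1L) == "T") {
        reg <- .set_base(reg, off, .sample_not("T"))
      }
    }
    if (run > 0L) {
      for (j in seq.int(utr, utr + run - 1L)) reg <- .set_base(reg, j, "T")
    }
    sent <- utr + run
    if (sent < nchar(reg) && substr(reg, sent + 1L, sent + 1L) == "T") {
      reg <- .set_base(reg, sent, .sample_not("T"))
    }
    reg
  }
  force_right <- function(reg, utr, run) {
    # "-" gene on the right: coding strand reads right-to-left, so the
    # forced bases are complemented and mirrored
    M <- nchar(reg)
    if (utr > 0L) {
      off <- M - utr
      if (substr(reg, off + 1L, off + 1L) == "A") {
        reg <- .set_base(reg, off, .sample_not("A"))
      }
    }
    if (run > 0L) {
      for (j in seq.int(M - utr - run, M - utr - 1L)) {
        reg <- .set_base(reg, j, "A")
      }
    }
    sent <- M - utr - run - 1L
    if (sent >= 0L && substr(reg, sent + 1L, sent + 1L) == "A") {
      reg <- .set_base(reg, sent, .sample_not("A"))
    }
    reg
  }
  for (g in seq_len(n)) {
    if (strand[g] == "+") {
      regions[g + 1L] <- force_left(regions[g + 1L], utr_len[g], run_len[g])
    } else {
      regions[g] <- force_right(regions[g], utr_len[g], run_len[g])
    }
  }

  # assemble the forward-strand genome and gene coordinates
  parts <- character(0)
  start <- integer(n); end <- integer(n)
  pos <- 0L
  for (g in seq_len(n)) {
    parts <- c(parts, regions[g])
    pos <- pos + region_len[g]
    gene_fwd <- if (strand[g] == "+") cds[g] else .revcomp(cds[g])
    start[g] <- pos
    end[g] <- pos + nchar(cds[g])
    parts <- c(parts, gene_fwd)
    pos <- end[g]
  }
  parts <- c(parts, regions[n + 1L])
  pos <- pos + region_len[n + 1L]

  gene_id <- sprintf("g%02d", seq_len(n))
  category <- sample(c("photosynthesis", "housekeeping"), n, replace = TRUE)
  ann <- data.frame(
    gene_id = gene_id, genome_id = "chr1", start = start, end = end,
    strand = strand, feature_class = "CDS", category = category,
    pseudogene = FALSE, stringsAsFactors = FALSE)

  # pseudogene paralogs: copy of a gene with one internal base deleted
  # (frameshift), appended after the last region
  ps_truth <- data.frame(gene_id = character(0), source_gene_id = character(0),
                         stringsAsFactors = FALSE)
  for (j in seq_len(config$n_pseudogenes)) {
    src <- sample.int(n, 1L)
    del <- sample(seq.int(4L, nchar(cds[src]) - 4L), 1L)
    ps_seq <- paste0(substr(cds[src], 1L, del - 1L),
                     substr(cds[src], del + 1L, nchar(cds[src])))
    ps_strand <- sample(c("+", "-"), 1L)
    ps_fwd <- if (ps_strand == "+") ps_seq else .revcomp(ps_seq)
    ps_id <- sprintf("ps%d", j)
    ann <- rbind(ann, data.frame(
      gene_id = ps_id, genome_id = "chr1", start = pos,
      end = pos + nchar(ps_seq), strand = ps_strand, feature_class = "CDS",
      category = ann$category[src], pseudogene = TRUE,
      stringsAsFactors = FALSE))
    parts <- c(parts, ps_fwd, .rand_seq(100L))
    pos <- pos + nchar(ps_seq) + 100L
    ps_truth <- rbind(ps_truth, data.frame(
      gene_id = ps_id, source_gene_id = gene_id[src],
      stringsAsFactors = FALSE))
  }

  genome <- data.frame(id = "chr1", sequence = paste(parts, collapse = ""),
                       description = "synthetic plastid chromosome",
                       stringsAsFactors = FALSE)
  stopifnot(nchar(genome$sequence) == pos)

  truth <- list(
    config = config,
    genes = data.frame(
      gene_id = gene_id, n_codons = ncod, strand = strand,
      start = start, end = end, polyu = polyu, utr_length = utr_len,
      tail_length = tail_len, templated_run = run_len,
      hotspot = gene_id %in% hotspots$gene_id,
      stringsAsFactors = FALSE),
    premature_stops = stops,
    hotspots = hotspots,
    pseudogenes = ps_truth)
  list(genome = genome, annotations = ann, truth = truth)
}

# conditional to-base sampler: weights of b -> x restricted to from == b
.to_base_sampler <- function(type_weights) {
  from <- chartr("U", "T", substr(EDIT_TYPES, 1L, 1L))
  to <- chartr("U", "T", substr(EDIT_TYPES, 3L, 3L))
  function(b) {
    w <- type_weights[from == b]
    sample(to[from == b], 1L, prob = w)
  }
}

#' Generate edited, tailed transcripts plus the event-level truth
#'
#' Plants per-site Bernoulli editing over each functional CDS.  Site
#' probabilities follow the configured genome-wide rate, multiplied inside
#' hotspots and weighted by substitution type so that the realized type
#' spectrum matches `type_weights` irrespective of base composition; the
#' substituted base is drawn from the type weights conditional on the
#' genomic base.  Every planted premature stop is forcibly corrected
#' (TAA -> CAA, TAG -> CAG, TGA -> CAA).  UTRs are edited at a low flat
#' rate.  Tails are appended per the architecture planned at genome
#' generation; pseudogene transcripts are emitted unedited and untailed.
#'
#' @param genome,annotations,truth Output of
#'   [generate_genome_and_annotations()].
#' @param config The same `synthetic_config`.
#' @return List with `transcripts` (data frame `id`, `sequence`,
#'   `description`) and the completed `truth` (adds `events`, per-gene and
#'   per-transcript tables).
#' @export
generate_transcripts <- function(genome, annotations, truth, config) {
  set.seed(config$seed + 1000L)
  genes <- truth$genes
  n <- nrow(genes)
  contig_len <- nchar(genome$sequence)
  cs_cache <- list(`+` = genome$sequence, `-` = .revcomp(genome$sequence))

  tw <- config$type_weights
  from_dna <- chartr("U", "T", substr(EDIT_TYPES, 1L, 1L))
  wfrom <- vapply(DNA_BASES, function(b) sum(tw[from_dna == b]), numeric(1))
  pick_to <- .to_base_sampler(tw)

  # collect editable CDS sites genome-wide (first/last codon and planted
  # stop codons excluded; stop codons are corrected by forced events)
  site_gene <- integer(0); site_pos <- integer(0)
  site_base <- character(0); site_mult <- numeric(0)
  gene_cds <- character(n)
  for (g in seq_len(n)) {
    row <- genes[g, ]
    gi <- .cs_interval(list(strand = row$strand, start = row$start,
                            end = row$end), contig_len)
    cds <- substr(cs_cache[[row$strand]], gi[1] + 1L, gi[2])
    gene_cds[g] <- cds
    len <- nchar(cds)
    pos <- seq.int(3L, len - 4L)
    st <- truth$premature_stops[truth$premature_stops$gene_id == row$gene_id, ]
    if (nrow(st)) {
      excl <- as.vector(outer(3L * st$codon_index, 0:2, `+`))
      pos <- setdiff(pos, excl)
    }
    mult <- rep(1, length(pos))
    hs <- truth$hotspots[truth$hotspots$gene_id == row$gene_id, ]
    if (nrow(hs)) mult[pos >= hs$start & pos < hs$end] <- config$hotspot_multiplier
    site_gene <- c(site_gene, rep(g, length(pos)))
    site_pos <- c(site_pos, pos)
    site_base <- c(site_base, strsplit(cds, "")[[1]][pos + 1L])
    site_mult <- c(site_mult, mult)
  }
  freq <- table(factor(site_base, levels = DNA_BASES)) / length(site_base)
  raw <- (wfrom[site_base] / as.numeric(freq[site_base])) * site_mult
  p <- config$edit_rate * raw * length(raw) / sum(raw)
  p <- pmin(p, 0.95)
  hit <- stats::runif(length(p)) < p

  n_hit <- sum(hit)
  events <- data.frame(gene_id = genes$gene_id[site_gene[hit]],
                       pos = site_pos[hit],
                       from_base = site_base[hit],
                       to_base = rep(NA_character_, n_hit),
                       region = rep("cds", n_hit),
                       forced = rep(FALSE, n_hit),
                       stringsAsFactors = FALSE)
  if (nrow(events)) {
    events$to_base <- vapply(events$from_base, pick_to, character(1))
  }

  # forced premature-stop corrections
  for (i in seq_len(nrow(truth$premature_stops))) {
    st <- truth$premature_stops[i, ]
    base0 <- 3L * st$codon_index
    gcodon <- strsplit(st$stop_codon, "")[[1]]
    ecodon <- strsplit(st$corrected_codon, "")[[1]]
    for (k in 0:2) {
      if (gcodon[k + 1L] != ecodon[k + 1L]) {
        events <- rbind(events, data.frame(
          gene_id = st$gene_id, pos = base0 + k,
          from_base = gcodon[k + 1L], to_base = ecodon[k + 1L],
          region = "cds", forced = TRUE, stringsAsFactors = FALSE))
      }
    }
  }

  # UTR editing at a low flat rate (final UTR base excluded so the poly(U)
  # site base is never turned into a U)
  for (g in seq_len(n)) {
    row <- genes[g, ]
    if (row$utr_length < 2L) next
    cds_len <- 3L * row$n_codons
    utr_pos <- seq.int(cds_len, cds_len + row$utr_length - 2L)
    gi <- .cs_interval(list(strand = row$strand, start = row$start,
                            end = row$end), contig_len)
    utr_seq <- strsplit(substr(cs_cache[[row$strand]], gi[1] + cds_len + 1L,
                               gi[1] + cds_len + row$utr_length), "")[[1]]
    hit_u <- which(stats::runif(length(utr_pos) ) < config$utr_edit_rate)
    for (k in hit_u) {
      events <- rbind(events, data.frame(
        gene_id = row$gene_id, pos = utr_pos[k],
        from_base = utr_seq[k], to_base = pick_to(utr_seq[k]),
        region = "utr", forced = FALSE, stringsAsFactors = FALSE))
    }
  }
  events <- events[order(events$gene_id, events$pos), , drop = FALSE]
  rownames(events) <- NULL

  # build transcripts: body = CDS + UTR with events applied, then tail
  build_body <- function(gene_ids) {
    # gene_ids in coding-strand order; body runs from the first gene's CDS
    # start to the last gene's poly(U) site
    first <- genes[genes$gene_id == gene_ids[1L], ]
    last <- genes[genes$gene_id == gene_ids[length(gene_ids)], ]
    gi_first <- .cs_interval(list(strand = first$strand, start = first$start,
                                  end = first$end), contig_len)
    gi_last <- .cs_interval(list(strand = last$strand, start = last$start,
                                 end = last$end), contig_len)
    span0 <- gi_first[1]
    span1 <- gi_last[2] + last$utr_length   # exclusive
    body <- strsplit(substr(cs_cache[[first$strand]], span0 + 1L, span1),
                     "")[[1]]
    for (gid in gene_ids) {
      grow <- genes[genes$gene_id == gid, ]
      gi <- .cs_interval(list(strand = grow$strand, start = grow$start,
                              end = grow$end), contig_len)
      ev <- events[events$gene_id == gid, , drop = FALSE]
      if (gid != gene_ids[length(gene_ids)]) {
        ev <- ev[ev$region == "cds", , drop = FALSE]  # internal UTRs unedited
      }
      off <- gi[1] - span0
      for (i in seq_len(nrow(ev))) {
        stopifnot(body[off + ev$pos[i] + 1L] == ev$from_base[i])
        body[off + ev$pos[i] + 1L] <- ev$to_base[i]
      }
    }
    paste(body, collapse = "")
  }

  tr_id <- character(0); tr_seq <- character(0); tr_desc <- character(0)
  tr_genes <- list()
  for (g in seq_len(n)) {
    row <- genes[g, ]
    body <- build_body(row$gene_id)
    tail <- if (row$polyu) strrep("T", row$tail_length) else ""
    tr_id <- c(tr_id, paste0(row$gene_id, "_t1"))
    tr_seq <- c(tr_seq, paste0(body, tail))
    tr_desc <- c(tr_desc, paste0("gene=", row$gene_id))
    tr_genes <- c(tr_genes, list(row$gene_id))
  }

  # dicistronic transcripts over adjacent same-strand functional pairs
  # whose downstream member is polyuridylylated
  pairs <- list()
  for (g in seq_len(n - 1L)) {
    if (genes$strand[g] != genes$strand[g + 1L]) next
    down <- if (genes$strand[g] == "+") g + 1L else g
    if (!genes$polyu[down]) next
    pairs <- c(pairs, list(c(g, g + 1L)))
  }
  pairs <- utils::head(pairs, config$n_polycistronic)
  for (pr in pairs) {
    ord <- if (genes$strand[pr[1L]] == "+") pr else rev(pr)
    gids <- genes$gene_id[ord]
    down <- genes[genes$gene_id == gids[2L], ]
    body <- build_body(gids)
    tail <- if (down$polyu) strrep("T", down$tail_length) else ""
    tr_id <- c(tr_id, paste0(paste(gids, collapse = "-"), "_t1"))
    tr_seq <- c(tr_seq, paste0(body, tail))
    tr_desc <- c(tr_desc, paste(paste0("gene=", gids), collapse = ";"))
    tr_genes <- c(tr_genes, list(gids))
  }

  # pseudogene transcripts: genomic copy, unedited, untailed
  for (i in seq_len(nrow(truth$pseudogenes))) {
    ps <- annotations[annotations$gene_id == truth$pseudogenes$gene_id[i], ]
    gi <- .cs_interval(ps, contig_len)
    tr_id <- c(tr_id, paste0(ps$gene_id, "_t1"))
    tr_seq <- c(tr_seq, substr(cs_cache[[ps$strand]], gi[1] + 1L, gi[2]))
    tr_desc <- c(tr_desc, paste0("gene=", ps$gene_id))
    tr_genes <- c(tr_genes, list(ps$gene_id))
  }

  transcripts <- data.frame(id = tr_id, sequence = tr_seq,
                            description = tr_desc, stringsAsFactors = FALSE)
  truth$events <- events
  truth$n_editable_sites <- length(site_base)
  truth$transcript_genes <- stats::setNames(tr_genes, tr_id)
  truth$gene_cds <- stats::setNames(gene_cds, genes$gene_id)
  list(transcripts = transcripts, truth = truth)
}

#' Generate ortholog protein sequences with hotspot-coupled divergence
#'
#' The query protein of each functional gene is the translation (table 11)
#' of the genomic CDS with its premature stops corrected.  The ortholog is
#' that protein with independent per-residue substitutions at the base
#' rate, plus extra substitutions in residues encoded by hotspot codons,
#' coupling low conservation to high editing density.
#'
#' @param genome,annotations,truth Generator state (after
#'   [generate_transcripts()]).
#' @param config The `synthetic_config`.
#' @return List with `orthologs` (data frame `id`, `sequence`; ids equal
#'   gene ids) and `queries` (the corrected-CDS translations).
#' @export
generate_ortholog_proteins <- function(genome, annotations, truth, config) {
  set.seed(config$seed + 2000L)
  genes <- truth$genes
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ids <- genes$gene_id
  queries <- character(length(ids))
  orths <- character(length(ids))
  for (g in seq_along(ids)) {
    cds <- truth$gene_cds[[ids[g]]]
    st <- truth$premature_stops[truth$premature_stops$gene_id == ids[g], ]
    for (i in seq_len(nrow(st))) {
      substr(cds, 3L * st$codon_index[i] + 1L, 3L * st$codon_index[i] + 3L) <-
        st$corrected_codon[i]
    }
    ncod <- nchar(cds) %/% 3L
    aa <- translate_codon(substring(cds, 3L * (seq_len(ncod) - 1L) + 1L,
                                    3L * seq_len(ncod)))
    if (aa[ncod] == "*") aa <- aa[-ncod]
    queries[g] <- paste(aa, collapse = "")
    p <- rep(config$ortholog_sub_rate, length(aa))
    hs <- truth$hotspots[truth$hotspots$gene_id == ids[g], ]
    if (nrow(hs)) {
      cod <- seq.int(hs$start %/% 3L, hs$end %/% 3L - 1L) + 1L
      cod <- cod[cod <= length(p)]
      p[cod] <- pmin(1, p[cod] + config$hotspot_ortholog_extra)
    }
    sub <- stats::runif(length(aa)) < p
    aa[sub] <- vapply(aa[sub], function(x) sample(setdiff(aa20, x), 1L),
                      character(1))
    orths[g] <- paste(aa, collapse = "")
  }
  list(orthologs = data.frame(id = ids, sequence = orths,
                              description = "synthetic ortholog",
                              stringsAsFactors = FALSE),
       queries = stats::setNames(queries, ids))
}

#' Generate a minicircle contig with terminal redundancy
#'
#' Emits a linear contig equal to a random circle of `circle_length` nt
#' followed by its own first `circle_redundancy` nt (the signature of an
#' assembler walking around a circular template), carrying one annotated
#' gene and exactly one copy of the restriction motif.
#'
#' @param config A `synthetic_config`.
#' @return List with `contig` (one-row data frame), `annotation` (one
#'   gene on the circle) and `truth` (planted parameters).
#' @export
generate_minicircle_contig <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$circle_redundancy >= config$circle_length) {
    .stopf("redundancy must be smaller than the circle")
  }
  set.seed(config$seed + 3000L)
  L <- config$circle_length
  motif <- .norm_nt(config$circle_motif)
  m <- nchar(motif)

  gene_len <- 3L * ((min(1800L, L - 400L)) %/% 3L)
  gene_start <- 100L
  circle <- .rand_seq(L)
  substr(circle, gene_start + 1L, gene_start + gene_len) <-
    .rand_cds(gene_len %/% 3L)
  motif_pos <- sample(seq.int(gene_start + gene_len + 20L, L - m - 20L), 1L)
  substr(circle, motif_pos + 1L, motif_pos + m) <- motif

  # remove accidental motif copies (both strands, wrap-around) without
  # creating in-frame stops inside the planted gene
  fix_occurrences <- function(circle) {
    for (iter in 1:20) {
      dbl <- paste0(circle, substr(circle, 1L, m - 1L))
      hits <- unique(c(
        Biostrings::start(Biostrings::matchPattern(
          motif, Biostrings::DNAString(dbl))) - 1L,
        Biostrings::start(Biostrings::matchPattern(
          .revcomp(motif), Biostrings::DNAString(dbl))) - 1L))
      hits <- hits[hits < L & hits != motif_pos]
      if (!length(hits)) return(circle)
      h <- hits[1L]
      j <- (h + m %/% 2L) %% L   # break the middle of the occurrence
      cur <- substr(circle, j + 1L, j + 1L)
      for (repl in setdiff(DNA_BASES, cur)) {
        cand <- .set_base(circle, j, repl)
        in_gene <- j >= gene_start && j < gene_start + gene_len
        if (in_gene) {
          k <- (j - gene_start) %/% 3L
          codon <- substr(cand, gene_start + 3L * k + 1L,
                          gene_start + 3L * k + 3L)
          if (.is_stop_codon(codon) && k < gene_len %/% 3L - 1L) next
        }
        circle <- cand
        break
      }
    }
    circle
  }
  circle <- fix_occurrences(circle)

  contig <- data.frame(
    id = "mc1",
    sequence = paste0(circle, substr(circle, 1L, config$circle_redundancy)),
    description = "synthetic minicircle contig (terminal redundancy)",
    stringsAsFactors = FALSE)
  annotation <- data.frame(
    gene_id = "mcg1", genome_id = "mc1", start = gene_start,
    end = gene_start + gene_len, strand = "+", feature_class = "CDS",
    category = "housekeeping", pseudogene = FALSE, stringsAsFactors = FALSE)
  list(contig = contig, annotation = annotation,
       truth = list(circle_length = L,
                    redundancy = config$circle_redundancy,
                    motif = motif, motif_pos = motif_pos,
                    circle = circle))
}

#' Generate a complete synthetic plastome data set
#'
#' Runs all generator stages and returns every input the analysis pipeline
#' consumes, together with the full ground-truth manifest.
#'
#' @param config A `synthetic_config` (default: `synthetic_config()`).
#' @return Object of class `synthetic_plastome`: `genomes` (chromosome and
#'   minicircle contigs), `annotations`, `transcripts`, `orthologs`,
#'   `queries` and `truth`.
#' @export
synth_plastome <- function(config = synthetic_config()) {
  ga <- generate_genome_and_annotations(config)
  tr <- generate_transcripts(ga$genome, ga$annotations, ga$truth, config)
  op <- generate_ortholog_proteins(ga$genome, ga$annotations, tr$truth,
                                   config)
  mc <- generate_minicircle_contig(config)
  truth <- tr$truth
  truth$minicircle <- mc$truth
  structure(list(
    genomes = rbind(ga$genome, mc$contig),
    annotations = rbind(ga$annotations, mc$annotation),
    transcripts = tr$transcripts,
    orthologs = op$orthologs,
    queries = op$queries,
    truth = truth,
    config = config
  ), class = "synthetic_plastome")
}

#' @export
print.synthetic_plastome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_plastome> seed %d: %d genes (+%d pseudogenes), %d transcripts, %d planted events\n",
    x$config$seed, x$config$n_genes, x$config$n_pseudogenes,
    nrow(x$transcripts), nrow(x$truth$events)))
  invisible(x)
}
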