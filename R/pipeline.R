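# One-command orchestration: poly(U) calling (tail stripping first, so
# tails are never miscalled as 3' editing clusters), editing calls and
# census, window statistics, minicircle scan, report tables and a run
# manifest.

#' Build a pipeline run configuration
#'
#' Either synthetic mode (`synthetic = TRUE`, everything generated from
#' `synth` and its seed) or real mode (paths to FASTA/annotation inputs;
#' transcripts are assigned to genes via `gene=<id>` tokens, semicolon
#' separated in genomic order for polycistronic transcripts, in the FASTA
#' description).
#'
#' @param synthetic Generate inputs with [synth_plastome()]?
#' @param synth A `synthetic_config` for synthetic mode.
#' @param genome,annotations,transcripts,orthologs Input paths (real mode).
#' @param annotation_dialect `"tsv"` or `"gff3"`.
#' @param min_tail Minimum poly(U) tail length (nt).
#' @param flank Genomic flank for transcript alignment (nt).
#' @param window,step Window statistics parameters (nt).
#' @param matrix Protein substitution matrix name.
#' @param background Region-enrichment background mode.
#' @param region_length Region length for the per-gene densest-window
#'   enrichment report (nt).
#' @param min_overlap Minimum terminal redundancy for circularity (nt).
#' @param motif Restriction motif mapped on detected circles.
#' @param stages Character subset of
#'   `c("polyu", "editing", "windows", "minicircle")`.
#' @param out_dir Optional output directory for report tables.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, synth = synthetic_config(),
                       genome = NULL, annotations = NULL,
                       transcripts = NULL, orthologs = NULL,
                       annotation_dialect = "tsv",
                       min_tail = 5L, flank = 400L,
                       window = 60L, step = 3L, matrix = "BLOSUM62",
                       background = "exclusive", region_length = 84L,
                       min_overlap = 20L, motif = "GAATTC",
                       stages = c("polyu", "editing", "windows",
                                  "minicircle"),
                       out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!synthetic) {
    for (p in c(genome, annotations, transcripts)) {
      if (is.null(p) || !file.exists(p)) {
        .stopf("real mode requires existing genome/annotations/transcripts")
      }
    }
  }
  structure(list(
    synthetic = synthetic, synth = synth, genome = genome,
    annotations = annotations, transcripts = transcripts,
    orthologs = orthologs, annotation_dialect = annotation_dialect,
    min_tail = as.integer(min_tail), flank = as.integer(flank),
    window = as.integer(window), step = as.integer(step), matrix = matrix,
    background = background, region_length = as.integer(region_length),
    min_overlap = as.integer(min_overlap), motif = motif,
    stages = stages, out_dir = out_dir), class = "run_config")
}

# translation of a CDS (coding-strand) with a set of gene-relative events
# applied; returns the residue string without the terminal stop
.edited_protein <- function(cds, events) {
  s <- strsplit(cds, "")[[1]]
  ev <- events[!is.na(events$genome_pos) & events$genome_pos >= 0 &
                 events$genome_pos < length(s), , drop = FALSE]
  s[ev$genome_pos + 1L] <- ev$to_base
  ncod <- length(s) %/% 3L
  cds2 <- paste(s, collapse = "")
  aa <- translate_codon(substring(cds2, 3L * (seq_len(ncod) - 1L) + 1L,
                                  3L * seq_len(ncod)))
  aa <- aa[!is.na(aa)]
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Run the full transcript-processing analysis
#'
#' Executes poly(U) calling, editing analysis, window statistics and the
#' minicircle scan in order, on synthetic or real inputs, and assembles
#' all report tables plus a machine-readable run manifest.  When several
#' transcripts cover a gene, the first (monocistronic) one defines the
#' gene's surveyed region and event set.
#'
#' @param config A `run_config`.
#' @return Object of class `plastid_run`: `tables` (named list of report
#'   data frames), `global_summary` (an `editing_summary`), `calls`
#'   (poly(U) call objects), `manifest`.  If `config$out_dir` is set the
#'   tables, canonical circle FASTA and manifest JSON are also written.
#' @export
run_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$synthetic) {
    sp <- synth_plastome(config$synth)
    genomes <- sp$genomes
    ann <- sp$annotations
    transcripts <- sp$transcripts
    orthologs <- sp$orthologs
    gene_map <- sp$truth$transcript_genes
  } else {
    genomes <- read_sequences(config$genome, "genome")
    ann <- read_annotations(config$annotations, config$annotation_dialect,
                            genome = genomes)
    transcripts <- read_sequences(config$transcripts, "transcript")
    orthologs <- if (!is.null(config$orthologs)) {
      read_sequences(config$orthologs, "protein")
    } else NULL
    gene_map <- lapply(transcripts$description, function(d) {
      toks <- regmatches(d, gregexpr("gene=[^;[:space:]]+", d))[[1]]
      sub("^gene=", "", toks)
    })
    names(gene_map) <- transcripts$id
  }

  calls <- list()
  events_by_gene <- list()
  surveyed <- integer(0)
  notes <- character(0)

  for (ti in seq_len(nrow(transcripts))) {
    tr <- transcripts[ti, , drop = FALSE]
    gids <- gene_map[[tr$id]]
    gids <- gids[gids %in% ann$gene_id]
    if (!length(gids)) {
      notes <- c(notes, sprintf("transcript %s: no gene assignment", tr$id))
      next
    }
    rows <- ann[match(gids, ann$gene_id), , drop = FALSE]
    contig <- genomes[genomes$id == rows$genome_id[1L], , drop = FALSE]
    span <- list(gene_id = paste(gids, collapse = "-"),
                 strand = rows$strand[1L],
                 start = min(rows$start), end = max(rows$end),
                 feature_class = "CDS")
    call <- tryCatch(
      detect_poly_u_tail(tr, span, contig, min_tail = config$min_tail,
                         flank = config$flank),
      error = function(e) {
        notes <<- c(notes, sprintf("transcript %s: %s", tr$id,
                                   conditionMessage(e)))
        NULL
      })
    if (is.null(call)) next
    # the poly(U) site is annotated relative to the downstream member gene
    cs_starts <- vapply(seq_along(gids), function(i) {
      .cs_interval(rows[i, , drop = FALSE], nchar(contig$sequence))[1]
    }, numeric(1))
    call$gene_id <- gids[which.max(cs_starts)]
    if ("polyu" %in% config$stages) {
      call <- tryCatch(annotate_poly_u_site(call, ann),
                       error = function(e) call)
    }
    calls[[tr$id]] <- call

    if ("editing" %in% config$stages) {
      for (i in seq_along(gids)) {
        g <- gids[i]
        if (!is.null(events_by_gene[[g]])) next  # first transcript wins
        ev <- call_editing_events(call$alignment, rows[i, , drop = FALSE])
        gi <- .cs_interval(rows[i, , drop = FALSE], nchar(contig$sequence))
        cols <- call$alignment$columns
        aligned <- cols$gpos[cols$state %in% c("match", "mismatch")]
        aligned <- aligned[!is.na(aligned)]
        events_by_gene[[g]] <- ev
        # surveyed region of the gene: its aligned CDS columns, plus the
        # aligned 3'-UTR when this gene carries the transcript's poly(U)
        # site
        surveyed[g] <- sum(aligned >= gi[1] & aligned < gi[2]) +
          if (call$gene_id == g) sum(aligned >= gi[2]) else 0L
      }
    }
  }

  all_events <- do.call(rbind, c(list(.empty_events()),
                                 unname(events_by_gene)))
  tables <- list()

  if ("polyu" %in% config$stages) {
    tables$polyu_calls <- do.call(rbind, c(
      list(data.frame(transcript_id = character(0), gene_id = character(0),
                      tail_length = integer(0), site = integer(0),
                      templated_run = integer(0), status = character(0),
                      utr_length = integer(0),
                      overlaps_downstream_cds = logical(0),
                      cistron_class = character(0), cistrons = character(0),
                      stringsAsFactors = FALSE)),
      lapply(calls, function(x) data.frame(
        transcript_id = x$transcript_id, gene_id = x$gene_id,
        tail_length = x$tail_length, site = x$site_genome_pos + 1L,
        templated_run = x$templated_run, status = x$status,
        utr_length = x$utr_length,
        overlaps_downstream_cds = x$overlaps_downstream_cds,
        cistron_class = x$cistron_class,
        cistrons = paste(x$cistron_gene_ids, collapse = ","),
        stringsAsFactors = FALSE))))
    rownames(tables$polyu_calls) <- NULL
  }

  global_summary <- NULL
  if ("editing" %in% config$stages) {
    tables$editing_events <- format_editing_events(all_events)
    gene_rows <- lapply(names(events_by_gene), function(g) {
      s <- summarize_editing(events_by_gene[[g]], max(1L, surveyed[g]))
      data.frame(gene_id = g, surveyed_length = s$surveyed_length,
                 total_events = s$total_events,
                 as.list(s$counts), check.names = FALSE,
                 pct_bases_edited = round_half_up(s$pct_bases_edited, 2),
                 pct_transitions = round_half_up(s$pct_transitions, 1),
                 pct_gc_enrich = round_half_up(s$pct_gc_enrich, 1),
                 pct_nonsynonymous = round_half_up(s$pct_nonsynonymous, 1),
                 stringsAsFactors = FALSE)
    })
    total_surveyed <- max(1L, sum(surveyed))
    global_summary <- summarize_editing(all_events, total_surveyed)
    g <- global_summary
    tables$editing_summary <- do.call(rbind, c(gene_rows, list(data.frame(
      gene_id = "ALL", surveyed_length = g$surveyed_length,
      total_events = g$total_events, as.list(g$counts), check.names = FALSE,
      pct_bases_edited = round_half_up(g$pct_bases_edited, 2),
      pct_transitions = round_half_up(g$pct_transitions, 1),
      pct_gc_enrich = round_half_up(g$pct_gc_enrich, 1),
      pct_nonsynonymous = round_half_up(g$pct_nonsynonymous, 1),
      stringsAsFactors = FALSE))))

    # premature stop correction per covered CDS gene
    stop_rows <- list()
    for (g in names(events_by_gene)) {
      row <- ann[ann$gene_id == g, , drop = FALSE]
      if (row$feature_class != "CDS" || row$pseudogene) next
      contig <- genomes[genomes$id == row$genome_id, , drop = FALSE]
      holder <- Filter(function(tid) g %in% gene_map[[tid]], names(calls))
      if (!length(holder)) next
      st <- verify_stop_correction(row, contig,
                                   calls[[holder[[1L]]]]$alignment)
      if (nrow(st)) {
        st <- cbind(gene_id = g, st, stringsAsFactors = FALSE)
        stop_rows <- c(stop_rows, list(st))
      }
    }
    tables$stop_correction <- do.call(rbind, c(
      list(data.frame(gene_id = character(0), codon_index = integer(0),
                      stop_codon = character(0),
                      transcript_codon = character(0),
                      status = character(0), stringsAsFactors = FALSE)),
      stop_rows))

    # paralog discrimination: each pseudogene against its most-edited
    # same-category functional gene of comparable length (synthetic truth
    # supplies the true source pairing when available)
    par_rows <- list()
    ps <- ann[ann$pseudogene, , drop = FALSE]
    for (i in seq_len(nrow(ps))) {
      g <- ps$gene_id[i]
      if (is.null(events_by_gene[[g]])) next
      src_id <- if (config$synthetic) {
        sp$truth$pseudogenes$source_gene_id[
          sp$truth$pseudogenes$gene_id == g]
      } else {
        cand <- names(events_by_gene)
        cand <- cand[cand %in% ann$gene_id[!ann$pseudogene]]
        if (!length(cand)) next
        cand[which.max(vapply(cand, function(x)
          nrow(events_by_gene[[x]]), numeric(1)))]
      }
      if (!length(src_id) || is.null(events_by_gene[[src_id]])) next
      pv <- paralog_discrimination_test(
        k_obs = nrow(events_by_gene[[g]]), len_a = surveyed[g],
        k_ref = nrow(events_by_gene[[src_id]]), len_b = surveyed[src_id])
      par_rows <- c(par_rows, list(data.frame(
        pseudogene = g, reference = src_id,
        k_obs = nrow(events_by_gene[[g]]),
        k_ref = nrow(events_by_gene[[src_id]]),
        p_value = pv, stringsAsFactors = FALSE)))
    }
    tables$paralog_tests <- do.call(rbind, c(
      list(data.frame(pseudogene = character(0), reference = character(0),
                      k_obs = integer(0), k_ref = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)),
      par_rows))
  }

  if ("windows" %in% config$stages && !is.null(orthologs)) {
    track_rows <- list(); corr_rows <- list(); enr_rows <- list()
    for (g in names(events_by_gene)) {
      orth <- orthologs[orthologs$id == g, , drop = FALSE]
      if (nrow(orth) == 0L) next
      row <- ann[ann$gene_id == g, , drop = FALSE]
      contig <- genomes[genomes$id == row$genome_id, , drop = FALSE]
      gi <- .cs_interval(row, nchar(contig$sequence))
      cds <- substr(.cs_seq(contig$sequence, row$strand), gi[1] + 1L, gi[2])
      query <- .edited_protein(cds, events_by_gene[[g]])
      nt_len <- 3L * nchar(query)
      if (nt_len < config$window) next
      et <- window_editing_track(events_by_gene[[g]], nt_len,
                                 config$window, config$step, gene_id = g)
      ct <- tryCatch(
        window_conservation_track(query, orth$sequence, config$window,
                                  config$step, config$matrix, gene_id = g),
        error = function(e) NULL)
      if (is.null(ct) || length(ct$starts) != length(et$starts)) next
      track_rows <- c(track_rows, list(data.frame(
        gene_id = g, start = et$starts + 1L,
        editing_fraction = et$values, conservation = ct$values,
        stringsAsFactors = FALSE)))
      cr <- tryCatch(correlate_tracks(et, ct), error = function(e) NULL)
      if (!is.null(cr)) {
        corr_rows <- c(corr_rows, list(data.frame(
          gene_id = g, r = cr$r, n = cr$n, p_value = cr$p_value,
          stringsAsFactors = FALSE)))
      }
      # densest region of the gene vs the rest
      pos <- events_by_gene[[g]]$genome_pos
      pos <- pos[!is.na(pos) & pos >= 0 & pos < nt_len]
      if (length(pos) && nt_len > config$region_length) {
        reg_starts <- seq.int(0L, nt_len - config$region_length, by = 3L)
        kvec <- vapply(reg_starts, function(s)
          sum(pos >= s & pos < s + config$region_length), integer(1))
        best <- reg_starts[which.max(kvec)]
        er <- region_enrichment_test(max(kvec), config$region_length,
                                     length(unique(pos)), nt_len,
                                     background = config$background)
        enr_rows <- c(enr_rows, list(data.frame(
          gene_id = g, region_start = best + 1L,
          region_length = config$region_length, k = er$k,
          background_rate = er$background_rate,
          binomial_p = er$binomial_p, chisq_p = er$chisq_p,
          stringsAsFactors = FALSE)))
      }
    }
    tables$window_tracks <- do.call(rbind, c(
      list(data.frame(gene_id = character(0), start = integer(0),
                      editing_fraction = numeric(0),
                      conservation = numeric(0), stringsAsFactors = FALSE)),
      track_rows))
    tables$correlations <- do.call(rbind, c(
      list(data.frame(gene_id = character(0), r = numeric(0),
                      n = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)),
      corr_rows))
    tables$enrichment <- do.call(rbind, c(
      list(data.frame(gene_id = character(0), region_start = integer(0),
                      region_length = integer(0), k = integer(0),
                      background_rate = numeric(0), binomial_p = numeric(0),
                      chisq_p = numeric(0), stringsAsFactors = FALSE)),
      enr_rows))
  }

  circle_fastas <- list()
  if ("minicircle" %in% config$stages) {
    mc_rows <- list()
    for (ci in seq_len(nrow(genomes))) {
      contig <- genomes[ci, , drop = FALSE]
      mc <- tryCatch(
        detect_terminal_redundancy(contig, config$min_overlap),
        error = function(e) NULL)
      if (is.null(mc)) next
      n_sites <- NA_integer_
      if (mc$is_circular) {
        mc <- canonicalize_circle(mc, ann)
        sites <- find_restriction_sites(mc, config$motif)
        n_sites <- nrow(sites)
        circle_fastas[[contig$id]] <- data.frame(
          id = paste0(contig$id, "_circle"),
          sequence = mc$canonical_sequence,
          description = paste0("canonical circle; anchor ",
                               mc$rotation_anchor),
          stringsAsFactors = FALSE)
      }
      mc_rows <- c(mc_rows, list(data.frame(
        contig_id = mc$contig_id, is_circular = mc$is_circular,
        terminal_overlap = mc$terminal_overlap,
        circle_length = mc$circle_length,
        rotation_anchor = mc$rotation_anchor,
        n_motif_sites = n_sites, stringsAsFactors = FALSE)))
    }
    tables$minicircles <- do.call(rbind, c(
      list(data.frame(contig_id = character(0), is_circular = logical(0),
                      terminal_overlap = integer(0),
                      circle_length = integer(0),
                      rotation_anchor = character(0),
                      n_motif_sites = integer(0), stringsAsFactors = FALSE)),
      mc_rows))
  }

  manifest <- list(
    package = "plastidproc",
    version = as.character(utils::packageVersion("plastidproc")),
    stages = config$stages,
    synthetic = config$synthetic,
    seed = if (config$synthetic) config$synth$seed else NA,
    parameters = list(min_tail = config$min_tail, flank = config$flank,
                      window = config$window, step = config$step,
                      matrix = config$matrix,
                      background = config$background,
                      min_overlap = config$min_overlap,
                      motif = config$motif),
    notes = notes)

  run <- structure(list(tables = tables, global_summary = global_summary,
                        calls = calls, events = all_events,
                        manifest = manifest), class = "plastid_run")
  if (!is.null(config$out_dir)) {
    write_report_tables(run, config$out_dir)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (cf in circle_fastas) {
      write_sequences(cf, file.path(config$out_dir,
                                    paste0(cf$id, ".fasta")))
    }
  }
  run
}

#' @export
print.plastid_run <- function(x, ...) {
  cat("<plastid_run>\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %s: %d rows\n", nm, nrow(x$tables[[nm]])))
  }
  if (length(x$manifest$notes)) {
    cat("  notes:\n")
    for (n in x$manifest$notes) cat("   -", n, "\n")
  }
  invisible(x)
}

#' @export
summary.plastid_run <- function(object, ...) {
  if (!is.null(object$global_summary)) print(object$global_summary)
  print(object)
  invisible(object)
}
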