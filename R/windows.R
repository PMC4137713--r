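# Sliding-window editing and conservation tracks, their Pearson
# correlation, and the enrichment / association tests.

.new_track <- function(gene_id, window, step, starts, values) {
  structure(list(gene_id = gene_id, window = as.integer(window),
                 step = as.integer(step), starts = as.integer(starts),
                 values = as.numeric(values)),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("<window_track> %s: %d windows of %d nt (step %d), mean %.3f\n",
              x$gene_id %||% "?", length(x$starts), x$window, x$step,
              mean(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sliding-window editing-frequency track
#'
#' The value of the window starting at CDS-relative position `s` (0-based)
#' is the number of edited positions in `[s, s + window)` divided by the
#' window length.
#'
#' @param events Classified editing events for one gene (the CDS-relative
#'   `genome_pos` column is used; events outside `[0, cds_length)` are
#'   ignored).
#' @param cds_length Length of the analyzed CDS (nt), must be >= `window`.
#' @param window Window length in nt (default 60).
#' @param step Step between window starts in nt (default 3, codon-aligned).
#' @param gene_id Optional gene label carried on the track.
#' @return A `window_track`.
#' @export
window_editing_track <- function(events, cds_length, window = 60L,
                                 step = 3L, gene_id = NULL) {
  stopifnot(step >= 1L)
  if (cds_length < window) .stopf("gene too short for windowing (%d < %d)",
                                  cds_length, window)
  pos <- events$genome_pos
  pos <- pos[!is.na(pos) & pos >= 0L & pos < cds_length]
  pos <- unique(pos)
  starts <- seq.int(0L, cds_length - window, by = step)
  values <- vapply(starts, function(s) {
    sum(pos >= s & pos < s + window) / window
  }, numeric(1))
  .new_track(gene_id %||% unique(events$gene_id)[1], window, step,
             starts, values)
}

#' Sliding-window protein conservation track
#'
#' Computes one global protein alignment between the query (the in-silico
#' translation of the edited transcript) and an ortholog, then scores each
#' nucleotide window over the query: identical aligned residues count 1,
#' positives (substitution-matrix score > 0 but not identical) count 0.5,
#' and query residues aligned to gaps count 0; the window value is the
#' summed score divided by the number of codons in the window.
#'
#' @param query_protein,ortholog_protein Amino-acid strings.
#' @param window Window length in nt, divisible by 3 (default 60).
#' @param step Step in nt (default 3).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gene_id Optional gene label.
#' @return A `window_track` whose starts match those of
#'   [window_editing_track()] run over `3 * nchar(query_protein)` nt.
#' @export
window_conservation_track <- function(query_protein, ortholog_protein,
                                      window = 60L, step = 3L,
                                      matrix = "BLOSUM62", gene_id = NULL) {
  if (window %% 3L != 0L) .stopf("window must be divisible by 3")
  if (!nzchar(ortholog_protein)) .stopf("empty ortholog")
  mat <- get(utils::data(list = matrix, package = "Biostrings",
                         envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    pattern = query_protein, subject = ortholog_protein, type = "global",
    substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  nres <- nchar(query_protein)
  score <- numeric(nres)
  qi <- 0L
  for (i in seq_along(pat)) {
    if (pat[i] == "-") next
    qi <- qi + 1L
    if (sub[i] == "-") next
    if (pat[i] == sub[i]) {
      score[qi] <- 1
    } else if (pat[i] %in% rownames(mat) && sub[i] %in% colnames(mat) &&
               mat[pat[i], sub[i]] > 0) {
      score[qi] <- 0.5
    }
  }
  nt_len <- 3L * nres
  if (nt_len < window) .stopf("gene too short for windowing (%d < %d)",
                              nt_len, window)
  starts <- seq.int(0L, nt_len - window, by = step)
  codons_per_window <- window %/% 3L
  values <- vapply(starts, function(s) {
    first <- s %/% 3L + 1L
    idx <- first:(first + codons_per_window - 1L)
    # windows not codon-aligned borrow the codon containing their start
    idx <- idx[idx <= nres]
    sum(score[idx]) / codons_per_window
  }, numeric(1))
  .new_track(gene_id, window, step, starts, values)
}

#' Pearson correlation between two window tracks
#'
#' @param a,b `window_track` objects with identical starts and at least
#'   3 windows; both must be non-constant.
#' @return Object of class `correlation_result` with `r`, `n`, `t_stat`
#'   and the two-sided `p_value` from the t distribution with n - 2 df.
#' @export
correlate_tracks <- function(a, b) {
  if (length(a$starts) != length(b$starts) ||
      !all(a$starts == b$starts)) {
    .stopf("tracks have different windows")
  }
  n <- length(a$values)
  if (n < 3L) .stopf("need at least 3 windows")
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0) {
    .stopf("zero variance track")
  }
  r <- stats::cor(a$values, b$values)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p <- max(p, .Machine$double.xmin)
  structure(list(r = r, n = n, t_stat = t_stat, p_value = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (n = %d windows), p = %.3g\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Enrichment of editing in a region versus the gene background
#'
#' Tests whether `k` edited positions over an `n`-nt region exceed the
#' background editing rate of the rest of the gene.  The binomial test
#' uses, by default, the background excluding the tested region (avoiding
#' self-contamination); the chi-squared test is Pearson's on the 2x2
#' region-by-edited table, 1 df, without continuity correction.
#'
#' @param k Edited positions in the region.
#' @param n Region length (nt).
#' @param total_k Edited positions in the whole gene (including region).
#' @param total_n Gene length (nt).
#' @param background `"exclusive"` (default) or `"inclusive"` of the region.
#' @return Object of class `enrichment_result` with `k`, `n`,
#'   `background_rate`, `binomial_p` (upper tail), `chisq_p` and a
#'   `low_expected` flag when any expected cell count is below 5.
#' @export
region_enrichment_test <- function(k, n, total_k, total_n,
                                   background = c("exclusive", "inclusive")) {
  background <- match.arg(background)
  stopifnot(n >= 1L, k >= 0L, k <= n, total_k >= k, total_n > n)
  rate <- if (background == "exclusive") {
    (total_k - k) / (total_n - n)
  } else {
    total_k / total_n
  }
  if (rate == 0 && k > 0) {
    .warnf("background editing rate is zero")
    binomial_p <- 0
  } else {
    binomial_p <- stats::pbinom(k - 1L, size = n, prob = rate,
                                lower.tail = FALSE)
  }
  m <- rbind(region = c(edited = k, unedited = n - k),
             rest = c(total_k - k, (total_n - n) - (total_k - k)))
  ch <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(k = k, n = n, background_rate = rate,
                 binomial_p = binomial_p,
                 chisq_stat = unname(ch$statistic),
                 chisq_p = ch$p.value,
                 low_expected = any(ch$expected < 5)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %d/%d edited vs background %.4f: binomial p = %.3g, chi-squared p = %.3g%s\n",
    x$k, x$n, x$background_rate, x$binomial_p, x$chisq_p,
    if (x$low_expected) " [low expected counts]" else ""))
  invisible(x)
}

#' Chi-squared association test for a 2x2 category table
#'
#' Pearson chi-squared, 1 df, no continuity correction (e.g. poly(U)
#' presence by photosynthesis/housekeeping gene category).
#'
#' @param table 2x2 matrix of counts.
#' @return List with `statistic`, `p_value` and `low_expected` (any
#'   expected count < 5).
#' @export
category_association_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    .stopf("zero marginal in association table")
  }
  ch <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ch$statistic), p_value = ch$p.value,
       low_expected = any(ch$expected < 5))
}
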