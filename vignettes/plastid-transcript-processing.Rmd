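---
title: "Detecting RNA editing, poly(U) tails and minicircles in divergent plastid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA editing, poly(U) tails and minicircles in divergent plastid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidproc)
```

## The biological problem

Fucoxanthin dinoflagellate plastids carry serially acquired,
fast-evolving genomes whose transcripts are post-transcriptionally
reshaped by two pathways inherited from the ancestral peridinin plastid:
substitutional sequence editing and 3′ poly(U) tail addition. Editing
changes a few percent of transcribed bases — mostly A→G and U→C
transitions that push transcripts toward higher GC content — and can
rescue genomic lesions such as premature in-frame stop codons. Poly(U)
tails are added at a defined site shortly downstream of the stop codon
and discriminate functional transcripts from those of pseudogene
paralogs. Fragments of these genomes also occur on episomal minicircles,
which an assembler renders as a linear contig that re-reads its own
start: the two contig ends share an identical sequence.

`plastidproc` implements the complete measurement chain for these
phenomena and couples it to a seeded synthetic data generator so that
every stage can be validated against a known truth.

## Conventions

All sequences are held internally in the DNA alphabet (input U mapped to
T; transcript-facing report columns are rendered back as U), so genome
and transcript live in one comparison alphabet. Coordinates are 0-based
half-open on the forward strand internally and 1-based inclusive in
every report table; reverse-strand genes are handled by
reverse-complementing the contig, i.e. every per-gene computation works
in "coding-strand" coordinates. N bases are carried through but excluded
from editing and tail calls.

## Editing analysis

A transcript (tail-stripped, see below) is aligned globally against its
gene's genomic window (gene ± a flank, default 200 nt for plain calls
and 400 nt in the pipeline) with free end gaps on the genomic side.
Scoring is match +2, mismatch −1, gap open −8, gap extend −2. The cheap
mismatch matters: editing reaches ~24% of positions in the most
divergent genes, and the aligner must absorb dense substitution clusters
rather than break them into spurious indels. Transcripts whose identity
falls below 60% are rejected as wrong locus assignments rather than
silently scored.

Each mismatch column with two unambiguous bases becomes one editing
event. Indel columns are never events — editing in this system is
strictly substitutional, and transcript/genome indels are genomic
features reported through the alignment column table. Events are
classified three ways:

* **kind** — transition iff {from,to} is {A,G} or {C,U};
* **GC effect** — enriching iff A/U→G/C, depleting iff G/C→A/U;
* **coding effect** — by translating the genomic codon and the edited
  codon (all co-edits in the codon applied, so TGA→CAA is recognized
  from its two component events) under the bacterial/plastid genetic
  code (translation table 11): stop_loss, stop_gain, synonymous,
  nonsynonymous, or noncoding for UTR events. Codons containing N are
  "indeterminate" and excluded from the synonymous/nonsynonymous split.

`summarize_editing` tallies the 12 substitution types in a fixed order
and derives the percentage rows of a census table. Percentages are kept
at full precision and also rounded half-away-from-zero at the printed
precision; the category percentages use the event total as denominator,
and the synonymous/nonsynonymous split is computed over CDS events only.
Published census tables sometimes print a curated event total that
differs from the sum of their per-type rows; the optional `total_events`
argument reproduces such tables as printed and is otherwise left at
`sum(counts)`.

`detect_premature_stops` scans the annotated frame of a genomic CDS for
TAA/TAG/TGA strictly before the terminal codon, and
`verify_stop_correction` reads the transcript bases aligned over each
such codon: `corrected` when they no longer form a stop, `uncovered`
when the transcript does not span the codon.

Pseudogene transcripts are distinguished by editing depletion: with the
functional paralog's editing rate as the null, the exact one-sided
binomial probability of observing at most the pseudogene's event count
over its surveyed length (`paralog_discrimination_test`).

## Poly(U) analysis

Tail detection is deliberately conservative and non-destructive. A
terminal A run (the remnant of oligo-d(A)-primed RT) is trimmed only
when a U run of at least `min_tail` precedes it. The maximal terminal U
run is provisionally stripped; if shorter than `min_tail` (default 5 —
long enough to suppress one-or-two-base noise, short enough to pass
every tail the pathway produces) it is restored to the body and the
call is `status = "none"`. The body is aligned as above; the poly(U)
site is the genomic position of the last aligned body base.

Whether a tail could be genomically templated is decided against the
genomic T run starting immediately after the site: a tail longer than
the run cannot have been transcribed from the genome and is
`posttranscriptional`; a tail within the run is `possibly_templated`
(such sites can arise by primer misannealing on a genomic T tract, so
they are flagged rather than trusted). The tail itself must be a strict
U run; no mixed-tail slack is allowed by default.

Site annotation computes the UTR length (0 when the transcript ends at
the stop codon's last base; negative, with an `internal_site` remark,
when the site lies inside the CDS), flags sites inside a downstream
same-strand CDS, and lists the cistron content — all same-strand CDSs
intersected by the aligned body, giving the mono-/di-/tricistronic
classification.

## Window statistics

Editing density and protein conservation are compared over 60-bp
sliding windows. The step defaults to 3 nt so windows stay codon-aligned
and each window's translation is well defined; the window start list is
shared by both tracks, so they correlate window-for-window. The editing
track counts edited positions per window. The conservation track is
computed from one global protein alignment (BLOSUM62, gap open 11,
extend 1) between the query — the translation of the edited transcript —
and an ortholog: identities score 1, positives (positive matrix score,
not identical) score 0.5, query residues over gaps score 0, and each
window averages its 20 codons. One global alignment rather than
per-window local searches keeps the track deterministic and free of
window-boundary artifacts.

`correlate_tracks` reports the sample Pearson r with the two-sided
p-value from the t distribution on n − 2 degrees of freedom. Region
enrichment uses the exact binomial upper tail with the background rate
taken from the gene *excluding* the tested region (self-contamination
would otherwise shrink every signal; the inclusive variant is available
via `background = "inclusive"`), plus Pearson's chi-squared on the 2×2
table without continuity correction. Continuity correction is off in
all chi-squared tests here; expected counts below 5 set a warning flag
rather than switching methods. No multiple-testing correction is applied
across genes: the statistics are reported per gene.

## Minicircle detection

A contig is called circular when its longest exact suffix–prefix
self-match reaches `min_overlap` (default 20 nt, long enough that chance
end-identity is negligible at plastid contig sizes; the overlap must
also be exact — the phenomenon being detected is assembler re-traversal,
not homology). The circle is the contig minus the redundant suffix. An
overlap spanning half the contig or more is rejected as a degenerate
perfect repeat. The canonical rotation starts at an annotated gene's 5′
end when available and otherwise at the lexicographically smallest
rotation, making downstream coordinates invariant to how the assembler
happened to rotate the contig. Restriction sites are scanned on the
doubled sequence so motifs straddling the junction are found, on both
strands, with palindromic motifs (EcoRI GAATTC) reported once per
position.

## The synthetic data generator

`synthetic_config()` fixes the study conditions the generator emulates;
the defaults are: 30 genes of 300–1,500 nt on random strands separated
by 50–300 nt spacers; a genome-wide per-site editing probability of
0.043 with a 12-type spectrum dominated by A→G and U→C; 30% of genes
carrying an 84-nt hotspot edited at 4× the background; 11 genes with one
premature in-frame stop each, every one forcibly corrected in the
transcript (TAA→CAA, TAG→CAG, TGA→CAA — the TGA case producing two
events); 70% of genes polyuridylylated with tails of 5–19 nt; geometric
3′-UTR lengths of mean 30 nt; 7% of tailed genes with a genomic T run
(8–12 nt, drawn at least as long as the tail) at the site; UTR editing
at 1.6% per site; two frameshifted pseudogene paralogs emitted unedited
and untailed; ortholog proteins diverged at 15% per residue plus 50%
extra inside hotspot codons; and a 2,323-nt minicircle with 150 nt of
terminal redundancy and a single EcoRI site.

Three design points deserve explanation:

* **Type-spectrum weighting.** Editing is planted per-site (Bernoulli),
  but a site's probability is weighted by the from-base marginal of the
  configured type spectrum divided by the realized frequency of that
  base among editable sites (then by the hotspot multiplier), and the
  whole vector is rescaled so its mean is exactly the configured rate.
  The substituted base is then drawn from the spectrum conditional on
  the genomic base. This makes the realized 12-type proportions converge
  to the configured weights regardless of the genome's base composition,
  and keeps the genome-wide editing rate at its target even though
  hotspots locally multiply it.
* **Architecture planned at genome time.** UTR lengths, tail lengths and
  templated T runs constrain the genomic sequence itself (a templated
  site needs a T tract; a clean site needs a non-T base at and after the
  site so that the detector's run-stripping recovers exactly the planted
  tail), so the poly(U) architecture is decided while the intergenic
  spacers are written and recorded in the truth manifest. Facing genes
  sharing a spacer have their UTRs capped to half the spacer, which
  truncates the geometric distribution slightly (realized mean ≈ 28 nt
  against the nominal 30).
* **Forced stop correction.** Premature-stop codons are excluded from
  random editing and corrected by dedicated forced events, because the
  emulated system corrects *all* premature stops; leaving correction to
  chance would make that property unreproducible.

The truth manifest records every planted event, tail, stop, hotspot and
the minicircle geometry, and satisfies a reconstruction invariant:
applying the manifest to the genome rebuilds every emitted transcript
byte-for-byte (this is tested).

What the generator does **not** emulate: sequencing error, RT-PCR
chimeras, transcript abundance, positional autocorrelation of editing
beyond hotspots, and real codon usage. Passing truth-recovery tests
therefore demonstrates the correctness of the measurement chain under
clean alignments, not robustness to noisy real-world assemblies; on real
data the identity floor and the conservative templating rule are the
main guards.

## Pipeline and problem sizes

`run_analysis()` executes poly(U) calling before editing analysis — a
non-templated tail is not genomic sequence, and stripping it first
prevents tails from being miscalled as 3′ editing clusters — then window
statistics and the minicircle scan. When several transcripts cover a
gene (mono- and dicistronic), the first defines the gene's surveyed
region and event set, so the census never double-counts. All report
tables are deterministic for a fixed configuration and seed.

The bundled tests and the acceptance script run the generator at its
default 30-gene size (about 30 kb of coding sequence, ~1,200 events per
genome), and the seed-sweep for the editing–conservation correlation
uses 100 independent genomes; a full sweep completes in well under five
minutes on a single core.

## Known limitations

* Real-mode transcript-to-gene assignment relies on `gene=` tokens in
  FASTA descriptions; there is no automatic locus search.
* The conservation track assumes the ortholog aligns globally; a
  domain-shuffled ortholog would need a different alignment strategy.
* Editing calls are made from finished transcript sequences; detection
  from read pileups is out of scope.
* The chi-squared tests report a low-expected-count flag but no exact
  alternative; at the event counts this analysis targets the Pearson
  statistic is adequate.
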