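Package: plastidproc
Title: Plastid Transcript Processing: RNA Editing, Poly(U) Tails and
    Minicircle Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of transcript processing in divergent algal plastid
    genomes, in particular the fucoxanthin dinoflagellate type.  Aligns
    transcript sequences to their genomic loci and calls substitutional RNA
    editing events, classifying each as transition or transversion, by GC
    effect, and by coding consequence under the bacterial/plastid genetic
    code; detects non-templated 3' poly(U) tails and annotates poly(U)
    sites (UTR length, downstream-CDS overlap, cistron content); computes
    sliding-window editing-frequency and protein-conservation tracks and
    their Pearson correlation, with binomial and chi-squared enrichment
    tests; detects episomal minicircles from terminal sequence redundancy
    of assembled contigs and maps restriction sites circularly; and
    includes a fully seeded synthetic plastid genome/transcriptome
    generator with a ground-truth manifest for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
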