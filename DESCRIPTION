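Package: riboTE
Title: Ribosome-Profiling Translational Efficiency Analysis with Synthetic
    Benchmarks
Version: 0.1.0
Authors@R:
    person("riboTE", "Developers", email = "ribote@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for transcript-space ribosome
    profiling analysis: footprint quality control (length distribution,
    reading-frame distribution, metagene P-site periodicity),
    RPKM-based translational efficiency (TE) quantification,
    differential-translation calling with Benjamini-Hochberg FDR control,
    5'UTR sequence-feature analysis (length, GC content, base-pairing
    folding score, upstream ORFs, terminal oligopyrimidine tracts,
    G-quadruplex motifs), and hypergeometric gene-set over-representation.
    A first-class synthetic-data module generates transcriptomes, gene
    models and paired footprint/total-mRNA read libraries with planted TE
    effects and 5'UTR features, so every stage is testable end-to-end
    against generative ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
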