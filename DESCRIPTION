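Package: kakscan
Title: Replicate-Concordant Single-Cell Variant Profiling with Ka/Ks and
    Randomization Null Models
Version: 0.1.0
Authors@R:
    person("Ana", "Rivera", email = "ana.rivera@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing substitution variants called from
    single-cell whole-genome sequencing of bacteria under multiple
    exposure conditions. Implements replicate-concordance filtering of
    whole-genome-amplification artifacts, codon-level synonymous /
    non-synonymous effect annotation against a reference genome and GFF3
    annotation, breadth-of-coverage normalized Ka/Ks statistics at the
    genome and gene level, combinatorial (Pascal) and Monte Carlo
    continuum-randomization tests of variant hotspot non-randomness,
    noncoding variant characterization (distance to nearest gene,
    substitution spectrum, GC direction, multi-base substitutions),
    sample purity and coverage metrics, and a fully seeded synthetic-data
    generator that emulates the structure of single-cell variant data so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
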