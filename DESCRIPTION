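Package: neosexdiff
Title: Substitution-Direction Spectra and Early Neo-Sex Chromosome
    Differentiation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the earliest stages of sex-chromosome
    differentiation from multi-species gene alignments and sexed
    resequencing panels. Assigns nucleotide substitutions to lineages by
    maximum parsimony (three ingroup species, optionally with an
    outgroup), classifies them into the six strand-pooled direction
    categories, and tabulates per-region G+C content and CpG-deamination
    context to detect GC-biased gene conversion. Detects male-specific
    substitutions and indels from IUPAC-encoded diploid panels, assigns
    neo-X/neo-Y gametolog alleles, audits open reading frame integrity,
    and tests lineage rate asymmetry with Tajima's relative rate test and
    Nei-Gojobori-style per-branch dN/dS counting. A bundled
    context-dependent (CpG-aware) event simulator generates alignments
    and gametolog panels with replayable truth logs so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
biocViews: Genetics, Phylogenetics, SequenceMatching, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
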