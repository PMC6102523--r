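Package: burpevol
Title: Molecular Evolution Toolkit for the BURP Domain Gene Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying the evolution of the
    plant-specific BURP domain-containing gene family: identification of
    family members from protein sequences by the conserved C-terminal
    CH-dyad pattern, curation (longest isoform, complete ORF),
    neighbor-joining phylogeny with bootstrap support and subfamily
    assignment, protein-guided codon alignments, Nei-Gojobori (1986)
    Ka/Ks and fourfold-degenerate transversion (4DTv) distances,
    tandem/segmental duplication classification and molecular-clock
    dating (T = Ks/2*lambda), Goldman-Yang codon site models (M0, M3,
    M7, M8) and branch-site model A with likelihood-ratio tests and
    empirical-Bayes detection of positively selected sites, Gu type-I
    and type-II functional divergence between subfamily clusters, and
    IUPAC-pattern scanning of upstream promoter regions. A seedable
    synthetic gene-family generator with full ground truth makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
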