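Package: frameAlign
Title: Frameshift- and Stop-Codon-Aware Multiple Alignment of Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns protein-coding nucleotide sequences at the amino-acid
    level while explicitly modelling frameshifts (1-2 nucleotide deletions,
    written "!") and premature stop codons (written "*"), so that
    pseudogenes, error-bearing sequencing reads and mis-annotated coding
    sequences can be aligned without disrupting codon structure. Implements
    a 15-move frameshift-aware pairwise dynamic program with affine gap
    costs, progressive multiple alignment guided by a UPGMA tree under a
    sum-of-pairs objective with quasi-natural (pessimistic) gap counts,
    tree-driven 2-cut refinement, dual nucleotide/amino-acid FASTA output
    and a tabular frameshift/stop event report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
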