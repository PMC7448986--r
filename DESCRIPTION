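Package: chemrec
Title: Annotation and Selection Analysis of Chemosensory Receptor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homology-based annotation of odorant (OR), gustatory (GR) and
    ionotropic (IR) receptor gene families in genome assemblies: six-frame
    translated Smith-Waterman search with Karlin-Altschul e-values, exon-by-exon
    chaining of hits into candidate loci with 2-kb flanks, spliced
    protein-to-genome gene models (GT..AG introns, frameshift and premature-stop
    aware), retention and pseudogene classification rules, iterative two-round
    identification, and transcript-based completeness accounting. Downstream,
    family phylogenies (JTT distances, neighbor joining, bootstrap supports,
    outgroup rooting) yield 1:1 orthologue pairs between sister species, which
    are tested for positive selection with pairwise GY94 codon site models
    (M7 beta vs M8 beta-plus-omega), a likelihood-ratio test, and naive and
    Bayes empirical Bayes identification of positively selected sites. A
    synthetic-genome forge and codon-evolution simulator provide ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
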