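Package: coralphy
Title: Phylogenomic Tests of Scleractinian Monophyly and the Naked-Coral
    Hypothesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether stony corals (Scleractinia) form a
    monophyletic group or whether corallimorpharians are "naked corals"
    nested within them. Implements maximum-likelihood phylogenetic
    inference under GTR+G+I and JTT+G+I substitution models (Felsenstein
    pruning, branch-length and model optimization, NNI tree search,
    nonparametric bootstrap), Bayesian MCMC over topologies, supermatrix
    concatenation and partitioning with back-translation of amino-acid
    alignments to codons, per-gene topology classification against the
    two competing hypotheses, gene-tree concordance factors, and
    compositional and saturation diagnostics, together with a simulator
    of multi-gene datasets with known generating topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
SystemRequirements: C++11
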