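Package: stagedyn
Title: Stage-Wise Brain Transcriptome Dynamics with Permutation FDR,
    Orthogroup Overlap and Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bulk RNA-seq time courses over an ordered series of
    behavioural stages (e.g. the stages of paternal care), each contrasted
    against a circadian-matched control group within a brain region. Provides
    a negative-binomial likelihood-ratio test with trend-shrunk dispersions
    and an empirical false discovery rate built from sample-label
    permutations; set algebra over the stage series (stage-unique genes,
    pairwise overlap with hypergeometric tests, "added shared" genes with
    direction-concordance chi-square and a sign-flip directional set test); a
    Monte Carlo orthogroup-level test for cross-species overlap of gene sets;
    mutual-information plus RMSD transcriptional regulatory network inference
    with transcription-factor target enrichment; and a negative-binomial
    simulator that plants stage-unique, carryover and additive effects,
    TF-target structure, and shared orthogroup signal with recorded ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
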