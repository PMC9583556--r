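Package: crmscout
Title: Prediction of Cis-Regulatory Modules by Integrating TF ChIP-seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cis-regulatory modules (CRMs) and their constituent
    transcription factor binding sites (TFBSs) by integrating many TF ChIP-seq
    peak datasets. Peaks are filtered and extended to fixed-length windows,
    motifs are found per dataset, frequently co-occurring motif pairs are
    clustered into unique motifs (UMs), a weighted UM interaction network is
    built, UM binding sites are projected to the genome and linked into CRM
    candidates, and candidates are scored and assigned empirical p-values
    against a third-order Markov sequence null scored under a weight-shuffled
    network. Includes a synthetic-data generator for end-to-end testing, a
    semi-theoretic FDR estimator, a genome-budget calculator for the fraction
    of a genome encoding CRMs, and evaluation utilities (recall under the
    50%-of-shorter rule, matched random controls, proportion-of-neutrality
    analysis of conservation scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
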