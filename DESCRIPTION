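Package: mvsim
Title: Multi-View Regulatory Network and Expression Data Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates hierarchically modular, scale-free gene and miRNA
    regulatory networks by score-guided motif replication, simulates their
    dynamics with Hill-kinetics ordinary differential equation models of
    transcriptional and post-transcriptional regulation, and emits noisy
    multi-subject expression datasets (one view per molecular layer) with
    full ground-truth annotation. Includes validation metrics (degree-law
    fitting, clustering-coefficient scaling, path-length scoring of
    candidate interactions) and configuration-driven end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
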