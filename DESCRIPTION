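Package: genestates
Title: Gene-State Counting from Stochastic Transcription Models and
    Post-Induction mRNA Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-state stochastic models of transcription. Implements
    waiting-time statistics of the irreversible N-state promoter model and its
    moment-matched mapping onto an effective telegraph model, steady-state mRNA
    copy-number distributions from the truncated chemical master equation with
    Wasserstein-distance comparison and distribution-shape classification,
    exact moment dynamics and short-time power-law theory following gene
    induction, exact stochastic simulation of induction experiments with
    extrinsic noise and binomial capture, and inference of a lower bound on the
    number of gene states by log-log and delayed power-law regression with
    cell-level bootstrapping.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Matrix,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
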