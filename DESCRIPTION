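Package: aldmix
Title: Local Ancestry Inference and Admixture Mapping from Dense Phased Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Local and global ancestry inference in admixed individuals from
    dense phased marker data. Ancestral linkage disequilibrium within fixed
    centimorgan windows is summarized by principal components of surrogate
    ancestral panels, and window-level emissions are logistic principal
    component regressions inside a hidden Markov model whose parameters are
    sampled by a Metropolis-within-Gibbs MCMC. Includes a synthetic ancestral
    panel and admixed-chromosome simulator, marker/individual/chain quality
    control, and admixture-mapping (MALD) association statistics with
    fine-mapping models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
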