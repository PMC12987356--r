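Package: streamDMM
Title: Multi-Stream Dirichlet Multinomial Mixture Clustering of Acoustic Tokens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of daily activities from discretized
    household sound. Audio segments encoded by a residual-vector-quantizer
    neural codec are tokenized into acoustic words, filtered by cumulative
    term-frequency ratio and noise-word removal, and clustered with a
    Dirichlet multinomial mixture extended to multiple conditionally
    independent token streams (for example, beamforming directions). The
    package provides the Dirichlet multinomial likelihood, a collapsed
    Gibbs sampler over segment-level activity assignments, burstiness
    diagnostics on word count distributions, a synthetic corpus generator
    matching the model's generative process, and the majority-vote
    cluster-to-activity evaluation protocol with fold-based cross
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
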