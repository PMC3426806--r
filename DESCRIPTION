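Package: phaseCall
Title: Bayesian Base Calling for Four-Channel Sequencing-by-Synthesis
    Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Hierarchical Bayesian base caller for four-channel (A, C, G, T)
    fluorescence intensity data from sequencing-by-synthesis instruments.
    The sampling model is a mixture of four truncated multivariate normal
    distributions that accounts for fading (exponential decay of mean
    signal over cycles), phasing (autoregressive carry-over from the
    previous cycle) and channel cross-talk (structured component means
    coupling the A-C and G-T channel pairs). Posterior base probabilities
    are obtained by Markov chain Monte Carlo, turned into base calls with
    Phred-scaled qualities, and ranked through a Bayesian false discovery
    rate. A forward simulator of the same generative model, plain-text
    intensity readers and writers, FASTQ output and a command-line
    interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    mvtnorm,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'basecall-fdr.R'
    'io.R'
    'cli.R'
    'model-core.R'
    'mcmc.R'
    'simulate.R'
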