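Package: coalpf
Title: Demographic Inference from Whole Genomes with a Coalescent Particle Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers past effective population sizes and recombination rates
    from multiple whole-genome haplotypes under the coalescent with
    recombination. The sequence of local genealogies along the genome is
    treated as a continuous-locus Markov jump process and sampled with a
    waypointed particle filter; an unbounded-lookahead auxiliary resampling
    distribution built from a digest of future singletons and doubletons
    reduces bias in recent epochs; and epoch-wise coalescence rates are
    estimated by stochastic EM or Variational Bayes with conjugate Gamma
    posteriors. Includes a sequential (SMC'-type) coalescent simulator used
    both for inference proposals and for generating synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    vcfR,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
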