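Package: smurf
Title: Differentiable Sequence Alignment and Joint Alignment-Aware
    Contact Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A smooth, differentiable formulation of Smith-Waterman and
    Needleman-Wunsch pairwise alignment with affine gaps: the logsumexp
    relaxation of the alignment dynamic program yields a Gibbs
    distribution over alignment paths whose expected match matrix (the
    posterior alignment) is the derivative of the smoothed score.  On
    top of this kernel the package implements a learned alignment
    module (convolutional residue-context encodings scored by dot
    products), a GREMLIN-style Markov random field trained by masked
    language modelling on soft alignment profiles, joint
    alignment-and-model training for unsupervised contact prediction
    from unaligned sequences, contact and alignment-consistency
    evaluation metrics, and a fully seeded synthetic-family generator
    (planted-contact Potts model, Gibbs sampling, indel corruption)
    so the whole pipeline can be exercised end to end without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
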