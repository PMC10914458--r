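Package: scsabc
Title: Selection Among Structurally Constrained and Empirical Protein
    Substitution Models by Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("scsabc", "developers", email = "scsabc@example.org",
           role = c("aut", "cre"))
Description: Simulates protein sequence alignments along coalescent or
    user-supplied genealogies under empirical amino-acid substitution
    models and under site-dependent structurally constrained substitution
    (SCS) models in which fitness depends on the folding free energy of
    the sequence threaded onto a representative structure.  Summarises
    query and simulated alignments with seven statistics (folding free
    energy mean and standard deviation, segregating sites, and four
    moments of pooled Grantham distances) and estimates per-model
    posterior probabilities with rejection, multinomial-logistic and
    neural-network approximate Bayesian computation, including
    cross-validation and goodness-of-fit reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
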