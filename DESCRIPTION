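Package: rjsitemodel
Title: Bayesian Site-Model Averaging for Nucleotide Alignments by
    Reversible-Jump MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Averages over time-reversible nucleotide substitution models,
    gamma rate heterogeneity, a proportion of invariable sites and
    equal versus estimated base frequencies within a single Markov chain,
    using trans-dimensional (reversible-jump) split and merge moves on the
    partition lattice of the six exchangeability rates.  Provides the full
    203-model reversible space, a 31-model transition/transversion split
    space and a 9-model named space, a Felsenstein pruning likelihood with
    pattern compression and a constant-time invariant-site term, a sequence
    and Yule-tree simulator for calibration studies, and post-processing
    into credible model sets, HPD intervals and coverage tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
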