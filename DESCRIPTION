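Package: qsn
Title: Signal and Noise Analysis of Quartet Phylogenies with Unequal Branch Lengths
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact site-pattern probability calculations for four-taxon trees
    under reversible substitution models (JC, K2P, HKY, GTR and generic
    k-state symmetric models), allowing unequal durations and substitution
    rates on the internode and the four subtending branches. Computes the
    probabilities of the synapomorphic and homoplasious parsimony-informative
    patterns, the probability of true (unobscured) synapomorphy, and the
    derived utility statistics y - Max(x1, x2) and Pi - Max(x1, x2) that
    predict consistency of parsimony inference. Includes branch-length-space
    scans that delimit the Felsenstein and Farris zones in p-length
    coordinates, utility-versus-rate curves with optimal and threshold
    substitution rates, model-specification comparisons, a Monte Carlo site
    simulator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
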