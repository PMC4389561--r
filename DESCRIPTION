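Package: geoshift
Title: Range Shifts and State-Dependent Diversification from Occurrence
    Records and Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the geographic history and diversification
    of clades from geo-referenced occurrence records and a dated (ultrametric)
    phylogeny. Cleans occurrence tables, codes species into user-defined
    regions by point-in-polygon tests with tiered presence filters, fits
    continuous-time Markov (Mk) models of region evolution and draws
    stochastic character maps to estimate binned relative range-shift rates
    through time, computes the multiple state speciation and extinction
    (MuSSE) likelihood with state-specific sampling fractions and fits rates
    by maximum likelihood, normalizes and compares rates across regions, and
    tests phylogenetic clustering of tip regions (parsimony score,
    association index, maximum exclusive single-state clade) against
    tip-permutation nulls. Includes a state-dependent birth-death simulator
    with recorded true histories and an occurrence-table generator with
    controlled contamination, so the whole pipeline can be exercised
    end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    sp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
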