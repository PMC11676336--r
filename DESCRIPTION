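Package: minidens
Title: Density Bounds and Optimal Design of k-mer Sampling Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing k-mer sampling schemes with a window
    guarantee (minimizer-type schemes). Implements the necklace-based
    lower bounds on the density of forward and local sampling schemes,
    exact density computation via charged-context enumeration, empirical
    density on sequences, reference implementations of the random,
    lexicographic, mod-minimizer, miniception and double-decycling
    minimizer schemes, and an integer-linear-programming search for
    provably minimum-density schemes over De Bruijn graphs. All bound
    computations use exact big-integer rational arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
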