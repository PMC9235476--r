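Package: mcoverlap
Title: Significance of Genome Annotation Overlaps Under a Markov-Chain Null
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether the number of reference intervals hit by a query
    genome annotation is statistically significant. Computes the exact
    probability mass function of the overlap count under a two-state
    Markov-chain null hypothesis fitted to the query by maximum likelihood,
    using a dynamic program whose time and memory are independent of genome
    length, and estimates p-values under the permutational (gold-standard)
    null with a rejection-free direct sampler based on Beta-Binomial
    inverse-transform sampling of gap partitions. Includes BED-style
    interval input, multi-chromosome combination by convolution, a
    synthetic-annotation generator for simulation studies, and brute-force
    reference implementations for validation on tiny instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
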