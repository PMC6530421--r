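Package: fourpoint
Title: Four-Point Linkage Analysis of Crossover Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the strength and genomic distribution of meiotic
    crossover interference from full-sib family genotype data by four-point
    linkage analysis. Gamete-type frequencies at quadruples of ordered
    markers are estimated by direct counting (testcross-informative markers)
    or an expectation-maximization algorithm over the 81 identifiable
    four-marker genotype classes (intercross-informative markers), and
    converted to pairwise recombination fractions and coincidence
    coefficients C1-C4, including the triple-interval ("high-dimensional")
    coefficient C4. Includes a genome scan over four-marker windows,
    regional comparisons of interference-strength distributions via a
    bounded L1 histogram distance, chromosome-level summaries and
    length-versus-interference fits, and a meiosis simulator that generates
    full-sib families with known interference structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
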