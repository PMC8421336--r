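Package: hhbargain
Title: Intra-Household Bargaining and Social Norms in Agent-Based Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates joint decision-making inside two-member households as a
    Nash bargain over time allocation and private-good transfers, with gendered
    social norms entering each member's utility through a conformity-weighted
    squared-distance penalty. The household bargain uses separate-spheres
    (zero-transfer) threat points and a Nash-product objective under
    participation constraints, solved by iterated best responses on a grid.
    Includes individual-based and unitary-household comparison models sharing
    the same norm mechanism, a deterministic seeded simulation engine, female
    wage-sweep experiment runners, and behaviour-change analytics such as
    transition-threshold detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
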