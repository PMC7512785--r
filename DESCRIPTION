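Package: pidcone
Title: Bivariate Partial Information Decomposition by Exponential Cone
    Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Bertschinger-Rauh-Olbrich-Jost-Ay (BROJA) bivariate
    partial information decomposition of a finite joint distribution of
    (X, Y, Z) into shared, unique and synergistic information.  The
    underlying optimization over the marginal polytope is assembled as an
    exponential cone program and solved by a primal path-following
    interior-point method that returns, alongside the decomposition,
    certified numerical-quality metrics: the primal feasibility violation,
    the dual feasibility violation and the duality-gap violation.  Also
    provides the analogous trivariate synergy and unique-information cone
    programs for a target with three sources, logic-gate and Copy-gate
    benchmark distributions, uniform simplex sampling of random joint
    distributions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
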