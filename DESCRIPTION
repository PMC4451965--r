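Package: dsrloops
Title: Relevant Positive Feedback Loops of Reaction Networks via DSR-Graph Injectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural analysis of biochemical reaction networks to locate
    the positive feedback loops that can underlie multistationarity. Builds
    the stoichiometric matrix and a symbolic influence (sign) matrix from a
    plain-text reaction list, expands the injectivity polynomial with exact
    integer and rational arithmetic, classifies its terms by sign, realizes
    the wrong-sign terms as nuclei (disjoint circuit covers) of the signed
    directed species-reaction (DSR) graph, and reports the positive feedback
    loops contained in wrong-sign nuclei together with an injectivity
    verdict. Ships the classical worked examples (mitotic trigger, Ring1B/Bmi1
    ubiquitination, two-site phosphorylation, a two-layer cascade, caspase
    activation) as fixtures and a seeded random-network generator for
    property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
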