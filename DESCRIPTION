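Package: fiska
Title: Fuzzy Inference System for Kidney Allocation
Version: 0.1.0
Authors@R:
    person("FISKA", "Maintainers", email = "maintainers@fiska.example.org",
           role = c("aut", "cre"))
Description: Ranks kidney-transplant waiting-list candidates against a
    deceased donor with a Mamdani fuzzy inference system (trapezoidal
    membership functions, max-min inference, centre-of-gravity
    defuzzification), alongside the two conventional allocation policies it
    is compared with: a multi-criteria point scoring system driven by
    IF-AHP-derived criterion weights, and an ABO/urgency filtering policy.
    Fuzzy rules are induced from score-labelled cohorts via a deterministic
    classification tree whose root-to-leaf paths are translated into
    linguistic rules. Includes ranking-agreement metrics (overlapping rate,
    two first choices), the raw EPTS post-transplant survival score, a
    seeded synthetic cohort generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
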