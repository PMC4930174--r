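Package: rwcoop
Title: Cooperation and Reputation in Networked Repeated Prisoner's Dilemmas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying conditional cooperation in repeated two-person
    Prisoner's Dilemmas played on a small complete social network, contrasting
    an atomized information regime (actors observe only their own interactions)
    with an embedded regime (actors observe all interactions, enabling
    reputation effects). Provides closed-form expected utilities and threshold
    discount factors for trigger-strategy equilibria, an exactly uniform
    sampler of m-regular interaction graphs, an agent-based simulator with
    trigger, strong-trigger and Bush-Mosteller learning strategies under
    tremble noise, a generator of lab-shaped synthetic experiment datasets,
    and the matching statistical pipeline: group-level cooperation summaries,
    exact Mann-Whitney tests, variance-comparison tests, and noncentral-t
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
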