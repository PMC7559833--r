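Package: panelval
Title: Expert-Panel Content Validation of Questionnaires with Aiken's V
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the content-validation stage of questionnaire
    development with small expert panels rating items on a bounded Likert
    scale. Screens panels for discordant judges with a leave-one-out
    deviance rule, computes Aiken's V content-validity coefficient per item
    with score-method confidence intervals, applies a validity threshold,
    and renders per-item reports. Includes embedded rating fixtures from a
    published validation of two 30-item physical-activity-on-prescription
    questionnaires, a synthetic panel generator with injected discordant
    experts, and an operating-characteristics harness for the screening
    rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
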