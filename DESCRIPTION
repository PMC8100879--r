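Package: checkup
Title: Scripted Conversational Mental-Health Checkup Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based conversational engine for workplace mental-health
    checkups. Delivers six standardized screening instruments (GAD-7, PHQ-9,
    DASS-21 stress subscale, ISI, OLBI, and a demand-control-support job
    stress scale) as a scripted decision-tree conversation with exact scoring
    and severity categorization, conditional branching (insomnia gated on the
    PHQ-9 sleep item), single-step back-navigation, a 24-hour session expiry
    rule, and a safety protocol for high-risk responses. Produces anonymized
    organization-level reports with campaign rates and small-group pooling,
    and ships a graded-threshold ordinal simulator of synthetic respondents
    so the full pipeline can be exercised without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
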