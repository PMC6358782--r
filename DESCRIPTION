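Package: artmetab
Title: Identification of Artemisinin Metabolites from MSE Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying phase-I metabolites of artemisinin (and
    related sesquiterpene lactones) in data-independent acquisition (MSE)
    LC-MS experiments. Candidate metabolites are enumerated from a parent
    drug by composing biotransformation rules (hydroxylation, deoxygenation,
    carbonyl reduction); blank-subtracted low-energy precursor ions are
    matched to candidate adduct m/z within a milli-Dalton tolerance;
    high-energy fragment ions are confirmed by neutral-loss path search; and
    metabolite panels observed in vivo (mouse plasma) and in vitro
    (microbial transformation broth) are compared. Ships a machine-readable
    transcription of the study's metabolite summary table and a seeded
    synthetic MSE data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
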