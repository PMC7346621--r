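Package: medcomplexity
Title: Automated Assessment and Reduction of Drug-Treatment Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based clinical decision support for medication-regimen
    complexity. Parses structured medication schedules (a simplified dialect
    of the German nationally standardized medication plan), screens them
    against a catalogue of 61 complexity factors (38 automatically detectable
    from dosage forms, dosage schemes, schedule structure and free-text
    keywords), personalizes findings through patient-facing key questions and
    distinct questions, and proposes optimisation measures including five
    alternative-drug suggestion algorithms. Ships a curated drug-reference
    fixture, a keyword lexicon, and a synthetic schedule generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
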