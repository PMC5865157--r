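Package: breathvoc
Title: Cross-Platform Mass Spectrometry Annotation of Breath Volatiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation of oxygenated volatile organic compounds (VOCs) in
    exhaled breath by combining evidence across orthogonal mass-spectrometry
    platforms. Predicts class-characteristic diagnostic ions for 70 eV
    electron ionisation (EI), water-reagent positive chemical ionisation
    (PCI) and selected-ion flow tube MS (SIFT-MS, H3O+ and NO+ precursors),
    matches predictions against observed peak tables together with Kovats
    retention indices, and combines the evidence into tiered consensus
    annotations. Includes quantitative platform intercomparison statistics
    (paired response regression, relative standard deviation, detection
    limits, class-composition profiles) and a synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
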