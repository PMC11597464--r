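Package: betalains
Title: Betalain Identification from LC-MS/MS Diagnostic Fragment Ions
Version: 0.1.0
Authors@R:
    person("Pitaya", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying betalain plant pigments (betacyanins and
    betaxanthins) in LC-MS/MS data by diagnostic fragment-ion fingerprints.
    Provides elemental-formula parsing and monoisotopic [M+H]+ mass
    arithmetic, a curated red pitaya betalain catalog with class taxonomy and
    framework ions, derivative (decarboxylation/dehydrogenation) enumeration
    and betaxanthin condensation, core-ion screening and classification of
    MS/MS spectra, precursor annotation by ppm mass accuracy with
    retention-time isomer resolution, multistage-MS neutral-loss
    interpretation, and a seed-controlled synthetic DDA spectrum generator
    for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
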