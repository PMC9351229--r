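Package: dosageqc
Title: Post-Imputation Quality Control for Genotype Dosage Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-marker genotype-imputation accuracy measures
    (IMPUTE2-style info score, MACH r-squared, Beagle allelic r-squared,
    and the anchor-based Iam_chance, Iam_HWE and hiQ indices) from
    Oxford-GEN-style a-posteriori genotype-probability ("dosage") files,
    applies marker and sample filtering, and classifies chromosome
    regions as cold, tepid, hot or very hot according to local enrichment
    of poorly imputed markers.  Includes a synthetic dosage-file
    generator with known ground truth for validation, a plotting helper
    for regional accuracy tracks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
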