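Package: twinliab
Title: Liability-Threshold ACE Models for Binary Phenotypes in Five-Group Twin Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classical twin-design analysis of binary phenotypes on the
    liability scale: normal-threshold models, tetrachoric twin correlations
    with profile-likelihood confidence intervals, five-group (MZM, DZM, MZF,
    DZF, DOS) ACE variance decomposition with qualitative sex limitation and
    birth-cohort moderation fitted by full-information maximum likelihood on
    raw pair data, and a nested likelihood-ratio model ladder. Includes a
    calibrated synthetic twin-cohort generator so the full pipeline can be
    exercised and validated without access to registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
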