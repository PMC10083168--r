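Package: retvol
Title: Nulla-Centered Retinal Volumetry and Reference-Database Statistics for Cynomolgus Monkey OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring regional retinal volumes from optical coherence
    tomography (OCT) label volumes of the cynomolgus monkey macula and for building
    a normative reference database from the resulting per-eye tables. The pipeline
    locates the deepest point of the inner limiting membrane (the nulla), centers a
    3000 micrometer cylindrical measurement grid on it (three concentric zones, four
    quadrants, nine slices), and computes regional volumes by voxel counting.
    Reference-database statistics cover grouped summaries, Pearson correlation
    blocks, principal component analysis of the slice volumes, two-factor MANOVA
    (Wilks' lambda) and per-slice type II ANOVA with Bonferroni-corrected
    significance stars. A parametric phantom generator produces label volumes with
    a known foveal pit and simulated cohorts with known group effects, so every
    stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
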