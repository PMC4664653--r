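Package: gm1ims
Title: Targeted Quantification of GM1 Ganglioside Species Ratios from
    MALDI Imaging Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and targeted analysis of MALDI imaging mass
    spectrometry (IMS) data for GM1 ganglioside species differing in their
    sphingosine long-chain base (d18:1 vs d20:1). Provides molecular-formula
    arithmetic, monoisotopic [M-H]- m/z prediction and isotope-envelope
    computation; a seeded synthetic-data generator that emulates multi-region
    brain phantoms with region-specific species ratios, baseline, gain and
    noise; imzML 1.1 reading and writing; local baseline removal; highest-peak
    area-under-curve quantification and per-ROI d18:1/d20:1 ratios; per-animal
    averaging with a minimum-measurement exclusion rule and per-region
    mean +/- SEM summaries; normality-gated two-group and multi-group
    comparisons (t-test or Mann-Whitney; one-way ANOVA with Tukey HSD or
    Kruskal-Wallis with Dunn post hoc); ion-image rendering; and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
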