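Package: bcnascore
Title: Broad Copy Number Aberration Scoring and Genome-Instability
    Classification of Colorectal Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls broad copy number aberrations (BCNAs) from marker-level
    log2-ratio copy-number tracks via calibration, isosegment detection,
    gap joining and arm-fraction filtering; converts calls into per-sample
    BCNA scores under the p-q-w or p-q scoring system; types samples by
    microsatellite instability (Bethesda panel plus BAT40); classifies
    microsatellite-stable tumors into low-BCNA and high-BCNA groups at the
    first quartile of the score distribution; and runs tumor-group versus
    normal expression contrasts with signed linear fold changes, one-way
    ANOVA, Benjamini-Hochberg correction and specific/shared differentially
    expressed gene cross-classification. Includes a synthetic-cohort
    generator with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
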