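Package: herbqc
Title: Fingerprint, Chemometric and Single-Marker Quality Control for
    Herbal Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control analysis pipeline for medicinal and edible
    herbal materials, worked out for Artemisiae argyi Folium (dried
    mugwort leaf). Implements rule-based annotation of negative- and
    positive-mode MS2 spectra of caffeoylquinic acids and flavonoids
    (neutral-loss chains, retro Diels-Alder ions, glycoside ring
    cleavages, relative-abundance isomer discrimination), HPLC-UV
    fingerprint construction (peak detection, integration, asymmetry and
    resolution metrics, relative-retention-time matching, cosine
    similarity), chemometric marker screening (PCA, OPLS-DA with VIP,
    S-plot and label-permutation validation), and quantitative analysis
    of multi-components by a single marker (QAMS) with external-standard
    cross-validation. A synthetic-data module simulates batch peak
    tables with planted region effects, chromatograms, calibration
    series and MS2 spectra so the whole pipeline is testable without
    instrument data; printed reference tables (relative correction
    factors, relative retention times, batch concentrations) ship as
    packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
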