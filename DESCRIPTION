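Package: aliprint
Title: Quantitative Analysis of Droplet-Bioprinted Airway Epithelial Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterizing droplet-based bioprinting of
    airway (nasal) epithelial cells and the resulting air-liquid-interface
    cultures. Computes dimensionless printability numbers (Ohnesorge, Weber,
    Reynolds, Froude, Bond, splashing parameter) for a bioink/jet
    configuration, estimates ciliary beat frequency from image-stack intensity
    traces by FFT with quadratic peak refinement, quantifies tight-junction
    (ZO-1) spacing from fluorescence line profiles, marker area fractions,
    LIVE/DEAD viability and DAPIxGFP histocytometry gating, and evaluates
    barrier function (blank-subtracted area-normalized TEER and FITC-dextran
    flux). A seeded synthetic-data module generates every input the pipeline
    consumes with ground truth stored alongside, so each stage is verifiable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
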