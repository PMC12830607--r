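Package: epimorph
Title: Observer-Independent Morphometry of Corneal Epithelial Thickness
    Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative, observer-independent assessment of corneal
    epithelial architecture for limbal stem cell deficiency (LSCD) models.
    Computes surface-irregularity metrics on per-eye epithelial thickness
    profiles (z-score standardization per animal, arithmetic mean roughness
    Ra, maximum profile height Rz, rolling standard deviation, skewness and
    sigma-exceedance fractions), extracts thickness profiles from labeled
    histology rasters along basal-contour normals, quantifies cell density
    per tissue compartment, analyses longitudinal optical coherence
    tomography (OCT) pachymetry relative to baseline, and produces paired /
    unpaired group-comparison tables and profile figures. A seeded
    synthetic-data generator emulates the statistical structure of study and
    control eyes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
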