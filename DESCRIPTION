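Package: uavpheno
Title: UAV Multispectral Plot Phenotyping for Wheat Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plot-level analysis of multitemporal multispectral UAV
    orthomosaics from cereal variety trials. Extracts single-band
    reflectances, vegetation indices (DVI, RVI, NDRE, MCARI, CCII) and
    gray-level co-occurrence matrix (GLCM) texture features (contrast,
    correlation, dissimilarity, energy, homogeneity) by zonal statistics
    over plot polygons; aligns flight dates on a growing-degree-day
    thermal-time axis; assembles single-date, spline-smoothed and
    moving-window temporal feature sets; and evaluates random-forest
    yield regression and yield-group classification under repeated
    cross-validation. Includes a synthetic variety-trial simulator
    (weather, canopy reflectance scenes with row texture, yields,
    phenology) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    mgcv,
    jsonlite,
    tiff,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
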