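Package: orchardet
Title: Remote-Sensing Evapotranspiration Phenotyping for Tree Orchards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-tree evapotranspiration and water-status phenotyping from
    airborne multispectral, thermal and photogrammetric rasters of row
    orchards. Covers canopy-height-model structure metrics with
    watershed crown delineation, spectral vegetation indices, Norman-Jarvis
    leaf-area-index inversion, an hourly hedgerow light-interception model,
    radiative-transfer based trait retrieval with trained regressors, the
    two-source energy balance (TSEB) with directly observed canopy and soil
    temperatures, the Shuttleworth-Wallace sparse-canopy potential
    evapotranspiration model, the crop water stress index CWSI = 1 - ETa/ETp,
    an irrigation water balance, and a fully synthetic orchard-campaign
    generator so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
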