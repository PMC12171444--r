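Package: soilNweb
Title: Gaseous Nitrogen Emissions and Soil Bacterial Community Ecology for
    Green-Manure Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for split-plot field trials that combine
    green-manure incorporation with reduced nitrogen fertilization. Computes
    ammonia volatilization fluxes from ventilation-chamber sponge extracts and
    nitrous oxide fluxes from static-chamber concentration time series,
    integrates them into cumulative seasonal emissions, and links them to soil
    bacterial community ecology: alpha and beta diversity, Sloan neutral
    community model fits, beta nearest-taxon index (betaNTI) and Raup-Crick
    (Bray-Curtis) null-model partitioning of assembly processes, Levins niche
    breadth, co-occurrence network topology with Zi-Pi keystone
    classification, and soil-property drivers via factorial effect statistics,
    permutation random-forest importance and partial least squares path
    modeling. A synthetic-data generator with known ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    MASS,
    vegan,
    igraph,
    randomForest,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
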