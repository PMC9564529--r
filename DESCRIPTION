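Package: ecolandopt
Title: Scenario-Based Optimal Allocation of Ecological Land
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples multi-objective linear programming of land-use quantity
    structure with a patch-generating cellular automaton for spatial
    allocation. Six land-use classes are optimized under human-needs
    scenarios (security via ecological footprint, spiritual via green
    equivalent, material via economic benefit, a comprehensive weighted
    scenario, and a linear-development baseline), demands are allocated on a
    raster landscape using random-forest growth probabilities (land expansion
    analysis strategy) and roulette-wheel patch growth with an adaptive
    demand coefficient, and results are audited against constraint sets and
    an ecological red-line mask. Includes GM(1,1) grey forecasting, a
    synthetic landscape generator with known driver effects, and
    change-table/red-line accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    boot,
    randomForest,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'landscape-core.R'
    'io.R'
    'synthetic-data.R'
    'needs-models.R'
    'grey-forecast.R'
    'mop-optimizer.R'
    'leas.R'
    'cars.R'
    'accounting.R'
    'pipeline.R'
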