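Package: nichePosition
Title: Thermal and Aridity Niche Position Indices from Gridded Monthly Climate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species-specific monthly thermal and aridity niche
    limits from range polygons or point occurrences overlaid on gridded
    monthly climate (maximum temperature, precipitation, potential
    evapotranspiration), and rescales environmental observations into
    Thermal and Aridity Position Indices (TPI/API) between those limits.
    Includes binomial verification against a synonym map, limit-table
    queries by species or higher taxon with month selection and
    year-averaging, an aridity index (precipitation over potential
    evapotranspiration) with guards for undefined and extreme values, and
    a deterministic synthetic-world generator (climate cube, taxonomies,
    geometries, observations with known ground truth) for testing and
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
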