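Package: heatcc
Title: Case-Crossover Analysis of Heat Exposure and Traumatic Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-stratified case-crossover studies of ambient heat
    and acute injury. Computes the Humidex apparent-temperature index on a
    gridded daily weather surface, links point locations to grid cells by
    nearest centroid, constructs month-by-weekday referent strata with
    employment-based exclusions, and estimates category-specific odds ratios
    by maximising the exact conditional likelihood (one case per stratum)
    with a purpose-built Newton-Raphson fitter. Includes the secondary and
    sensitivity analyses typical of occupational heat studies and a fully
    synthetic study generator for verifying every pipeline stage and the
    estimator's parameter-recovery properties.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), survival, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
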