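Package: musubada
Title: Multiple-Subject Barycentric Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Barycentric discriminant analysis (BADA) and its multi-table
    extension MUSUBADA for assigning observations to predefined categories
    when variables are grouped into subtables of unequal size (for example
    voxels grouped by participant or region of interest). Computes category
    barycenters, decomposes them with a generalized singular value
    decomposition under row-mass and column-weight metrics, classifies
    observations by nearest barycenter in factor space, and quantifies
    category separation through inertia decomposition, permutation tests,
    cross-validated (jackknife and leave-one-block-out) confusion matrices,
    and bootstrap confidence ellipses. Includes discriminant correspondence
    analysis and Hellinger variants for count data, multiple factor analysis
    and STATIS subtable normalizations, partial (per-subtable) projections
    and inertias, and a synthetic multi-subject block-design data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
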