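Package: greenreach
Title: Supply-Demand Adjusted Two-Step Floating Catchment Area Analysis of
    Park Access Equity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures spatial accessibility to urban parks and the equality
    of that access on a fine demand grid. Implements a Huff-model extension
    of the two-step floating catchment area (2SFCA) method with Gaussian
    travel-time decay, composite park attractiveness built from park area,
    street green-view index and Shannon diversity of surrounding service
    functions, network travel times for walking, cycling and driving,
    an equality-index classification, local Moran's I (LISA) cluster
    detection with permutation inference, and Lorenz-curve/Gini equity
    summaries. Includes a seeded synthetic-city generator so the whole
    pipeline can be exercised without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
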