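Package: envtrack
Title: Environmental Annotation of Animal Movement Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates animal movement trajectories and gridded geographic
    areas with environmental variables from heterogeneous gridded datasets.
    Tracks are transformed to each dataset's native grid, interpolated first
    in space (nearest neighbour, bilinear, or inverse-distance weighting)
    and then in time, and extended with derived flight and terrain
    covariates: wind speed and direction from u/v components, tail-wind
    support and crosswind relative to flight heading, thermal and orographic
    uplift, and slope, aspect and rugosity from digital elevation models.
    Includes an n-dimensional grid model with tile indexing, a scene cache
    with LFU/LRU eviction, coordinate transforms between WGS84 and common
    native projections, a synthetic fixture generator with closed-form
    oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
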