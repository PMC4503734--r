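Package: callscape
Title: Territory Isopleths and Audience-Targeted Vocal Advertisement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spatial analysis of vocal advertisement placement in group-living
    territorial animals. Estimates group territories from GPS fixes with the
    adaptive sphere-of-influence local convex hull (a-LoCoH) method and nested
    density isopleths (50/75/95 percent), tests call placement against
    movement-proportional and area-proportional null models, builds 100 m
    buffer zones around neighbouring territories to quantify audience
    targeting by pedigree relatedness and neighbour-group composition, and
    compares body-mass costs of calling with paired tests. Includes a
    synthetic-data generator with planted, recoverable effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    polyclip,
    sp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
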