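Package: vespalocate
Title: Bait-Station Triangulation of Vespa velutina Nests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates nests of the invasive yellow-legged hornet (Vespa
    velutina) from observations taken at protein bait stations. Converts
    the shortest bait-nest-bait round-trip time of a marked individual
    into a minimum/maximum distance band, builds a bearing sector around
    the individual's mean vanishing direction, intersects the resulting
    sector-annulus regions within and across bait stations into a
    convergent search area, and suggests placement of a second bait
    station. Includes a stochastic foraging-trip simulator for end-to-end
    validation against a known nest, CSV readers for field data, GeoJSON
    export of search polygons, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    polyclip,
    stats,
    truncnorm,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
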