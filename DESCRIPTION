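Package: polycontact
Title: Polygon-Based Contact Networks from Real-Time Location Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds proximity- and polygon-based animal contact networks from
    real-time location system (RTLS) point fixes. Point trajectories are
    cleaned and regularised onto fixed time grids, headings are estimated
    from consecutive relocations, and each fix is transformed into rigid
    oriented polygons (body sections, visual fields) described by a planar
    template model. Spatial contact thresholds are calibrated for RTLS
    positional error by simulating in-contact point pairs, pairwise polygon
    distances yield contact bouts and time-aggregated weighted networks, and
    path-randomisation null models with Mantel and chi-squared comparisons
    support inference. Includes a correlated-random-walk simulator with
    scripted ground-truth contact scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
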