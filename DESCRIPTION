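Package: vaxscape
Title: Spatio-Temporal Forecasting of Childhood Vaccine Hesitancy on ZIP-Code Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for forecasting childhood vaccine hesitancy at the ZIP-code
    level from insurance-claims panels. Builds weighted ZIP-level graphs from
    aggregated person-level contacts, geographic adjacency, or centroid
    distances; fits a two-module spatio-temporal learner (message-passing
    graph layers per quarter feeding a recurrent sequence model) trained with
    separate MAPE plus L2 losses; selects training ZIP codes under a label
    budget with an output-diversity active-learning loop; and characterises
    spatial structure with weighted Moran's I, the isolation index, and a
    Poisson Kulldorff scan statistic on graphs. A seeded synthetic-data
    generator emulates claims records, geographies, contact networks, and
    quarterly panels so the whole pipeline is testable without restricted
    claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
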