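Package: dispenergy
Title: Bioenergetics of Animal Dispersal and Dispersal-Cost-Weighted
    Landscape Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A mechanistic energy-budget model of the transfer phase of
    active animal dispersal. Allometric relationships for energy storage,
    basal metabolic rate, travel speed and locomotion cost predict the
    energetic cost of moving any distance, and the physiological maximum
    dispersal distance, for flying birds, running mammals and swimming
    fishes from body mass alone. On top of the energy budget the package
    builds dispersal-cost-weighted spatial networks over patch landscapes
    (random, clustered, or user-supplied coordinates) and computes
    connectance and weighted connectance, and it compares predicted maxima
    against empirical maximum-dispersal-distance records. Includes a
    command-line interface and a reproduction suite for the published
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    igraph,
    withr,
    xml2
Config/testthat/edition: 3
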