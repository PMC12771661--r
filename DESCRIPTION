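Package: raopart
Title: Rao Quadratic Entropy Diversity Partitioning for Managed Grassland Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Alpha and pairwise beta diversity partitioning of plot-by-species
    cover data with Rao's quadratic entropy, in taxonomic and phylogenetic
    facets, with the Jost equivalent-number correction; multivariate
    group-dispersion (distance-to-centroid) beta responses via principal
    coordinates; Dufrene-Legendre indicator species analysis with a
    permutation null; interaction regression of diversity on an expansive
    species cover gradient crossed with management, and hierarchical
    partitioning of explained variance. Includes a synthetic community
    generator emulating mown versus abandoned semi-natural grassland plots
    under an expansive grass cover gradient, used for end-to-end parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
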