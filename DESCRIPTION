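Package: scalescan
Title: Scale-Dependent Temporal Beta Diversity of Resurveyed Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying compositional change of ecological
    assemblages between repeated surveys across a continuous range of
    spatial grains. Site pairs are matched across periods by fluvial
    distance, temporal change is measured with the Morisita-Horn or
    Jaccard dissimilarity, sites are pooled into spatial clusters via a
    Ward hierarchy on river-network distances cut at every cluster count
    K from the number of pairs down to one, and discontinuities in the
    change-versus-scale relationship are tested with a bootstrap null
    built from the local-scale values. Includes Hill-number
    alpha/beta/gamma diversity partitioning with bootstrap standard
    errors and a seeded generator of dendritic riverscape metacommunities
    for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
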