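Package: commtopo
Title: Topological Relationships Between Social Network Communities and
    Intervention Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models qualitative topological relationships (disjoint,
    containment, equality, partial overlap, touch) between possibly
    overlapping communities in a social network using multisets of
    connected-component sizes of the communities' intersection, union and
    differences.  Interventions on the network are defined as desired
    topological relationships, expressed as sets of necessary and
    sufficient conditions on those multisets, and compiled into verified
    sequences of feasible edit operations (vertex removal, edge addition
    and removal, community reassignment).  Includes planners for community
    separation, fragmentation, infiltration, influence-based containment
    with assimilative-influence diffusion, and ego-network coverage, plus
    generators for planted-relationship and school-friendship test
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
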