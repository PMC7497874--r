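Package: duonet
Title: Egocentric and Duocentric Social Network Analysis for Matched
    Respondent Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds egocentric networks from name-generator survey exports
    (up to five alters with roles, support flags, and pairwise tie reports),
    computes the standard egocentric measure suite (network size, alter-alter
    density, role composition, support prevalence, family friendship,
    disconnected members), merges matched young-adult and parent surveys into
    duocentric networks with exact name matching and maximum-value resolution
    of conflicting tie reports, computes duocentric measures (overlap and
    unique members, parent centrality, 75-percent-rule characteristics, and
    social-capital ADD accounting over parent-unique alters), generates
    seeded synthetic survey cohorts with the same statistical structure for
    testing, and exports sociograms with multidimensional-scaling layouts to
    GraphML, DOT, and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
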