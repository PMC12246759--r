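Package: fragnet
Title: Town-Level Social Network Fragmentation and Health (Mis)information Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the community structure of town-level online
    social networks relates to individual exposure to, and beliefs about, true
    and fake health-related statements. Implements a size-adjusted modularity
    (fragmentation) index F = Q/Qmax with Louvain community detection, stratified
    seed-account selection with breadth-first ego-network sampling and node/edge
    coverage bounds, construction of survey-derived outcome variables (encounter
    shares, recoded Likert attitude sums, agreement shares, attitude polarization
    and a misinformation-error score), ordinary least squares with town-clustered
    CR1 robust standard errors, linear effect contrasts, and a synthetic study
    generator (planted-partition town graphs, account rosters and respondent
    surveys with known effect sizes) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
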