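Package: crmge
Title: Global Epistasis in Community Function from Consumer-Resource Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-culture consumer-resource models of microbial community
    function and the analysis machinery for global epistasis in
    community-function landscapes. Simulates single-species growth on many
    substitutable carbon sources under Liebig co-limitation by nitrogen, and
    multi-species communities competing for a central carbon source with
    byproduct excretion, cross-feeding trophic cascades, niche partitioning,
    and facilitation. Enumerates background communities (or background
    resource sets), runs paired simulations with and without a focal species
    or resource, assembles change-in-function (deltaF) versus background
    function (F) scans, fits them by ordinary least squares and
    density-weighted correlation, and compares measured slopes and intercepts
    against the carbon-share analytic approximation
    deltaF = alpha*C0*beta_j - alpha*F.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
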