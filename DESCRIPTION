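Package: curvgate
Title: Curvature-Guided Highest Density Region Gating for Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic and semi-automatic gating of flow cytometry samples in
    one to three dimensions using the curvHDR approach: regions of
    statistically significant high negative curvature of a binned kernel
    density estimate seed candidate gates, their convex hulls are grown by a
    target volume factor via circle/sphere rolling, and each grown region is
    refined into a level-tau highest density region gate fitted to the events
    it contains. Includes rectangle-gate composition, per-event membership,
    FCS and delimited-text input, JSON gate interchange, a seedable synthetic
    sample generator with ground-truth labels, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    data.table,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
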