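Package: sdmflow
Title: Collaborative Species Distribution Modeling Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for expert-in-the-loop species distribution
    modeling at national scale. Provides auditable occurrence-record curation
    (standardization, automated quality flags, 1-km spatial deduplication,
    append-only edit logs with full revert), a tiered modeling ladder driven
    by occurrence count (point buffers, convex hulls, a climate-envelope
    model, and an L1-regularized presence-background model with spatial-block
    tuning), percentile training-presence thresholding, expert-feedback map
    editing (omission slider, over/under-prediction polygons, habitat masks),
    a score-based model validation registry with IUCN-style range statistics,
    and a synthetic-landscape generator for end-to-end testing with virtual
    species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    glmnet,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
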