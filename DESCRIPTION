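Package: nonself
Title: Comparative Analysis of Fungal Transcriptional Responses to Non-Self
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing a fungus's transcriptional responses to
    heterospecific non-self (bacteria) and conspecific non-self (vegetative
    incompatibility). Implements gene versatility scoring from homolog hit
    counts (orphan / quantile-bin / core-genome classification and a 0..n+1
    index), construction of direction-specific differentially expressed gene
    sets at fold-change and p-value thresholds with time-point pooling,
    Venn and overlap statistics with Fisher and chi-square tests, sign tests
    for regulation-magnitude bias between conditions, sliding-window
    chromosomal landscapes with calling of low-versatility regions and
    up-regulation hotspots, categorical enrichment with fold-change threshold
    sweeps, secondary-metabolite cluster summaries, reciprocal-best-hit
    orthology with cross-species response overlap, and a seeded synthetic-data
    generator that emulates the statistical structure of such a study so every
    stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
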