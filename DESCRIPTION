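Package: CommFBA
Title: Community Metabolic Network Reconstruction and Flux Balance Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven reconstruction of microbial community
    metabolic networks. Merges single-species genome-scale metabolic models
    into mixed-bag or compartmentalized community models, gap-fills draft
    networks at the individual or community level by exact minimal-cost
    (parsimony) search over a candidate reaction database, predicts growth
    and interspecies metabolite exchanges with flux balance analysis (FBA)
    and parsimonious FBA, and scores flux predictions against
    gene-expression-derived reaction activity calls (transcriptomic FBA and
    four-category consistency reports). Ships a deterministic synthetic
    phototroph-heterotroph consortium generator so the full workflow runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Metabolomics, SystemsBiology, Network, GraphAndNetwork, Software
RoxygenNote: 7.3.3
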