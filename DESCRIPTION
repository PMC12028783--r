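Package: alleloscreen
Title: Allelopathy Bioassay Screening, Scoring and Multi-Criteria Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for seed-germination allelopathy screens of donor plant
    root exudates: germination metrics (germination percentage, germination
    potential, simple vigor index), the allelopathy response index RI and its
    composite SE, entropy-weighted TOPSIS ranking of donor species, one-way
    ANOVA with Duncan's multiple range test and compact letter displays,
    permutation variable importance, PCA profiling of physiological stress
    indicators, and a synthetic bioassay generator with planted treatment
    effects for simulation-based validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
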