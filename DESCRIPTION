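Package: replitad
Title: Replication Initiation Zones at Stratified Chromatin Domain Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links DNA replication initiation zones (IZs) to structurally and
    genetically stratified TAD/subTAD boundaries. Detects chromatin domains and
    corner-dot loops from Hi-C contact matrices via multi-scale insulation and a
    local-background Poisson dot caller, stratifies domain boundaries into six
    classes by corner-dot status and CTCF+cohesin motif orientation, calls IZs
    from 16-fraction Repli-seq with early/early-mid/late timing classes, and
    tests IZ-boundary colocalization against size- and compartment-matched
    random intervals with an empirical randomization P value. Ships a synthetic
    genome generator with planted architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
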