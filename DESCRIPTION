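Package: depredate
Title: Quantifying Marine Mammal Depredation on Demersal Longline Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying depredation of demersal longline catches by
    marine mammals from per-set fishery observer records. Provides spatial and
    temporal binning of observer data onto a dual-resolution grid (half-degree
    boxes and 10 km squares grouped into named areas), catch-per-unit-effort
    (CPUE) and observations-per-unit-effort (OPUE) summaries, scenario-stratified
    catch-rate comparisons, per-cell depredation percentages with hot-spot
    detection, nearest-unaffected-line matching, same-day predator track
    chaining under a distance threshold, and a daily energetics budget for
    orcas. A synthetic fishery simulator generates observer-style records with
    known ground truth so that every pipeline stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
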