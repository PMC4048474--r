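Package: telosim
Title: Stochastic Simulation of Telomere Shortening and Replicative
    Senescence
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulator of telomere erosion during cell
    replication.  Tracks the four telomere ends of each chromosome through
    the end-replication problem, supports constant and length-dependent
    loss rates and division probabilities (cases A1, A2, B1, B2), scales
    from independent chromosomes to cells of 46 chromosomes whose shortest
    telomere gates division, and models Werner's syndrome as stochastic
    extra deletions that can abort division.  Provides replicate
    ensembles with passaging, population-doubling accounting, senescence
    summaries, telomere-length histograms, Gompertz growth fitting, and a
    command-line interface writing CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
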