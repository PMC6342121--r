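Package: sstindex
Title: Taxonomy-Free OTU-Based Diatom Water-Quality Index Across
    Clustering Resolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Develops and evaluates a taxonomy-free benthic-diatom water
    quality index computed directly from operational taxonomic unit (OTU)
    relative abundances. A reference pollution gradient is built as the
    first principal component of log-transformed water chemistry; each
    OTU's ecological optimum and tolerance are estimated by weighted
    averaging along that gradient; per-sample index values follow an
    adapted Zelinka-Marvan weighted-average equation. The package sweeps
    the OTU clustering resolution (sequence similarity threshold, SST)
    with repeated stratified train/test randomizations and reports index
    performance (fit to the gradient), discrimination power and
    stability. A synthetic-community generator with known niche ground
    truth (Gaussian responses on a latent gradient, lognormal abundances,
    multinomial read sampling, ultrametric merge tree emulating SST
    coarsening) makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
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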