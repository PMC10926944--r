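Package: methpel
Title: Potential Energy Landscape Analysis of DNA Methylation from
    Read-Level Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models read-level CpG methylation patterns with a
    one-dimensional Ising model, turning whole-genome bisulfite sequencing
    reads into potential energy landscapes. Exact transfer-matrix dynamic
    programming yields methylation-level probability distributions per
    analysis region, summarised as mean methylation level (MML) and
    normalized methylation entropy (NME); samples are compared by the
    Jensen-Shannon distance (JSD) between level distributions, and genes and
    genomic features are ranked by methylation discordance with
    permutation-based significance. Includes a synthetic bisulfite-read
    generator with known ground truth (paired normal/tumor profiles with
    global hypomethylation, elevated entropy, and focal bivalent-promoter
    hypermethylation) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
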