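Package: strrealign
Title: Repeat-Aware Realignment of Short Reads over Short Tandem Repeat Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic-programming realignment of mapped short reads against a
    genome model in which short-tandem-repeat (STR) unit subsequences may be
    traversed cyclically any number of times, with affine gap penalties,
    rotating multi-base deletions inside repeat units, and flat-penalty read
    clipping. Includes a BAM-in/BAM-out realignment pipeline that projects
    repeat-aware alignments back to reference coordinates as standard CIGARs,
    a paired-end STR benchmark read simulator with diploid repeat-number
    variation, a naive spanning-read STR size estimator, and evaluation
    statistics (call rate, RMSE with NA-to-reference substitution, Mendelian
    trio consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
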