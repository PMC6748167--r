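Package: dualmark
Title: Paired Modeling of 5-Methylcytosine and 5-Hydroxymethylcytosine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Co-analysis of paired bisulfite (BS) and oxidative bisulfite
    (oxBS) DNA modification data at base-pair resolution. Estimates
    5-methylcytosine (5-mC) and 5-hydroxymethylcytosine (5-hmC) proportions
    per probe and sample by constrained binomial maximum likelihood, fits
    per-probe beta regressions for each mark separately, and fits a
    mixed-effects beta regression that treats the two marks as repeated
    measures of a single DNA-modification outcome, testing a
    condition-by-modification interaction to detect shifts in the
    5-mC/5-hmC balance. Includes probe filtering, Benjamini-Hochberg
    multiple-testing correction, probe classification, a comparison of the
    paired and separate analyses, and a synthetic-data generator for power
    and error-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
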