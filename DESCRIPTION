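Package: hmoxmeta
Title: Meta-Analysis of the HMOX1 Promoter (GT)n Length Polymorphism and COPD
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control genetic association meta-analysis of the
    heme oxygenase 1 (HMOX1) promoter (GT)n length polymorphism and
    chronic obstructive pulmonary disease (COPD). Builds 2x2 allele and
    genotype contingency tables from per-study short/medium/long (S/M/L)
    allele and L-carrier (type I/type II) genotype counts, computes Woolf
    log odds ratios with continuity correction, pools them by
    inverse-variance fixed-effect and DerSimonian-Laird random-effects
    models with Cochran Q and I-squared heterogeneity statistics, tests
    Hardy-Weinberg equilibrium for bi- and multi-allelic loci, performs
    subgroup and leave-one-out sensitivity analyses, and runs Egger
    regression and Begg rank-correlation publication-bias diagnostics.
    Ships the published study counts as a packaged fixture and a
    simulator that generates case-control studies under a carrier
    odds-ratio model with between-study heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
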