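Package: magicwheat
Title: Design, Simulation and Analysis of Eight-Founder MAGIC Wheat Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiparent advanced generation inter-cross (MAGIC)
    populations built from eight inbred founders through a replicated funnel
    crossing scheme and single seed descent. Enumerates two-way, four-way and
    eight-way funnel crosses and selects balanced replicated designs by
    perfect-matching removal on the four-way pairing graph; simulates meiosis
    under the Haldane map function through the funnel and selfing generations
    to produce recombinant inbred line genotypes with full founder-mosaic
    descent tracking; applies marker and line quality-control filters and
    computes expected-heterozygosity diversity summaries; estimates pairwise
    linkage disequilibrium (D', r-squared) and lowess-smoothed decay curves;
    provides closed-form segregation expectations for a monogenic recessive
    trait under selfing with chi-square goodness of fit; and runs a
    pedigree-aware single-marker association scan with Bonferroni thresholds,
    peak support intervals, covariate rescans and diagnostic-marker
    concordance tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
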