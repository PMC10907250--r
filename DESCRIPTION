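Package: tempocov
Title: Decomposing Temporal Allele-Frequency Change into Gene Flow, Linked
    Selection, and Drift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the temporal variance-covariance matrix of genome-wide
    allele-frequency change from time-series allele-frequency panels (such as
    ancient-DNA time transects), corrects it for pseudohaploid sampling noise,
    admixture from known source populations, proxy-sample noise, and the
    drift-admixture interaction, and decomposes the total variance in
    allele-frequency change into contributions of gene flow (A), linked
    selection (G), and residual drift.  Uncertainty is quantified by a block
    bootstrap over genomic windows with pivot confidence intervals, and
    statistics can be recomputed in annotation quantile bins (recombination
    rate, B-value).  A forward Wright-Fisher simulator with pulse admixture,
    pseudohaploid sampling, and selection overlays generates validation data
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
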