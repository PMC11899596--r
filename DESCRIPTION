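Package: cerebcpm
Title: Connectome-Based Predictive Modeling of Cerebellocerebral Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) for parcellated
    functional connectivity restricted to connections of interest, such as
    cerebellocerebral and cerebellocerebellar edges. Provides tangent-space
    connectivity estimation with Ledoit-Wolf shrinkage covariance and the
    affine-invariant geometric mean, family-aware k-fold cross-validated CPM
    with positive and negative predictive networks, permutation-based
    significance testing, weighted-degree network characterization, overlap
    analysis between predictive networks, and a synthetic connectome
    generator with planted predictive edges for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
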