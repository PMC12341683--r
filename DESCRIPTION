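Package: survkan
Title: Kolmogorov-Arnold Networks for Interpretable Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proportional-hazards survival regression with Kolmogorov-Arnold
    networks (KANs): networks whose edges carry learnable B-spline activation
    functions that are summed at the nodes. The single network output is the
    log-partial hazard, trained against a fast sorted-prefix approximation of
    the negative Cox partial log-likelihood with sparsity (L1 + entropy)
    regularization. After training, low-magnitude activations are pruned
    (automatic feature selection) and the surviving activations are distilled
    progressively into closed-form symbolic expressions (linear fit,
    affine-wrapped operator library, genetic-programming fallback), yielding
    an explicit formula for the log-partial hazard. Includes a
    proportional-hazards survival simulator driven by symbolic log-hazard
    formulae, Harrell's concordance index with bootstrap confidence intervals,
    a linear (optionally Lasso-penalized) Cox baseline, and tabular
    survival-data preprocessing utilities (label encoding, univariate Cox
    screening, correlated-feature consolidation, simple imputation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
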