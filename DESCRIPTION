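Package: mtperm
Title: Curation, Leakage-Aware Splitting and Masked Multitask Modeling of
    Permeability and Efflux Assay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling sparse multiendpoint permeability and efflux
    data sets (Caco-2 and MDCK apparent permeability and efflux ratios) and for
    validating multitask molecular-property regressors without train/test
    leakage. Implements structure standardization, qualifier-aware value
    parsing, replicate aggregation, a heteroscedastic sigma-versus-mean outlier
    filter, Bemis-Murcko scaffold computation, five splitting strategies
    (stratified-random repeated holdout, scaffold-balanced, leaky and
    all-for-one temporal rounds, modality-grouped and plain k-fold
    cross-validation), quantitative leakage reports, a masked-loss multitask
    neural regressor with optional physicochemical descriptor augmentation, a
    random-forest single-task baseline, and a synthetic assay-data generator
    reproducing the statistical structure of industrial permeability data
    (endpoint sparsity, heteroscedastic replicate noise, late-starting assays,
    censored values, mixed modalities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
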