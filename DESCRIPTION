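Package: seizmod
Title: Subject-Specific EEG Band-Power Fluctuations and Seizure Evolution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes continuous multichannel intracranial EEG band power into
    subject-specific fluctuations on timescales of minutes to days and relates
    those fluctuations to changes in seizure evolutions. The pipeline computes
    Welch band power in 30-second epochs, reduces it with nonnegative matrix
    factorization (NNSVD-LRC initialization, multiplicative updates, rank
    selection by reconstruction error and component redundancy), extracts
    mode-aligned intrinsic mode functions with multivariate empirical mode
    decomposition, characterizes them with Hilbert-Huang marginal spectra
    (peak fluctuation frequency, circadian mode detection), attributes mode
    power to frequency bands and channels (Gini heterogeneity), builds per-mode
    seizure distance matrices, and explains dynamic-time-warping seizure
    dissimilarity with a nonnegativity-constrained LASSO, OLS refit and two
    permutation significance tests. A synthetic-data module generates
    recordings with planted circadian/ultradian/multidien modulators so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'bandpower.R'
    'contrib.R'
    'hht.R'
    'io.R'
    'memd.R'
    'nmf.R'
    'pipeline.R'
    'regress.R'
    'seizdist.R'
    'seizmod-package.R'
    'synthdata.R'
    'utils.R'
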