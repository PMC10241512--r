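Package: cortexstate
Title: Baseline Cortical State, Trial-History Whitening, and Choice Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating pre-stimulus cortical population state to
    behavior in trial-based two-alternative forced-choice experiments.
    Computes per-trial baseline firing rate, a shuffle-normalized population
    synchrony statistic, the coefficient of variation, and rate-normalized
    multitaper spectra from trial-aligned spike times; cross-whitens baseline
    signals (firing rate, synchrony, facial movement, pupil size) by
    per-session trial-history regression into temporally white "innovations";
    fits binomial and Gaussian mixed models with per-session random intercepts
    and slopes, with hierarchical (within-session) bootstrap confidence
    intervals, a robust outlier rule on resampled coefficients, and quantile
    p-values; fits weighted psychometric functions and tests slope differences
    between baseline-state conditions with within-session permutation tests;
    and decodes stimulus and choice from evoked population activity with
    cross-validated L2-regularized logistic regression. A synthetic
    multi-session dataset generator with known ground truth (gated, epoch,
    common-cause, and null couplings between state and accuracy) supports
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
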