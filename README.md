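# cortexstate

Tools for asking how the state of cortical population activity *before* a
stimulus relates to what a subject then does with it, in trial-based
two-alternative forced-choice (2AFC) experiments. The package was built for
head-fixed mice discriminating tone frequency against a 14 kHz boundary while
auditory-cortex multi-unit activity (MUA), facial movement (optic flow) and
pupil size are recorded, but every stage operates on plain tabular inputs.

The scientific core:

* **Shuffle-normalized synchrony.** For each 2-s pre-stimulus baseline,
  `Synch = SD_bins(pooled count) / mean_surrogates(SD_bins)` with 20-ms bins
  and 100 surrogates that keep the spike count but place spike times uniformly
  at random. Uncorrelated Poisson-like firing gives `Synch = 1` at any firing
  rate, so synchrony and rate can be studied as separate axes of cortical
  state (unlike the classical CV of the population count, which is rate-
  entangled). Rate-normalized multitaper spectra (DPSS tapers, `2TW-1` tapers,
  unit mean above a 10 kHz cutoff) show which frequencies drive it.
* **Innovations (cross-whitening).** Per session, each baseline signal
  (OpticF, PupilS, FR, Synch) is regressed on the previous 10 trials'
  outcomes and signal values plus the trial number (51 parameters + offset),
  and the residual — the signal's temporally white, trial-by-trial
  "innovation" — replaces the raw signal in behavioral models, removing the
  spurious associations that slow within-session drifts otherwise create.
* **Outcome-conditioned mixed models with a hierarchical bootstrap.**
  Binomial/Gaussian mixed models with per-session random intercepts and
  slopes (diagonal covariance, Laplace-class estimation), predictors z-scored
  within session, fitted unconditionally and conditioned on the previous (or
  next) trial's outcome; uncertainty from resampling trials with replacement
  within each session, a 7xMAD outlier rule on resampled coefficients, and
  quantile p-values (twice the opposite-sign fraction).
* **Psychometric state splits** (4-parameter logistic, weighted ML) with
  within-session permutation tests for slope differences between favorable
  and unfavorable baseline states, and **evoked-activity decoding**
  (cross-validated L2 logistic regression, stimulus axes conditioned on
  choice and vice versa) with projection x state interaction models.
* **A synthetic-data generator** that emits multi-session datasets with known
  ground truth under four causal scenarios — outcome-**gated** state-accuracy
  coupling, a hidden **epoch** process, a **common cause**, or **null** — so
  the whole chain (metrics -> innovations -> models -> tests) is validated by
  parameter recovery and scenario discrimination, without any data download.

## Worked example

Generate a gated-scenario dataset at the default study conditions (20 sessions
x 400 trials; state -> accuracy coupling of +0.3 logit/SD on the firing-rate
innovation and -0.3 on the synchrony innovation, active only after errors),
whiten the signals, and fit the accuracy models:

```r
library(cortexstate)

cfg <- synth_config(seed = 1)            # scenario = "gated" by default
ds  <- generate_dataset(cfg)
sig <- compute_innovations(ds$signals, ds$trials)
tab <- build_analysis_table(ds$trials, sig)

fits <- run_accuracy_models(tab, n_resamples = 500, seed = 11)
print(fits$after_error)
```

```
Hierarchical bootstrap (500 retained of 500 resamples; 0 outliers, 0 non-converged)
        term estimate  median     q25     q75   ci_lo   ci_hi p_value
 (Intercept)   1.2282  1.2423  1.1923  1.2976  1.1019  1.3899  <0.004
        stim   0.3541  0.3634  0.3133  0.4160  0.2148  0.5337  <0.004
         trn   0.0269  0.0291 -0.0147  0.0839 -0.1205  0.1798   0.664
   opticf_iz  -0.0495 -0.0450 -0.1097  0.0151 -0.2160  0.1267   0.604
   pupils_iz   0.0344  0.0391 -0.0281  0.0998 -0.1496  0.2027   0.688
       fr_iz   0.4237  0.4330  0.3682  0.4893  0.2545  0.6100  <0.004
    synch_iz  -0.2302 -0.2381 -0.2965 -0.1825 -0.3983 -0.0829   0.008
```

After errors, accuracy rises with evidence strength (`stim`) and — the
phenomenon of interest — is higher when the baseline is elevated (`fr_iz`
+0.42, quantile p < 0.004) and desynchronized (`synch_iz` -0.23, p = 0.008),
recovering the injected coupling (movement and pupil, which carry no injected
accuracy effect, stay at zero). The same model on after-correct trials
(`fits$after_correct`) finds no state effect, and the unconditional model's
state coefficients are attenuated toward zero (here +0.13 / -0.09) — ignoring
previous outcome occludes the coupling.

Scenario discrimination (is the coupling gated by errors, or does a slow
"epoch" drive both errors and coupling?) repeats the analysis conditioned on
the **next** trial's outcome: on gated data it finds nothing, on epoch data it
finds the coupling. See `run_accuracy_models(..., conditions = "next_error")`
and the methods vignette (`vignettes/cortexstate-methods.Rmd`).

A command-line front end over the same functions lives at
`inst/cli/pipeline.R` (subcommands `simulate | metrics | innovations | fit |
psych | decode | report`), e.g.

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pipeline.R", package="cortexstate"))') \
  simulate --out data/gated --seed 3
```

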