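---
title: "Baseline cortical state and choice behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline cortical state and choice behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cortexstate` analyzes how the state of cortical population activity in the
seconds before a stimulus relates to what the animal then does with that
stimulus. It is built around trial-based 2AFC experiments in head-fixed mice
discriminating tone frequency against a 14 kHz category boundary, with
simultaneously recorded multi-unit activity, facial movement (optic flow) and
pupil size, but every stage operates on generic tabular inputs. This vignette
explains the statistical machinery, the choices it embodies, and what the
synthetic-data tests do and do not establish.

## Quantifying baseline state from spikes

Each trial contributes a 2-s pre-stimulus baseline `[-2, 0)` s of pooled
multi-unit activity (MUA; unit identity is never used). Two statistics
summarize it:

* **Firing rate (FR)** — total spike count divided by (number of units x
  window length), in spikes/s per unit (`compute_fr()`).
* **Synchrony (Synch)** — the SD across 20-ms bins of the pooled population
  count, divided by the mean of the same statistic over 100 surrogates in
  which the same number of spikes is placed independently and uniformly at
  random in the window (`compute_synch()`). Because the surrogates preserve
  the count exactly, the ratio is 1 in expectation for statistically
  uncorrelated Poisson-like firing regardless of rate, and grows when the
  population co-fluctuates at timescales slower than the bin. This
  normalization is what makes Synch approximately independent of FR, unlike
  the coefficient of variation (`compute_cv()`), which scales as
  `1/sqrt(rate)` and is therefore negatively entangled with FR.

Conventions the statistic needs but that are easy to get wrong: bins tile the
window from the left edge and are half-open (a spike on a boundary belongs to
the right bin); uniform surrogate placement is realized by drawing bin indices
directly, which is exactly equivalent because within-bin positions never enter
the statistic; a baseline with zero spikes yields a *missing* Synch and CV,
never zero — missing state values propagate and simply drop that trial from
state regressors. Surrogate streams are seeded per trial from
(master seed, session, trial) so results do not depend on evaluation order.

The frequency content behind Synch is made explicit by
`multitaper_spectrum()`: a point-process multitaper estimate on the 30 kHz
recording grid using `2*TW - 1` discrete prolate spheroidal tapers (TW = 10
for single baselines, TW = 5 when averaging across trials), normalized by its
own mean power above 10 kHz. The high-frequency limit of a point-process
spectrum is the firing rate, so the normalized spectrum of Poisson firing is
flat at 1 and coordinated low-frequency fluctuation appears as excess
normalized power below ~16 Hz. The DPSS tapers are computed from the standard
symmetric tridiagonal eigenproblem on a 1024-point grid and spline-interpolated
to the target length (re-normalized to unit energy); at these time-bandwidth
products the interpolation error is far below the taper-to-taper variance of
the estimate.

## Innovations: whitening against slow drift

All four baseline signals (OpticF, PupilS, FR, Synch) drift within a session
and fluctuate slowly over many trials. Slowly varying signals have few
effectively independent samples per session, so any two of them correlate by
chance, and regressions of behavior on raw baseline signals inherit that bias.
The package's answer is the *innovation*: per session, each signal is
regressed (OLS) on the previous 10 trials' outcomes (1 = reward, 0 = no
reward), the previous 10 values of all four signals, and the trial number —
51 parameters plus intercept — and the residual is kept
(`compute_innovations()`). Innovations are the temporally white,
trial-by-trial component of each signal. `whiteness_report()` verifies this:
innovation auto- and cross-correlations at lags 1-10 sit inside the
`2/sqrt(n)` band, while raw-signal correlations do not.

Two properties deserve emphasis. First, whitening is *temporal*: if the slow
drivers of two signals are themselves contemporaneously correlated, a residual
instantaneous (lag-0) correlation between their innovations survives, strongly
attenuated. This is expected, and the instantaneous innovation correlations
are themselves analysis targets (e.g., movement vs. firing-rate innovations).
Second, because previous outcomes are regressors, default innovations are
*exactly orthogonal* to the previous trial's outcome — so any analysis that
asks whether the baseline carries information about the previous outcome must
use innovations computed with `include_outcome = FALSE`.

Choices the source data do not dictate, documented here as ours: the first 10
trials of each session (no full history) are masked out of all downstream
fits rather than zero-padded; premature and skip trials count as 0 (no reward)
in the outcome history and contribute rows and lags like any other trial;
sessions whose usable rows would not exceed the 51-parameter design are left
missing with a warning rather than overfit.

## Mixed models and the hierarchical bootstrap

Every behavioral question is posed as a generalized linear mixed model with
recording session as the grouping factor and a per-session random intercept
*and* random slope for every fixed effect (`fit_glmm()`). Binary outcomes
(correct/error, skip/valid, premature/valid, previous outcome) use a
binomial-logit model; reaction time uses a Gaussian one. All predictors are
z-scored separately within each session (idempotently), so session-by-session
differences in the marginal statistics of the predictors cannot masquerade as
trial-by-trial associations.

Estimation maximizes a Laplace-class approximate marginal likelihood: for a
candidate vector of random-effect SDs (the covariance is diagonal — with ~20
sessions there is little information to estimate random-effect correlations,
and the diagonal structure is markedly more stable), the fixed effects and
random-effect modes are obtained by penalized IRLS, and the profiled deviance
(penalized deviance plus the log-determinant of the per-session conditional
precision) is minimized over the SDs by Nelder-Mead. The inner solver
exploits the per-session block structure (a small Schur complement per
session), which makes a full fit on ~8,000 trials take well under a second
and, crucially, makes bootstrap refits cheap. Degenerate inputs take explicit
paths: single-session data fall back to an ordinary GLM (flagged), constant
model-matrix columns are dropped and reported with coefficient zero, and
non-convergence is flagged on the returned object, never silent.

Uncertainty comes from a hierarchical bootstrap (`hierarchical_bootstrap()`):
trials are resampled with replacement within each session, preserving each
session's trial count and the session set itself; each resample is refit, and
coefficient distributions are summarized by median, interquartile range and
95% CI. A resample is discarded as an outlier when any coefficient sits more
than 7 literal MADs (no scale constant) from the coefficient's median across
resamples; for well-behaved fits this removes well under one percent.
Two-sided p-values use the quantile rule: twice the fraction of resamples
whose sign opposes the point estimate, with exact zeros counted as opposite
(conservative) and an all-same-sign distribution reported as a bound
`< 2/n_draws`. Resampling-with-replacement within a session is equivalent to
multinomial case weights on the session's rows, so refits reuse the original
design with new weights and warm starts. By default the random-effect SDs are
held at their full-data estimates while fixed effects and modes are re-solved
per resample; fixed-effect bootstrap quantiles are insensitive to
re-estimating the variance components, and `theta = "refit"` is available
when the variance components themselves are of interest. Note the inferential
target: this bootstrap quantifies within-session resampling noise with the
session set fixed (the sessions are the population analyzed), not sampling of
new sessions.

## The behavioral models

`build_analysis_table()` applies the exclusions (first 10 trials per session;
free-reward/intervention trials and their successors; sessions with fewer
than 100 trials or signal-detection d' below 1, with a 1/(2N) boundary
correction) and derives the conditioning columns. Trial classes follow the
response-timing rules: first lick before the 0.65-s go signal = premature;
first lick in the 0.7-1.7 s response window = valid; no lick within 2 s =
skip; anything else is excluded.

* **Accuracy models** (`run_accuracy_models()`): `correct ~ stim + trn +
  OpticF_I + PupilS_I + FR_I + Synch_I` on valid trials, unconditional (with
  the previous-outcome indicator added as fixed and random term) and
  conditioned on the previous valid trial's outcome. The central phenomenon
  the package is built to detect: after errors, accuracy increases with
  elevated (FR_I > 0) and desynchronized (Synch_I < 0) baselines; after
  corrects, no such coupling. Conditioning on the *next* trial's outcome is
  the control that separates outcome-gated coupling from the "epoch"
  alternative (a slow hidden state that raises error rates and switches the
  coupling on): an epoch is approximately symmetric in time around an error,
  gating is not. Variants: raw signals instead of innovations, quadratic
  state terms, alternative baseline windows, and a single joint predictor —
  the projection of the z-scored (FR_I, Synch_I) pair on the -45 degree axis
  after errors (`(FR - Synch)/sqrt(2)`) or the +45 degree axis after corrects.
* **Outcome decoding** (`run_outcome_decoding()`): `pCorr ~ trn +
  innovations` with outcome-free innovations — does the baseline remember the
  previous outcome? Reward licking dilates the next baseline's pupil, so
  PupilS_I is the expected carrier; the cross-correlation between the outcome
  and pupil series (`slow_component_xcorr()`: 5-trial moving average, linear
  detrend, z-score, lags -20..20, median/MAD across sessions) shows the same
  relationship as an asymmetry at positive lags. The signed discriminability
  index `dprime_state_by_outcome()` uses the pooled-SD convention
  `(mean_c - mean_e)/sqrt((var_c + var_e)/2)`.
* **Responsivity models** (`run_responsivity_models()`): premature-vs-valid
  and skip-vs-valid binomial models and a Gaussian RT model (valid trials
  only), all with `trn` and previous-class indicators (previous valid error is
  the reference class).

## Psychometrics

`fit_psychometric()` fits a four-parameter logistic — location, slope of the
core logistic, lapse and guess rates box-constrained to [0, 0.2] — by
unpenalized weighted maximum likelihood; aggregate fits weight each trial by
its session's share of the dataset. `favorable_split()` labels trials by the
state quadrant (after errors: favorable = FR_I(z) > 0 and Synch_I(z) < 0,
unfavorable the mirror image; after corrects both positive / both negative),
and `slope_permutation_test()` tests whether the favorable-state psychometric
slope exceeds the unfavorable one by shuffling the labels within each session
(preserving per-session label counts, asserted on every surrogate) and
reporting the one-sided fraction of surrogates at or above the observed slope
difference. The test direction (favorable > unfavorable) is fixed a priori.

## Evoked-activity decoding

To ask whether baseline state shapes the *sensory representation* rather than
downstream choice processes, `evoked_counts()` collects spike counts in the
0-150 ms evoked window and `fit_axes()` builds per-session decoding axes by
L2-regularized logistic regression with cross-validation — stimulus axes fit
separately within each choice (and choice axes within each stimulus category),
so that above-chance task performance cannot leak one variable into the
other's decoder. The source description of the procedure mixes "five folds"
with 90%/10% splits repeated 10 times; we implement k-fold cross-validation
(each fold held out once, penalty chosen by inner cross-validation on the
training 90%) with the fold count configurable and defaulting to 10. Fold
assignment is re-randomized (1000 repetitions by default; tests use 100) and
each trial's projection is the median of its held-out decision values.
Conditioning levels with only one class are flagged as degenerate, never
silently fit. `interaction_glmm()` then predicts the decoded label from the
projection, FR_I, Synch_I, and the projection x state interactions (products
of the per-session z-scored main effects), separately after corrects and
errors; a positive projection x FR_I interaction after errors means the evoked
representation is more discriminable on elevated baselines.

One subtlety the synthetic experiments exposed: when behavioral gating is
present, choice-conditioned stimulus labels are correctness indicators within
each conditioning level, so the behavioral state-accuracy coupling itself
induces apparent projection x state interactions. The injected-mechanism
recovery test therefore switches behavioral gating off while injecting the
evoked-gain mechanism, isolating the pathway under test.

## The synthetic-data generator

`generate_dataset()` draws multi-session datasets with known ground truth.
Per session, each of the four signals is the exact sum of a linear session
trend (amplitude ~ N(0, 0.4) latent SD across sessions), a slow AR(1)
component (coefficient 0.9, stationary SD 1, cross-signal correlation 0.6),
and fast i.i.d. innovations (SD 1, correlations: OpticF-FR 0.3,
PupilS-Synch 0.2, OpticF-PupilS 0.3); rewarded trials add a pupil kick
(0.8 latent SD) to the next baseline. Emitted units place FR at 5 +/- 0.8
spikes/s and Synch at 1.30 +/- 0.12, matching the scales the metrics produce
on cortical MUA; pupil is in percent above the session minimum. The magnitudes
of the slow and fast components are free parameters of the generator (the
source experiments do not quantify them); the defaults make the slow
component as large as the fast one — R-squared of the innovation regressions
then lands near 0.4, within the range seen in real sessions — and are fixed
once here, not tuned per analysis.

Trial classes are drawn sequentially from logistic models with the
trial-number ramp, previous-class indicators and fast state components as
inputs (skips rise through the session, cluster in bouts, and follow facial
movement; prematures decay through the session and follow constricted pupil),
and valid-trial accuracy follows a logistic model in evidence strength
(six frequencies at signed evidence -2.2..2.2 in octave-like units around the
14 kHz boundary), the session ramp, and — depending on the causal scenario —
the fast state components. Intercepts are calibrated deterministically
(quadrature plus a short simulation refinement on an isolated RNG stream) so
the realized mix hits 70% valid / 7% premature / 23% skip and 77% accuracy.

The four scenarios encode the competing causal accounts the analyses must
separate: `gated` (state-accuracy coupling of +0.3 logit/SD on FR and -0.3 on
Synch active only after a valid error), `epoch` (a hidden two-state Markov
chain with ~15-trial dwell that simultaneously raises error probability by
2 logits and switches the same coupling on), `common_cause` (a shared
per-trial driver moving state and outcome together), and `null`. The epoch
error boost is set so that, at matched coupling strength, conditioning on the
next outcome has usable power to flag the epoch scenario — with a weak
error-rate contrast the epoch and gated scenarios are formally distinct but
statistically indistinguishable at these problem sizes.

When spikes are emitted, each trial's baseline is a doubly stochastic Poisson
process on a 20-ms grid: all units share a multiplicative AR(1) rate
modulation (correlation time 0.15 s, hence band-limited below ~16 Hz) whose
depth is solved from the trial's emitted Synch value (`m =
sqrt((S^2 - 1)/lambda_bin)`) and whose mean is the emitted FR, so the measured
metrics track the latent drives by construction and E[Synch] is monotone in
the modulation depth. Evoked-window spikes are Poisson with per-unit
log-rate stimulus tuning, optionally scaled after errors by the fast FR
component — the injected mechanism for the interaction analysis.

What passing on synthetic data does *not* show: the generator's slow
components are AR(1), not the nonstationary mixtures of real physiology; its
innovations are exactly Gaussian and its accuracy model exactly logistic, so
model misspecification, sorting artifacts, pupil-tracking noise and
unit-count drift are all untested here. The synthetic results validate the
*machinery* (estimators unbiased, p-values calibrated, conditioning logic
able to separate the scenarios at realistic effect sizes), not any claim
about a particular dataset.

## Numerical choices and problem sizes

Replicated analyses in the test suite run at 300-500 bootstrap resamples and
problem sizes of 4-20 sessions x 120-400 trials, with 20 seeded replicates
where detection rates are asserted; full-scale single analyses use the same
code paths with `n_resamples = 5000` as in typical published use. PIRLS stops
at a relative penalized-deviance change of 1e-9 (cap 200 iterations) with
step-halving; the outer Nelder-Mead uses |theta| so the zero-variance boundary
is interior; linear predictors are clamped at +/-30 on the logit scale.
Psychometric fits run L-BFGS-B from a plain logistic-regression start with the
slope capped at 200 per unit stimulus range (the step-function limit). Ties
in quantile p-values (exact zero draws) count against significance. All
stochastic stages take explicit seeds, and per-trial/per-session streams are
derived from the master seed by a mixed congruential map, keeping every seed
below 2^31.

## Known limitations

The random-effect covariance is diagonal by design; correlated random effects
require a different backend. The bootstrap treats sessions as fixed; it does
not propagate between-animal variation (a mice-within-session nesting is out
of scope). The evoked decoder is linear; time-resolved or nonlinear decoding
is not attempted. The RT model is fit on valid trials only — premature RTs
are governed by a different process and are analyzed only as a class
probability.
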