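---
title: "Modelling bifurcation dynamics in single-trial neural responses"
author: "bifdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bifurcation dynamics in single-trial neural responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifdyn)
```

## The scientific question

When a faint stimulus is presented near the perceptual threshold, the same
physical input is sometimes consciously perceived and sometimes not. Two
families of accounts make different predictions about what single-trial
neural activity should look like as stimulus strength varies:

* **unimodal dynamics** — the evoked response grows (linearly or
  sigmoidally) with stimulus strength, and trials scatter unimodally
  around that mean;
* **bifurcation dynamics** — each trial lands in one of two discrete
  modes, a *high* (perceived) state or a *low* (baseline) state, and
  stimulus strength only changes the probability of ending up high.

Averaged responses cannot distinguish these accounts: both predict a
smooth non-linear mean. The across-trial *variability* can. A two-mode
mixture produces a characteristic peak of across-trial SD at intermediate
stimulus strength (where the two modes are about equally likely) and
bimodal single-trial distributions near threshold, whereas unimodal
dynamics produce flat or monotone variability profiles. `bifdyn`
implements this model-based analysis end to end for a near-threshold
auditory detection design: stimuli at SNRs of −13 to −5 dB in 2-dB steps
against continuous masking noise, plus noise-only trials, 160 trials per
condition, 20 participants.

## The four generative models

The unit of analysis is a scalar activity $x$ per trial — either a
ROI-averaged evoked potential or the signed distance to a linear decision
boundary ("projected activity") — averaged within a 30-ms window. Writing
$s$ for the SNR in dB:

**Null (0)** $x \sim \mathcal N(\mu, \sigma^2)$ regardless of the
stimulus.

**Unimodal linear (1)**
$x \sim \mathcal N(\mu(s), \sigma(s)^2)$ with
$\mu(s) = \mathrm{slope}\,(s - s_{\max}) + \mu_{\max}$, floored at
$\mu_{\mathrm{noise}}$ (a stimulus cannot push the mean below its
no-stimulus level), and $\sigma(s) = \mathrm{slope}_\sigma\,\mu(s) +
\mathrm{intercept}_\sigma$. The anchoring at $(s_{\max}, \mu_{\max})$
rather than a conventional intercept makes the fitted $\mu_{\max}$
directly comparable to the measured activity at the strongest stimulus.

**Unimodal non-linear (2)**
the same Gaussian family with a logistic mean
$\mu(s) = L\,\Lambda(k(s - s_{\mathrm{thr}})) -
L\,\Lambda(k(s_{\max} - s_{\mathrm{thr}})) + \mu_{\max}$,
where $\Lambda$ is the standard logistic; the subtraction anchors
$\mu(s_{\max}) = \mu_{\max}$. Noise-only trials take the $s \to -\infty$
asymptote of this curve (the model has no separate noise parameter).

**Bifurcation (3)** a two-component Gaussian mixture with shared
$\sigma$:
$$p(x \mid s) = \beta(s)\,\mathcal N(x;\, \mu_{\mathrm{hi}}(s), \sigma^2)
 + (1 - \beta(s))\,\mathcal N(x;\, \mu_{\mathrm{noise}}, \sigma^2),$$
$\beta(s) = \Lambda(k(s - s_{\mathrm{thr}}))$ the probability of the high
state, and $\mu_{\mathrm{hi}}(s) = L_{\mathrm{hi}}\,
\Lambda(k_{\mathrm{hi}}(s - s_{\mathrm{thr}})) + \mathrm{step}$ the
high-state mean. Noise-only trials have $\beta = 0$. Its across-trial
variance, $\sigma^2 + \beta(1-\beta)\,(\mu_{\mathrm{hi}} -
\mu_{\mathrm{noise}})^2$, peaks where $\beta \approx 1/2$ — the
variability signature.

Model 1 is a limiting case of Model 2 and participates only in
simulation and illustration; the comparison set is {0, 2, 3}.

Note a structural subtlety: Models 2 and 3 are *not* nested, because
Model 3 shares $s_{\mathrm{thr}}$ between the mixture weight and the
high-state mean — letting $\beta \to 1$ everywhere forces the high-state
mean flat. The mixture therefore does not automatically dominate the
unimodal model even in training likelihood, and cross-validation decides
the comparison on predictive grounds.

## Fitting and model comparison

Each model is fit per participant and per 30-ms window by maximum
likelihood with Nelder–Mead search (`fit_trial_model()`). Numerical
choices:

* parameter vectors with any non-positive SD or steepness score
  $-\infty$, which confines the unconstrained simplex to the feasible
  region without constrained optimization;
* relative function tolerance $10^{-10}$, at most $200 d$ iterations for
  $d$ parameters, and one restart from the incumbent (restarts can only
  improve the returned likelihood). The window sweep
  (`fit_window_sweep()`) relaxes this to $10^{-8}$ with no restart; we
  verified the per-window model ranking is unchanged while the sweep runs
  about twice as fast;
* initialization follows condition summary statistics (means and n−1
  SDs of the extreme-SNR and noise-only conditions; the threshold starts
  at the SNR midpoint). Because the SD rule expresses $\sigma$ as a
  function of $\mu$, the SD line is initialized in the $(\mu, \sigma)$
  plane; mean-difference slopes that must be positive are floored at
  0.01.

Model evidence per participant is approximated by the 5-fold
cross-validated log-likelihood (`crossval_loglik()`): blocks — not
trials — are shuffled once per participant and chunked into five
near-equal folds, so training and test trials never share a block; the
held-out sums are averaged over folds. Using predictive likelihood is the
correction for the models' different parameter counts.

Group-level inference uses random-effects Bayesian model selection
(`rfx_bms()`): a Dirichlet prior over population model frequencies
(concentration 1), variational posterior updates until the concentration
changes by less than $10^{-6}$, exceedance probabilities by Monte-Carlo
over the Dirichlet posterior ($10^5$ draws, seeded), and the Bayes
omnibus risk (BOR) from the variational free energy against the exact
evidence of the equal-frequency null. The reported statistic is the
protected exceedance probability
$\mathrm{pxp}_k = (1-\mathrm{BOR})\,\mathrm{EP}_k + \mathrm{BOR}/K$.
At finite sample size the BOR saturates below 1 even for exactly tied
evidence (about 0.90 for 20 participants and 3 models); the tests compare
against that ceiling rather than the asymptote. Across time windows,
multiplicity is controlled by the Simes global test (`simes_global()`)
and, for per-window display, Benjamini–Hochberg FDR (`bh_fdr()`). Since
BMS outputs are not p-values, the package applies Simes to whatever
window-wise p-vector the analyst supplies (e.g. the profile-correlation
p-values); this reading is a package choice.

## Profiles, prediction, decoding

`response_profiles()` computes per-condition across-trial means and SDs
(n−1 denominator throughout) and subtracts the noise-only mean and SD
respectively, so profiles are comparable across participants; the
noise-only entry is exactly zero afterwards. `heard_labels()` applies
the 30 % audibility criterion (inclusive at 30, the trough of the
bimodal rating distribution). `activity_density()` z-scores a
participant's trials with all conditions pooled and estimates
per-condition densities with a Gaussian kernel at the normal-reference
bandwidth $\hat\sigma (4/3n)^{1/5}$ on the fixed grid of 91 points from
−9 to +9 (step 0.2 z-units), so participant curves average cleanly.

`profile_correlation()` correlates each participant's neural profile
(per window) with their behavioral profile over the same conditions
(6 points in the active design) and tests the coefficients against zero
with a one-sided t-test (positive coupling), FDR-corrected across
windows. `best_shift()` implements the active-to-passive threshold-shift
search: the behavioral profile is shifted down the SNR axis by one or
two grid levels (the design step is 2 dB; shifts are in grid levels, with
the noise-only value filling vacated entries), and the shift maximizing
the sum of window-wise correlations exceeding mean + 3 SD of the
pre-stimulus baseline correlations wins; ties go to the smaller shift. A
caveat discovered during development: with 6-point profiles the null
spread of a correlation coefficient is large ($\mathrm{SD} \approx
0.45$), so the 3-SD band is only informative when the pre-stimulus
correlations cluster tightly (as they do when baseline activity has a
stable stimulus-independent pattern); when no window exceeds the band
for any candidate, the function warns and returns the smaller shift.

`state_log_bf()` computes, from a fitted bifurcation model, the
log-likelihood ratio that a trial's activity belongs to the high versus
the low state. It is a pure likelihood ratio by default — the prior odds
$\beta/(1-\beta)$ are excluded, with a `posterior = TRUE` option, a
choice that matters once trials are pooled across SNRs. No behavioral
information enters the fit or the score at any stage, which is the point:
`report_auc()` (Mann–Whitney rank AUC, ties counting one half) then
measures how well these unsupervised scores discriminate heard from
not-heard reports (active sessions, by default pooling the intermediate
SNRs −11, −9, −7 dB) or sound-versus-other mind-wandering probes
(passive sessions, all conditions pooled). Group inference is a
two-sided t-test of per-participant AUCs against 0.5, FDR-corrected
across windows. We use the rank-sum AUC estimator throughout; a paired
signed-rank statistic does not apply to independent present/absent
samples.

The decoding stage (`train_presence_classifier()`,
`projected_activity()`, `temporal_generalization()`) produces the
projected activity consumed by all of the above: an L2-penalized
logistic regression (C = 1) on features standardized with training-fold
statistics, trained on the maximal-SNR versus stimulus-absent contrast
under block-respecting 10-fold cross-validation, every trial scored out
of fold by its signed distance to the decision plane. Temporal
generalization trains at one time sample and tests at all others and all
SNRs; decimation is expressed relative to the 500 Hz acquisition rate,
so `decim = 5` targets 100 Hz and is the identity on fixtures already at
100 Hz. Group maps use the exact two-sided sign test against 0.5 (ties
dropped; at least 6 participants, below which p < 0.05 is unreachable)
with FDR across cells.

## The synthetic-experiment generator

Because the analysis targets data that cannot ship with a package, the
generator (`generate_dataset()`) produces complete synthetic experiments
with the statistical structure the analysis assumes. A scenario assigns a
generating model to each 30-ms window; the stock `switch_scenario()`
uses null dynamics before stimulus onset, unimodal non-linear dynamics
up to 300 ms, and bifurcation dynamics thereafter — the regime change the
pipeline is designed to detect. Windows default to −90 to 600 ms (23
windows), covering a pre-stimulus baseline and the period where the
regime question is live.

Population defaults (means ± SD across participants) are chosen once to
emulate a realistic experiment in arbitrary units with baseline SD about
1: threshold −9 ± 1 dB (the central design level), steepness 1.2 ± 0.2
per dB, high-state amplitude 3 ± 0.5 with baseline step 0.5, giving
roughly a 2-SD state separation at threshold; unimodal scenarios use a
matching logistic mean with an SD slope of 0.15. Participant vectors are
redrawn until valid for the design.

For bifurcation windows a *single* latent high/low state is drawn per
trial from $\beta(s)$ and shared by all bifurcation windows — the
all-or-none character of the late response. Reports are linked to that
state by an invented lapse model (the experiment observes reports, it
does not model them): with lapse probability 0.1 the reported state
flips; audibility ratings are then drawn from a truncated normal on the
matching side of the 30 % criterion (heard: mean 60, SD 15 %, on
[30, 100]; unheard: mean 5, SD 7 %, on [0, 30)). This makes the derived
`heard` flag equal the lapsed latent state exactly while reproducing the
bimodal rating distribution, with modes on either side of 30 %. Passive
sessions label (lapsed) high-state trials "sound" and others uniformly
"task" / "thoughts" / "nothing". Multichannel epochs
(`generate_epochs()`) paint the per-window activity onto a fixed
64-channel topography with spatially correlated sensor noise, 100 Hz
from −500 to +2000 ms.

What the generator deliberately does **not** emulate: temporal
autocorrelation of activity across windows within a regime (windows are
conditionally independent given the trial state), 1/f background
spectra, artifacts, latency jitter, or any coupling between audibility
magnitude and activity beyond the binary state. Passing tests therefore
demonstrate that the pipeline recovers the generative structure it
assumes, at realistic scale and noise — not that real EEG satisfies
those assumptions.

## Problem sizes and reproducibility

The test suite and the acceptance script run the expensive checks at the
scale the properties are stated for — 20 participants × 160 trials per
condition for model and parameter recovery, 50 participants for recovery
error medians, 7 windows around the switch for the regime-change check —
and scale down only the multichannel chain-equivalence check (8
participants, 60 trials per condition, 10 windows), where the comparison
is a per-window agreement rate rather than an estimate. All randomness
flows through explicit integer seeds; the pipeline writes tables with
9-significant-digit floats so reruns with the same configuration are
byte-identical. Epoch arrays use a plain-text container (JSON header plus
full-precision sample lines) behind `read_epochs()`/`write_epochs()`.

## Known limitations

* The noise-only convention for Models 2 and 3 (low-SNR asymptote,
  $\beta = 0$) is a modelling choice where the design leaves the value
  unspecified.
* The shared threshold between $\beta$ and the high-state mean makes
  Model 3 non-nested with Model 2 (see above); comparisons are
  predictive, not likelihood-ratio tests.
* The report linking constants are fixture choices, not estimates; no
  quantitative state-to-rating mapping is claimed.
* The 3-SD rule in the shift search is fragile for short profiles (see
  above) and falls back, with a warning, to the smaller shift.
* Hierarchical (shared-across-participant) estimation and gradient-based
  optimizers are out of scope; each participant is fit independently.
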