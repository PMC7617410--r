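---
title: "Modelling decision confidence with drift-diffusion accumulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decision confidence with drift-diffusion accumulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmconf)
```

## The problem

In a two-array dot-comparison task, an observer watches two patches of dots
whose counts are redrawn every 50 ms from truncated normals separated by 90
dots, and decides which side has more on average, then rates confidence.
The drift diffusion model (DDM) explains the choices and response times:
the observer accumulates the signed difference in momentary evidence, and
in free-response blocks commits when the accumulator hits a threshold.  But
a bare DDM makes a paradoxical prediction for confidence: every decision
terminates at the same accumulated difference, so confidence should be
constant.  `ddmconf` implements a family of DDM variants that resolve this
by (i) continuing accumulation through the sensory/motor pipeline after
the decision, and optionally adding (ii) trial-to-trial drift-rate
variability (V), (iii) linearly collapsing thresholds (D), and (iv) a
Bayesian readout that penalizes accumulated evidence by the time it took
to accumulate (calibrated, C, or miscalibrated, M).  Confidence is treated
strictly ordinally: the noisy readout is mapped to four bins through
fitted bounds, so no assumption about scale use is needed.

## The model

Evidence enters as the signed per-frame dot difference
$e_k = n^{\text{left}}_k - n^{\text{right}}_k$ (dots), held constant within
each 50 ms frame; the accumulator follows
$$dX = \varphi\, e(t)\, dt + \sigma_{\text{acc}}\sqrt{dt}\,\eta,$$
with $\varphi \sim N(1, \sigma_\varphi^2)$ drawn once per trial (fixed at 1
without V).  Accumulator units are dot-seconds; the halfway point between
the array means cancels in the difference, and all gain is absorbed into
the parameters.  In free response, a response is triggered at the first
crossing of $\pm(a - b\,t)$ ($b = 0$ without D) and accumulation continues
on the realized frames for the pipeline duration $I$; under interrogation,
accumulation lasts exactly the stimulus duration and the response is the
sign of the final state (no response lapses).

Confidence is a monotone transform of
$$x_c = \frac{X}{1 - \gamma + \gamma t},$$
where $t$ is the total accumulation time (the response time under free
response, the stimulus duration under interrogation).  For the accumulator
readout $\gamma = 0$; for the calibrated Bayesian readout $\gamma$ is fixed
by the task statistics,
$\gamma = \sigma_\varphi^2\bar\mu^2 / (\sigma_\varphi^2\bar\mu^2 +
\sigma_{\text{acc}}^2 + \sigma_{\text{stim}}^2)$ with
$\sigma_{\text{stim}}^2 = 2\,\text{SD}_{\text{array}}^2\,\Delta t$ the
white-noise-equivalent stimulus variance (the observer is assumed to
ignore the within-frame constancy of the noise, and the coupling between
processing quality and effective stimulus variability); for the
miscalibrated readout $\gamma = \text{logit}^{-1}(\Gamma)$ is free.  The
signed readout is corrupted by metacognitive noise $\sigma_m$ *after* the
time division (the in-text description puts the noise "on the readout" for
every readout type; applying it to the final scalar is the single
implementation consistent with all of them), and compared against three
increasing bounds $d_1 < d_2 < d_3$ with half-open bins $[d_i, d_{i+1})$.
With probability $\lambda$ — and with certainty when a free response is
faster than the pipeline ($rt \le I$) — the report is replaced by a
uniform draw over the four bins.

## The trial-by-trial likelihood

The likelihood of a binned report conditions on the stimulus, the response
and the response time; responses and response times themselves are never
scored (no first-passage densities are computed).  Under free response the
accumulator sat exactly at $R\,(a - b\,t_{\text{dec}})$ at
$t_{\text{dec}} = rt - I$; conditioning $\varphi$ on that endpoint (a
Gaussian conditioning that deliberately ignores the constraint of
non-absorption before $t_{\text{dec}}$) and propagating through the
pipeline evidence gives a normal final state, so bin masses are
normal-CDF differences.  Under interrogation the final state is
$N(S, \sigma_\varphi^2 S^2 + \sigma_{\text{acc}}^2 D)$ — the variance
inflation is itself a Gaussian approximation to the $\varphi$ scale
mixture — truncated to the side of the observed response.  Both
approximations are certified against full forward simulation by the test
suite's oracle checks (three Monte-Carlo standard errors per bin under
interrogation; mean absolute bin error below 0.03 for free response),
not assumed.

Two numerical points matter.  First, the truncated-normal-times-Gaussian
integral of the interrogation case is evaluated by Gauss–Legendre
quadrature in whichever variable leaves a smooth integrand: over the
accumulator when $\sigma_m \ge k\,\text{sd}(X)$, otherwise over the
metacognitive noise with the rule split at the kinks the truncation
induces at $\varepsilon = d_i$.  Normalizing by the same rule makes the
four bins sum to one by construction and keeps the ratio finite in deep
tails (error responses to strong evidence); the default 128-node rule is
converged to well below $10^{-8}$ absolute error, and the fitting path
uses a 32-node rule (worst-case bin error below $10^{-6}$).  Second, each trial's log probability is floored at
$\log(\lambda/4)$, the smallest value the lapse mixture can justify.

## Parameters, bounds and fitting

All variants share eight parameters ($\sigma_{\text{acc}}$, $\sigma_m$,
$a$, $I$, $\lambda$, $d_{1..3}$); V adds $\sigma_\varphi$, D adds $b$, M
adds $\Gamma$ (8–11 in total).  Fitting maximizes the summed log
likelihood with a multi-start scheme: random draws (scale parameters
log-uniform, bin bounds proposed relative to the sampled threshold),
the best start refined by bounded quasi-Newton (`nlminb`, relative
tolerance $10^{-8}$) on a transformed space — $\log\sigma_{\text{acc}}$,
$\log a$, and $(d_1, \log \Delta d_2, \log \Delta d_3)$ so the bound
ordering holds by construction.  No community-standard box bounds or
start distributions exist for these parameters; the boxes used here ($\sigma_{\text{acc}} \in [10^{-2}, 10^3]$, $a \in [1, 10^3]$,
$I \in [0, 1]$ s, $\lambda \in [0, 0.5]$, $\sigma_m \in [0, 10^3]$,
$\sigma_\varphi \in [0, 3]$, $\Gamma \in [-10, 10]$, $b$ kept below
$a/\max rt$ so the collapsing bound stays positive over the observed
decision times) are declared here as this package's own defaults, chosen
to keep the likelihood finite everywhere in the box.  The reference
profile uses 200 starts and 40 repeats; the `"fast"` profile (50 starts,
5 repeats) is the desk-scale profile used throughout the test suite and
recovery studies.

Model comparison uses five-fold cross-validation
stratified by condition with the mean held-out negative log likelihood
per trial (−LLcv) as the score, paired differences to the best model with
10,000-resample bootstrap intervals, and a random-effects comparison that
treats the model identity as a Dirichlet-distributed population variable,
inverted variationally from per-participant −BIC/2 evidences, with
exceedance probabilities from $10^5$ Dirichlet draws.  The
prediction-duplicate variants C and DC (a calibrated observer without
drift variability applies no penalty) enter only this random-effects
analysis, giving the ten-plus-two comparison set.

## The synthetic-data generator

No human data ship with the package, so the generator is a first-class,
fully tested module: it
reproduces the experiment's design — 16 blocks of 40 trials, free/
interrogation alternating within randomized pairs, equal left/right
correct counts per block, interrogation durations drawn from a truncated
normal matched to the previous free block's response times (fallback
750/400 ms), dot counts rounded and rejection-resampled into (0, 3096]
— and forward-simulates every trial by Euler–Maruyama at 1 ms (the
discretization is bounded by a step-refinement test at 4× refinement).

Default observer parameters were fixed *a priori* to reproduce the
published human headline statistics — roughly 77% accuracy, ~2 s mean
response time, a 6-frame (300 ms) pipeline, and near-flat confidence
versus response time under interrogation: $\sigma_{\text{acc}} = 190$
dot·s$^{-1/2}$·s$^{1/2}$-scaled units, $a = 280$ dot·s (these two follow
from the stationary-drift accuracy and mean-decision-time identities at a
90 dots/s drift), $I = 0.3$ s, $\lambda = 0.05$, $\sigma_m = 30$,
$\Gamma = 1.4$ ($\gamma \approx 0.80$, strong enough that the time
penalty roughly cancels evidence growth under interrogation).  Simulated
studies draw per-participant values from ranges around these (e.g.
$\sigma_m \in [15, 60]$, $\Gamma \in [0.4, 2.2]$) so that
between-participant recovery statistics are defined.  Bin bounds are set
at each simulated participant's readout quartiles, mirroring the
per-participant quantile binning applied to human reports; a continuous
report (the noisy readout itself; for lapsed trials a uniform draw within
the lapsed bin's padded bounds) accompanies the 4-level bin so the
model-free battery can 5-quantile-bin confidence and apply the raw-value
exclusion rule exactly as preregistered.

What the generator does *not* emulate: overweighting of stimulus-onset
evidence, trial-to-trial pipeline-duration variability, response lapses,
confidence response times, and idiosyncratic confidence-scale use.
Passing tests therefore certify the internal consistency of likelihood,
fitting and analysis code under the model's own assumptions — not that
human data would be fit equally well.

## The model-free battery

The analysis battery mirrors the preregistered pipeline: evidence
fluctuations (dot counts centred on their generating means, signed toward
the choice); the pipeline duration estimated by fitting a step function
(drop between 1 and 10 frames, RMSE-minimal, ties broken toward the
smallest drop) to the mean fluctuation over the 12 pre-response frames;
trial exclusions (no confidence report, or at most as many whole frames
before the response as the pipeline estimate) and participant exclusions
(accuracy < 60%, any raw confidence value over 30% of reports, any
5-quantile bin under 5%, under 70 included trials, predictor condition
number over 1000 — evaluated per condition, either condition failing
excludes the participant); per-participant cumulative-probit regressions
of 5-binned confidence on z-scored response time, predecision evidence,
pipeline evidence and accuracy, with slopes back-transformed to raw
units; and the four one-tailed tests on those coefficients with
one-sample Cohen's *d*.  On interrogation trials the stimulus has cleared
before the response is permitted, so frame lags and the predecision/
pipeline split are taken relative to stimulus offset — the final stimulus
frames play the "pipeline" role purely for cross-condition comparison.
Evidence predictors for the regressions are raw dot sums over whole
frames (the likelihood code, by contrast, uses time-weighted sums with
fractional frames; the regression battery is model-free and works in the
stimulus's native per-frame dot units).  Kendall's tau for the confidence kernel
is the tie-corrected tau-b.

## Design choices on genuinely open points

* **Dot truncation** is by rejection (round, then resample out-of-range
  values) rather than clipping; clipping would place atoms at the bounds.
* **Interrogation durations** are rounded down to whole frames, matching
  the frame-locked display.
* **Γ → γ** is the logistic map; only the transformed variable is named
  in the source description.
* **The threshold slope applies at decision time** $t_{\text{dec}} = rt -
  I$ (bound value $a - b\,t_{\text{dec}}$), while the readout's time
  penalty uses the total accumulation time; the two times are distinguished
  only implicitly in the source description.
* **Free-response stimuli** are generated to 20 s; a path that has not
  crossed by then is flagged censored and scored as a certain lapse; the
  task design needs no cap (crossings this slow essentially never occur
  at the default parameters).
* **Deep-tail normalization** uses the same quadrature for numerator and
  denominator on a log scale instead of a separate Mills-ratio expansion:
  the conditional bin masses stay exact ratios and cannot produce 0/0.
* **Positive accumulator direction is "left"**, responses are stored as
  ±1 with left = +1 throughout.
* **Feature-safety in model recovery** is asserted on the BIC winner:
  AIC's weaker complexity penalty admits occasional ties that add a
  feature, so "never adds an absent feature" is a BIC-level claim.

## Problem sizes used by the test suite

The oracle and recovery studies run at sizes chosen to give stable
statistics on a single core: 2×10⁵ forward simulations per interrogation
oracle cell (3×3×3 grid), 2–6×10⁵ full paths per free-response oracle
cell, 12 simulated participants × 640 trials for parameter recovery and
24 × 640 for the preregistered-test battery (fast fitting profile), and
6 participants per generator at 320 trials for the feature-safety
recovery with candidate set {0, V, M, DM}.

## Known limitations

The free-response likelihood inherits the endpoint approximation of the
drift-scaling posterior; its error grows with $\sigma_\varphi$ and with
very slow decisions, and is controlled empirically (oracle tolerance
0.03) rather than analytically.  Metacognitive noise is weakly identified
from 640 binned reports: $\sigma_m$ trades off against the time-penalty
weight and the accumulator-noise terms along a flat likelihood ridge, and
its maximum-likelihood estimate can collapse to zero on individual
simulated participants even though the generating value generalizes
better out of sample — recovery studies of $\sigma_m$ should treat
per-participant point estimates with caution at this sample size.  The collapsing bound is linear only, and
parameter sets whose bound reaches zero inside the observed decision
times are rejected rather than reparameterized.  BMS exceedance
probabilities are Monte-Carlo estimates; rerun with a larger
`n_samples` if the third decimal matters.
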