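# ddmconf

Drift-diffusion models of decision confidence for the two-array
dot-comparison task: a generative task simulator, trial-by-trial analytic
likelihoods of binned confidence for ten model variants, maximum-likelihood
fitting with cross-validated and random-effects model comparison, and the
accompanying model-free behavioral battery (pipeline-duration estimation,
ordinal probit evidence regressions, psychophysical kernels).

## Who this is for

Researchers in perceptual decision making who want to test whether
confidence reports can be explained by the *same* evidence accumulation
that produces the choice.  In the drift diffusion model (DDM) the observer
accumulates the signed difference in momentary evidence,
`dX = phi * e(t) dt + sigma_acc * sqrt(dt) * eta`, and responds at the
first crossing of `±(a − b t)` under free response, or after the stimulus
ends under interrogation.  Because free-response decisions always terminate
on a threshold, a bare DDM predicts constant confidence; the variants here
add post-decision "pipeline" accumulation (all variants), trial-to-trial
drift-rate variability (V), collapsing thresholds (D), and a Bayesian
confidence readout

    x_c = X / (1 − gamma + gamma t)

whose time penalty `gamma` is either fixed by the task statistics
(calibrated, C) or a free miscalibration parameter (M).  Confidence is
ordinal: the readout, corrupted by metacognitive noise `sigma_m` and mixed
with a lapse rate `lambda`, falls into one of four bins at fitted bounds
`d1 < d2 < d3`.  The likelihood scores each observed confidence bin
conditional on that trial's stimulus, response and response time — choices
and response times are conditioned on, never fitted.

## Worked example

Simulate one miscalibrated-Bayesian observer under the experiment's design
(16 blocks of 40 trials, free-response and interrogation blocks
alternating in pairs), then refit the generating variant:

```r
library(ddmconf)
cfg  <- task_config()            # 50 ms frames, 90-dot separation, SD 220
spec <- model_spec("M")
ds   <- simulate_dataset(cfg, default_params(spec), spec, seed = 42)

mean(ds$trials$response == ds$trials$correct_side)  # accuracy
#> [1] 0.7796875
mean(ds$trials$rt[ds$trials$condition == "free_response"])
#> [1] 1.941553

enc <- encode_trials(ds$trials, ds$frames, cfg$frame_duration)
set.seed(1)
fit <- fit_model(enc, spec, fit_config("fast"))
fit
#> ML fit, variant M: logLik = -741.908 (n = 640, k = 9), AIC = 1501.82, BIC = 1541.97
round(gamma_from_Gamma(fit$params$Gamma), 2)   # fitted time-penalty weight
#> [1] 0.8
```

The simulated observer applies a strong time penalty
(`gamma_from_Gamma(1.4)` is 0.80) and the fit recovers it.  The
`logLik` is the summed log probability of the 640 observed confidence
bins; `AIC`/`BIC` follow from the variant's 9 parameters, and
`fit$evidence` (−BIC/2) feeds the random-effects comparison
(`bms_random_effects()`, `family_comparison()`).  Cross-validated
comparison uses `crossvalidate()` and `compare_fixed_effects()`; the
model-free battery — pipeline estimation, preregistered exclusions,
per-participant ordinal probit regressions and the four one-tailed tests
on their coefficients — runs via `analyze_dataset()`.

A command-line wrapper with `simulate`, `fit`, `compare`, `analyze` and
`recover` subcommands is installed at `inst/cli/ddmconf.R`.

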