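#' Reference parameter values for simulated observers
#'
#' A parameter set chosen to reproduce the task's headline human statistics
#' (roughly 77% accuracy, ~2 s mean response time, a 6-frame processing
#' pipeline, confidence nearly flat in response time under interrogation):
#' `sigma_acc = 190`, `sigma_m = 30`, `a = 280`, `I = 0.3`, `lambda = 0.05`,
#' with `sigma_phi = 0.5`, `b = 25` and `Gamma = 1.4` (`gamma ~ 0.80`) for
#' variants that use them.  Bin bounds `d` default to `NULL` so that
#' [simulate_dataset()] calibrates them at each simulated participant's
#' readout quartiles.
#'
#' @param spec A `ddm_spec`.
#' @param d Optional explicit bin bounds.
#' @return A [ddm_params()].
#' @export
default_params <- function(spec, d = NULL) {
  ddm_params(spec, sigma_acc = 190, sigma_m = 30, a = 280, I = 0.3,
             lambda = 0.05, d = d,
             sigma_phi = if (spec$drift_variability) 0.5,
             b = if (spec$collapsing_bound) 25,
             Gamma = if (spec$readout == "bayes_miscalibrated") 1.4)
}

#' Sample heterogeneous participant parameters
#'
#' Draws one parameter set per simulated participant, jittered around
#' [default_params()] over ranges wide enough that between-participant
#' differences (e.g. in metacognitive noise or the time-penalty weight) are
#' identifiable, while keeping every participant inside the task's
#' exclusion criteria by construction.  The pipeline duration is held at
#' 0.3 s (6 frames) for all participants.
#'
#' @param spec A `ddm_spec`.
#' @param n Number of participants.
#' @return List of `n` [ddm_params()] with `d = NULL`.
#' @export
sample_participant_params <- function(spec, n) {
  lapply(seq_len(n), function(i) {
    ddm_params(spec,
               sigma_acc = runif(1, 160, 220),
               sigma_m = runif(1, 15, 60),
               a = runif(1, 230, 330),
               I = 0.3,
               lambda = runif(1, 0.01, 0.08),
               d = NULL,
               sigma_phi = if (spec$drift_variability) runif(1, 0.3, 0.8),
               b = if (spec$collapsing_bound) runif(1, 10, 40),
               Gamma = if (spec$readout == "bayes_miscalibrated")
                 runif(1, 0.4, 2.2))
  })
}
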