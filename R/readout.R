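#' Map the unconstrained miscalibration parameter to the time-penalty weight
#'
#' The miscalibrated Bayesian observer's time penalty is governed by
#' `gamma` in (0, 1); it is fitted on the unconstrained scale as
#' `Gamma = qlogis(gamma)`.
#'
#' @param Gamma Real number.
#' @return `gamma = plogis(Gamma)`.
#' @export
gamma_from_Gamma <- function(Gamma) plogis(Gamma)

#' Time-penalty weight of a calibrated Bayesian observer
#'
#' For an observer with perfect knowledge of the task statistics, the weight
#' given to elapsed time reflects the share of drift-rate variability in the
#' total variability of the evidence stream:
#' `gamma = sigma_phi^2 mu^2 / (sigma_phi^2 mu^2 + sigma_acc^2 + stim_var)`,
#' with `mu` the expected evidence rate and `stim_var` the white-noise
#' equivalent stimulus variance per second.  Without drift-rate variability
#' the accumulation rate carries no information about difficulty and
#' `gamma = 0`: the readout reduces to the accumulator state.
#'
#' @param params A [ddm_params()].
#' @param stats A [task_stats()].
#' @return `gamma` in `[0, 1)`.
#' @export
calibrated_gamma <- function(params, stats = task_stats()) {
  sp <- params$sigma_phi
  if (is.null(sp) || sp == 0) return(0)
  num <- sp^2 * stats$mean_rate^2
  num / (num + params$sigma_acc^2 + stats$stim_var)
}

# gamma entering the readout, per variant
resolve_gamma <- function(params, spec = params$spec, stats = NULL) {
  switch(spec$readout,
         accumulator = 0,
         bayes_calibrated = calibrated_gamma(params,
                                             if (is.null(stats)) task_stats() else stats),
         bayes_miscalibrated = gamma_from_Gamma(params$Gamma))
}

#' Confidence readout
#'
#' The scalar the observer's confidence report is a monotone function of:
#' the final accumulator state for the core readout, or the accumulated
#' evidence penalized by accumulation time, `X / (1 - gamma + gamma t)`, for
#' the Bayesian readouts.
#'
#' @param X Final accumulator state (dot.s).
#' @param t Time spent accumulating evidence, seconds.
#' @param spec A `ddm_spec`.
#' @param gamma Time-penalty weight in `[0, 1]`; defaults to 0 for the
#'   accumulator readout.
#' @return The readout `x_c`.
#' @export
readout <- function(X, t, spec, gamma = 0) {
  stopifnot(all(t >= 0), all(gamma >= 0 & gamma <= 1))
  if (spec$readout == "accumulator") X else X / (1 - gamma + gamma * t)
}

#' Split a stimulus into predecision and pipeline evidence
#'
#' The decision is taken at `t_dec = rt - I`; evidence presented before then
#' drove the choice, evidence presented in the final `I` seconds was still in
#' sensory and motor processing pipelines and informs only confidence.  Both
#' sums are time-weighted (dot.s); a frame straddling `t_dec` contributes
#' fractionally by temporal overlap.
#'
#' @param stimulus A `ddm_stimulus`.
#' @param rt Response time, seconds.
#' @param I Pipeline duration, seconds.
#' @return List with `E_pre`, `E_pipe` (dot.s), `t_dec` (seconds) and
#'   `lapse_certain` (`TRUE` when `rt <= I`, in which case `E_pre = 0` and
#'   the confidence report is modelled as certainly a lapse).
#' @export
split_evidence <- function(stimulus, rt, I) {
  if (rt <= 0) stop("rt must be > 0")
  e <- stimulus_evidence(stimulus)
  dt <- stimulus$frame_duration
  t_dec <- rt - I
  if (t_dec <= 0)
    return(list(E_pre = 0,
                E_pipe = cpp_evidence_integral(e, dt, 0, rt),
                t_dec = t_dec, lapse_certain = TRUE))
  list(E_pre = cpp_evidence_integral(e, dt, 0, t_dec),
       E_pipe = cpp_evidence_integral(e, dt, t_dec, rt),
       t_dec = t_dec, lapse_certain = FALSE)
}

#' Posterior over the drift-rate scaling given a threshold crossing
#'
#' Gaussian conditioning of the trial's drift-rate scaling
#' `phi ~ N(1, sigma_phi^2)` on the event that the accumulator, driven by the
#' predecision evidence `E_pre` plus accumulator noise, sat exactly at the
#' (signed) threshold at the decision time.  The constraint that the path did
#' not touch a threshold earlier is deliberately ignored; the quality of this
#' endpoint approximation is bounded by the simulation oracle tests.
#'
#' @param E_pre Time-weighted predecision evidence, dot.s (signed).
#' @param t_dec Decision time, seconds; must be > 0.
#' @param crossed_value Signed accumulator value at the crossing,
#'   `R * (a - b t_dec)`.
#' @param params A [ddm_params()].
#' @return List with `mean` and `variance` of `phi` given the crossing.
#' @export
posterior_drift_scaling <- function(E_pre, t_dec, crossed_value, params) {
  if (t_dec <= 0) stop("t_dec must be > 0")
  sp <- params$sigma_phi
  if (is.null(sp) || sp == 0) return(list(mean = 1, variance = 0))
  den <- sp^2 * E_pre^2 + params$sigma_acc^2 * t_dec
  list(mean = 1 + sp^2 * E_pre * (crossed_value - E_pre) / den,
       variance = sp^2 * params$sigma_acc^2 * t_dec / den)
}

#' Final accumulator state on a free-response trial
#'
#' Given the response and response time, the accumulator sat at the signed
#' threshold `R (a - b t_dec)` at decision time; over the pipeline it
#' accrued the pipeline evidence scaled by the (posterior) drift-rate
#' scaling, plus accumulator noise.  The final state at `rt` is Gaussian:
#' `mean = crossed + m_phi E_pipe`, `var = v_phi E_pipe^2 + sigma_acc^2 I`.
#'
#' @param stimulus A `ddm_stimulus`.
#' @param response `+1` or `-1`.
#' @param rt Response time, seconds; must exceed `I`.
#' @param params A [ddm_params()].
#' @param spec A `ddm_spec` (defaults to the params' spec).
#' @return List with `mean` and `variance` of `X(rt)` (dot.s).
#' @export
final_state_free <- function(stimulus, response, rt, params,
                             spec = params$spec) {
  ev <- split_evidence(stimulus, rt, params$I)
  if (ev$lapse_certain) stop("rt <= I: no predecision accumulation")
  b <- if (is.null(params$b)) 0 else params$b
  bound <- params$a - b * ev$t_dec
  if (bound <= 0) stop("collapsing bound non-positive at decision time (degenerate threshold)")
  crossed <- response * bound
  post <- if (spec$drift_variability)
    posterior_drift_scaling(ev$E_pre, ev$t_dec, crossed, params)
  else list(mean = 1, variance = 0)
  list(mean = crossed + post$mean * ev$E_pipe,
       variance = post$variance * ev$E_pipe^2 + params$sigma_acc^2 * params$I)
}

#' Final accumulator state on an interrogation trial (before conditioning)
#'
#' Accumulation lasts exactly the stimulus duration `D`; with `S` the
#' time-weighted total signed evidence, the final state is
#' `N(S, sigma_phi^2 S^2 + sigma_acc^2 D)` (variance inflation by drift-rate
#' variability only for variants with V).
#'
#' @param stimulus A `ddm_stimulus` with a `planned_duration`.
#' @param params A [ddm_params()].
#' @param spec A `ddm_spec`.
#' @return List with `mean` and `variance` of the final state.
#' @export
final_state_interrogation <- function(stimulus, params, spec = params$spec) {
  D <- stimulus$planned_duration
  if (is.null(D)) stop("stimulus has no planned duration (not an interrogation trial)")
  S <- cpp_evidence_integral(stimulus_evidence(stimulus),
                             stimulus$frame_duration, 0, D)
  sp <- if (spec$drift_variability) params$sigma_phi else 0
  list(mean = S, variance = sp^2 * S^2 + params$sigma_acc^2 * D)
}
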