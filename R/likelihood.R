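#' Bundle a stimulus with the observables the likelihood conditions on
#'
#' @param stimulus A `ddm_stimulus`.
#' @param response `+1` (left) or `-1` (right).
#' @param rt Response time from stimulus onset, seconds.
#' @param confidence_bin Ordinal confidence report in 1..4, or `NA`.
#' @return An object of class `ddm_trial`.  `accumulation_time` is `rt` on
#'   free-response trials and the planned stimulus duration on interrogation
#'   trials (which must not exceed `rt`).
#' @export
behavioral_trial <- function(stimulus, response, rt, confidence_bin = NA) {
  stopifnot(inherits(stimulus, "ddm_stimulus"), response %in% c(-1, 1))
  if (rt <= 0) stop("rt must be > 0")
  if (!is.na(confidence_bin) && !confidence_bin %in% 1:4)
    stop("confidence_bin must be in 1..4")
  t_acc <- if (stimulus$condition == "interrogation") {
    if (stimulus$planned_duration > rt + 1e-9)
      stop("interrogation accumulation time exceeds rt")
    stimulus$planned_duration
  } else rt
  structure(list(stimulus = stimulus, response = response, rt = rt,
                 accumulation_time = t_acc, confidence_bin = confidence_bin),
            class = "ddm_trial")
}

encode_one_trial <- function(trial) {
  st <- trial$stimulus
  list(cond = as.integer(st$condition == "interrogation"),
       R = trial$response, t_acc = trial$accumulation_time, rt = trial$rt,
       bin = if (is.na(trial$confidence_bin)) NA_integer_
             else as.integer(trial$confidence_bin),
       offset = 0L, nframes = length(st$frames_left),
       frames = stimulus_evidence(st), dt = st$frame_duration)
}

#' Pack a trials/frames table pair into the fast likelihood layout
#'
#' Fitting evaluates the likelihood thousands of times; this packs the
#' per-trial frame evidence into flat vectors once.  Trials without a
#' confidence report are dropped (they carry no likelihood).
#'
#' @param trials Trials table with columns `participant`, `trial`,
#'   `condition`, `response`, `rt`, `stimulus_duration`, `confidence_bin`.
#' @param frames Frames table with columns `participant`, `trial`, `frame`,
#'   `dots_left`, `dots_right` (frames 0-indexed within trial).
#' @param frame_duration Frame length, seconds.
#' @return An opaque list consumed by [dataset_log_likelihood()] and the
#'   fitting functions.
#' @export
encode_trials <- function(trials, frames, frame_duration = 0.05) {
  keep <- !is.na(trials$confidence_bin)
  trials <- trials[keep, , drop = FALSE]
  key_t <- paste(trials$participant, trials$trial, sep = "\r")
  frames <- frames[order(frames$participant, frames$trial, frames$frame), ]
  key_f <- paste(frames$participant, frames$trial, sep = "\r")
  ev_all <- frames$dots_left - frames$dots_right
  split_ev <- split(ev_all, factor(key_f, levels = unique(key_f)))
  idx <- match(key_t, names(split_ev))
  if (anyNA(idx)) stop("frames table is missing trials present in the trials table")
  ev_list <- split_ev[idx]
  nframes <- lengths(ev_list)
  frames_vec <- unlist(ev_list, use.names = FALSE)
  offset <- c(0L, cumsum(nframes))[seq_along(nframes)]
  inter <- trials$condition == "interrogation"
  list(cond = as.integer(inter),
       R = as.numeric(trials$response),
       t_acc = ifelse(inter, trials$stimulus_duration, trials$rt),
       rt = as.numeric(trials$rt),
       bin = as.integer(trials$confidence_bin),
       offset = as.integer(offset),
       nframes = as.integer(nframes),
       frames = as.numeric(frames_vec),
       dt = frame_duration,
       n = nrow(trials),
       condition = trials$condition,
       participant = trials$participant)
}

#' Analytic confidence-bin probabilities for one trial
#'
#' Probability of each of the four ordinal confidence bins given the
#' stimulus, response and response time.  On free-response trials the final
#' accumulator state is Gaussian given the threshold crossing
#' ([final_state_free()]); the signed, time-penalized, metacognitive-noise
#' corrupted readout is therefore Gaussian and bin masses are normal-CDF
#' differences at the bounds `d`.  On interrogation trials the final state
#' ([final_state_interrogation()]) is additionally conditioned on producing
#' the observed response (`R X > 0`) before the linear readout; the
#' truncated-normal-times-Gaussian integral is evaluated by log-scaled
#' Gauss-Legendre quadrature (absolute error below 1e-8 at the default node
#' count), normalized so the four bins sum to one.  The model mass is mixed
#' with a uniform lapse component `lambda/4` per bin; a free-response trial
#' with `rt <= I` is scored as certainly a lapse.
#'
#' @param trial A [behavioral_trial()].
#' @param params A [ddm_params()] with bounds `d` set.
#' @param spec A `ddm_spec`; defaults to the params' spec.
#' @param stats A [task_stats()] (needed for calibrated readouts).
#' @param n_nodes Quadrature nodes for the interrogation integral.
#' @return List with `p` (length-4 probability vector, sums to 1) and
#'   `lapse_component` (the mixture weight on the uniform lapse).
#' @export
confidence_bin_probabilities <- function(trial, params, spec = params$spec,
                                         stats = NULL, n_nodes = 128) {
  enc <- encode_one_trial(trial)
  gl <- gl_rule(n_nodes)
  p <- cpp_bin_probs(enc$cond, enc$R, enc$t_acc, enc$rt, enc$offset,
                     enc$nframes, enc$frames, enc$dt,
                     params_to_cpar(params, stats), gl$nodes, gl$weights)[1, ]
  if (anyNA(p)) stop("collapsing bound non-positive at decision time (degenerate threshold)")
  lam_eff <- if (enc$cond == 0 && enc$rt <= params$I) 1 else params$lambda
  list(p = p, lapse_component = lam_eff)
}

#' Log likelihood of one confidence report
#'
#' Log of the observed bin's probability under
#' [confidence_bin_probabilities()], floored at `log(lambda/4)` when
#' `lambda > 0` for numerical stability.
#'
#' @inheritParams confidence_bin_probabilities
#' @return Scalar log probability.
#' @export
trial_log_likelihood <- function(trial, params, spec = params$spec,
                                 stats = NULL, n_nodes = 128) {
  if (is.na(trial$confidence_bin)) stop("trial has no confidence report")
  pr <- confidence_bin_probabilities(trial, params, spec, stats, n_nodes)
  floor_p <- if (params$lambda > 0) params$lambda / 4 else 1e-300
  log(max(pr$p[trial$confidence_bin], floor_p))
}

#' Dataset log likelihood
#'
#' Sum of per-trial log likelihoods over an encoded dataset (confidence
#' reports are conditionally independent across trials given the stimuli,
#' responses and response times).
#'
#' @param encoded Output of [encode_trials()].
#' @param params A [ddm_params()].
#' @param spec,stats,n_nodes See [confidence_bin_probabilities()].
#' @param per_trial Return the per-trial vector instead of the sum.
#' @return Total log likelihood (or per-trial vector).
#' @export
dataset_log_likelihood <- function(encoded, params, spec = params$spec,
                                   stats = NULL, n_nodes = 64,
                                   per_trial = FALSE) {
  gl <- gl_rule(n_nodes)
  ll <- cpp_trial_loglik(encoded$cond, encoded$R, encoded$t_acc, encoded$rt,
                         encoded$bin, encoded$offset, encoded$nframes,
                         encoded$frames, encoded$dt,
                         params_to_cpar(params, stats),
                         gl$nodes, gl$weights)
  if (per_trial) ll else sum(ll)
}
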