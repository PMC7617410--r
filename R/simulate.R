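# padded outer bounds used to draw a continuous report for lapsed trials
pad_bounds <- function(d) {
  w <- d[3] - d[1]
  c(d[1] - w, d[1], d[2], d[3], d[3] + w)
}

bin_from_readout <- function(s, d) findInterval(s, d) + 1L

#' Forward-simulate one trial
#'
#' Free response: Euler-Maruyama integration of
#' `dX = phi e(t) dt + sigma_acc sqrt(dt) eta` at step `dt_sim`, with `e(t)`
#' the signed frame difference held constant within each 50 ms frame and
#' `phi ~ N(1, sigma_phi^2)` drawn once per trial; the first crossing of
#' `+/-(a - b t)` triggers the response at `rt = t_dec + I`, and accumulation
#' continues on the realized frames until `rt`.  Interrogation: accumulation
#' lasts exactly the planned stimulus duration (integrated exactly; there is
#' no absorbing boundary), the response is the sign of the final state, and
#' the response itself follows the cue after a short motor delay.  The
#' confidence readout is time-penalized per the variant, corrupted by
#' metacognitive noise, and lapses with probability `lambda` (with certainty
#' when `rt <= I`) replace the report with a uniform bin.
#'
#' @param stimulus A `ddm_stimulus`.
#' @param params A [ddm_params()]; `d` may be `NULL`, in which case the
#'   confidence bin is left `NA` (see [simulate_dataset()]).
#' @param spec A `ddm_spec`.
#' @param stats A [task_stats()] (calibrated readouts).
#' @param config Task configuration (interrogation cue delay).
#' @param dt_sim Simulation step, seconds.
#' @param t_max Hard cap on decision time, seconds; a free-response trial
#'   with no crossing by `t_max` is flagged censored and scored as a lapse.
#' @return A list with the observables (`response`, `rt`,
#'   `accumulation_time`, `confidence_bin`, `confidence_raw`) and the latent
#'   variables (`phi`, `decision_time`, `final_state`, `readout_signed`,
#'   `lapsed`, `censored`).
#' @export
simulate_trial <- function(stimulus, params, spec = params$spec,
                           stats = NULL, config = task_config(),
                           dt_sim = 0.001, t_max = 20) {
  gamma <- resolve_gamma(params, spec, stats)
  sp <- if (spec$drift_variability) params$sigma_phi else 0
  b <- if (spec$collapsing_bound) params$b else 0
  ev <- stimulus_evidence(stimulus)
  dt <- stimulus$frame_duration
  if (stimulus$condition == "free_response") {
    path <- cpp_free_paths(ev, dt, 1L, sp, params$sigma_acc, params$a, b,
                           params$I, dt_sim, t_max)
    censored <- path$censored[1]
    if (censored && path$decision_time[1] < t_max - 1e-6)
      stop("stimulus shorter than the required accumulation (insufficient stimulus)")
    R <- path$response[1]; rt <- path$rt[1]; t_acc <- rt
    X <- path$x_rt[1]; phi <- path$phi[1]; t_dec <- path$decision_time[1]
    lapse_certain <- censored || rt <= params$I
  } else {
    D <- stimulus$planned_duration
    S <- cpp_evidence_integral(ev, dt, 0, D)
    phi <- 1 + sp * rnorm(1)
    X <- phi * S + params$sigma_acc * sqrt(D) * rnorm(1)
    R <- if (X >= 0) 1 else -1
    t_dec <- D; t_acc <- D
    rt <- D + rtrunc_norm1(config$cue_response_delay_mean,
                           config$cue_response_delay_sd, c(0.1, 1))
    censored <- FALSE; lapse_certain <- FALSE
  }
  k <- 1 / (1 - gamma + gamma * t_acc)
  s <- if (is.na(X)) NA_real_
       else R * k * X + params$sigma_m * rnorm(1)
  lapsed <- lapse_certain || runif(1) < params$lambda
  if (lapsed) {
    bin <- sample.int(4L, 1L)
    raw <- if (is.null(params$d)) NA_real_ else {
      pb <- pad_bounds(params$d); runif(1, pb[bin], pb[bin + 1])
    }
  } else {
    bin <- if (is.null(params$d)) NA_integer_ else bin_from_readout(s, params$d)
    raw <- s
  }
  list(stimulus = stimulus, response = R, rt = rt, accumulation_time = t_acc,
       decision_time = t_dec, confidence_bin = bin, confidence_raw = raw,
       phi = phi, final_state = X, readout_signed = s,
       lapsed = lapsed, censored = censored)
}

#' Simulate a complete block-structured study
#'
#' Reproduces the experiment design: `n_blocks` blocks of `trials_per_block`
#' trials, each successive pair comprising one free-response and one
#' interrogation block in random order, equal left/right correct counts per
#' block, and interrogation durations matched to the response times of the
#' most recent free-response block.  When a participant's `d` is `NULL`, the
#' bin bounds are set at the quartiles of that participant's non-lapse
#' readouts (mirroring per-participant quantile binning of reports) and
#' recorded in the returned true parameters.
#'
#' @param config A [task_config()].
#' @param params A [ddm_params()] or a list of one per participant.
#' @param spec A `ddm_spec`.
#' @param n_participants Number of participants (ignored when `params` is a
#'   list).
#' @param seed Master seed; per-participant seeds are derived from it and
#'   recorded.
#' @param stats,dt_sim,t_max Passed to [simulate_trial()].
#' @return An object of class `ddm_dataset`: `trials` and `frames` tables
#'   (one row per trial / per frame), `participants` (true parameters and
#'   seed per participant), `config`, `spec`, `seed`.
#' @export
simulate_dataset <- function(config, params, spec = NULL, n_participants = 1,
                             seed = NULL, stats = NULL, dt_sim = 0.001,
                             t_max = 20) {
  if (inherits(params, "ddm_params")) {
    if (is.null(spec)) spec <- params$spec
    params <- rep(list(params), n_participants)
  } else if (is.null(spec)) spec <- params[[1]]$spec
  n_p <- length(params)
  if (n_p < 1) stop("at least one participant required")
  if (!is.null(seed)) set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, n_p)
  trials_l <- list(); frames_l <- list(); truth <- list()
  dt <- config$frame_duration
  for (p in seq_len(n_p)) {
    set.seed(pseeds[p])
    par_p <- params[[p]]
    max_I <- par_p$I
    stim_dur_free <- t_max + max_I + dt
    last_free_rts <- numeric(0)
    rows <- list(); fr <- list(); tr_idx <- 0L
    for (pair in seq_len(config$n_blocks / 2)) {
      order_pair <- sample(c("free_response", "interrogation"))
      for (cond in order_pair) {
        sides <- sample(rep(c(1, -1), config$trials_per_block / 2))
        block_rts <- numeric(0)
        for (side in sides) {
          tr_idx <- tr_idx + 1L
          dur <- if (cond == "interrogation")
            sample_interrogation_duration(last_free_rts, config)
          else stim_dur_free
          stim <- sample_stimulus(config, cond, side, dur)
          sim <- simulate_trial(stim, par_p, spec, stats, config, dt_sim, t_max)
          n_keep <- if (cond == "free_response")
            min(ceiling(sim$rt / dt - 1e-9), length(stim$frames_left))
          else length(stim$frames_left)
          rows[[tr_idx]] <- data.frame(
            participant = p, block = 2L * (pair - 1L) +
              match(cond, order_pair), trial = tr_idx, condition = cond,
            correct_side = side, response = sim$response, rt = sim$rt,
            stimulus_duration = if (cond == "interrogation") dur else sim$rt,
            n_frames = n_keep,
            confidence_bin = sim$confidence_bin,
            confidence_raw = sim$confidence_raw,
            halfway = stim$halfway_point,
            phi = sim$phi, decision_time = sim$decision_time,
            final_state = sim$final_state,
            readout_signed = sim$readout_signed,
            lapsed = sim$lapsed, censored = sim$censored)
          fr[[tr_idx]] <- data.frame(
            participant = p, trial = tr_idx,
            frame = seq_len(n_keep) - 1L,
            dots_left = stim$frames_left[seq_len(n_keep)],
            dots_right = stim$frames_right[seq_len(n_keep)])
          if (cond == "free_response") block_rts <- c(block_rts, sim$rt)
        }
        if (cond == "free_response") last_free_rts <- block_rts
      }
    }
    tdf <- do.call(rbind, rows)
    par_true <- par_p
    if (is.null(par_p$d)) {
      ok <- !tdf$lapsed & !tdf$censored & !is.na(tdf$readout_signed)
      d_p <- unname(quantile(tdf$readout_signed[ok], c(0.25, 0.5, 0.75),
                             type = 7))
      if (any(diff(d_p) <= 0)) stop("degenerate readout distribution; cannot calibrate bin bounds")
      par_true <- ddm_params(spec, par_p$sigma_acc, par_p$sigma_m, par_p$a,
                             par_p$I, par_p$lambda, d = d_p,
                             sigma_phi = par_p$sigma_phi, b = par_p$b,
                             Gamma = par_p$Gamma)
      pb <- pad_bounds(d_p)
      lap <- which(tdf$lapsed)
      tdf$confidence_bin[!tdf$lapsed & ok] <-
        bin_from_readout(tdf$readout_signed[!tdf$lapsed & ok], d_p)
      for (i in lap) {
        b_i <- sample.int(4L, 1L)
        tdf$confidence_bin[i] <- b_i
        tdf$confidence_raw[i] <- runif(1, pb[b_i], pb[b_i + 1])
      }
      tdf$confidence_raw[!tdf$lapsed] <- tdf$readout_signed[!tdf$lapsed]
    }
    truth[[p]] <- list(params = par_true, spec = spec, seed = pseeds[p])
    trials_l[[p]] <- tdf
    frames_l[[p]] <- do.call(rbind, fr)
  }
  structure(list(trials = do.call(rbind, trials_l),
                 frames = do.call(rbind, frames_l),
                 participants = truth, config = config, spec = spec,
                 seed = seed),
            class = "ddm_dataset")
}

#' @export
print.ddm_dataset <- function(x, ...) {
  cat("ddm_dataset:", length(x$participants), "participant(s),",
      nrow(x$trials), "trials, variant", x$spec$name, "\n")
  invisible(x)
}

#' Monte-Carlo confidence-bin probabilities (simulation oracle)
#'
#' Forward-simulates the generative process on a given stimulus and returns
#' conditional confidence-bin frequencies: interrogation simulations are
#' conditioned on the observed response, free-response simulations are
#' retained when their response matches and their response time falls in
#' `rt_window`.  The lapse mixture is applied analytically (it is exact and
#' adds no Monte-Carlo noise).  Serves as the independent oracle for
#' [confidence_bin_probabilities()].
#'
#' @param stimulus A `ddm_stimulus`.
#' @param response Conditioning response, `+1` or `-1`.
#' @param rt_window Length-2 window `[lo, hi]` on response time
#'   (free-response only).
#' @param params,spec,stats Model and parameters.
#' @param n_sims Number of forward simulations (>= 1e4).
#' @param dt_sim,t_max Simulation controls for free-response paths.
#' @return List with `p` (length-4), `se` (Monte-Carlo standard errors) and
#'   `n_retained`.
#' @export
mc_bin_probabilities <- function(stimulus, response, rt_window = NULL,
                                 params, spec = params$spec, stats = NULL,
                                 n_sims = 2e5, dt_sim = 0.001, t_max = 20) {
  if (n_sims < 1e4) stop("n_sims must be at least 1e4")
  if (is.null(params$d)) stop("bin bounds d required")
  gamma <- resolve_gamma(params, spec, stats)
  sp <- if (spec$drift_variability) params$sigma_phi else 0
  ev <- stimulus_evidence(stimulus)
  dt <- stimulus$frame_duration
  if (stimulus$condition == "interrogation") {
    D <- stimulus$planned_duration
    S <- cpp_evidence_integral(ev, dt, 0, D)
    phi <- 1 + sp * rnorm(n_sims)
    X <- phi * S + params$sigma_acc * sqrt(D) * rnorm(n_sims)
    keep <- response * X > 0
    X <- X[keep]; t_acc <- rep(D, length(X))
  } else {
    if (is.null(rt_window)) stop("rt_window required for free-response trials")
    b <- if (spec$collapsing_bound) params$b else 0
    path <- cpp_free_paths(ev, dt, as.integer(n_sims), sp, params$sigma_acc,
                           params$a, b, params$I, dt_sim, t_max)
    keep <- !path$censored & path$response == response &
      path$rt >= rt_window[1] & path$rt <= rt_window[2]
    X <- path$x_rt[keep]; t_acc <- path$rt[keep]
  }
  n_ret <- length(X)
  if (n_ret < 500)
    stop("fewer than 500 retained simulations (insufficient conditioning)")
  k <- 1 / (1 - gamma + gamma * t_acc)
  s <- response * k * X + params$sigma_m * rnorm(n_ret)
  bins <- bin_from_readout(s, params$d)
  freq <- tabulate(bins, 4) / n_ret
  lam <- params$lambda
  list(p = (1 - lam) * freq + lam / 4,
       se = (1 - lam) * sqrt(freq * (1 - freq) / n_ret),
       n_retained = n_ret)
}
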