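#' Evidence fluctuations for choice
#'
#' Per-frame dot counts centred on their generating means, expressed in the
#' direction of the choice: `(dots_chosen - mu_chosen) - (dots_unchosen -
#' mu_unchosen)`.  The halfway point cancels, leaving
#' `response * (dots_left - dots_right) - response * correct_side *
#' mean_separation`.
#'
#' @param dots_left,dots_right Integer per-frame dot counts.
#' @param response,correct_side `+1` / `-1`.
#' @param mean_separation Generating mean separation, dots.
#' @return Numeric vector of per-frame fluctuations (dots).
#' @export
evidence_fluctuations <- function(dots_left, dots_right, response,
                                  correct_side, mean_separation = 90) {
  response * (dots_left - dots_right) - response * correct_side * mean_separation
}

# frames wholly before the response (free response) or before stimulus
# offset (interrogation, where the stimulus has cleared before the response
# is permitted, so its final frames play the pipeline role)
n_whole_frames <- function(trials, frame_duration) {
  ifelse(trials$condition == "free_response",
         floor(trials$rt / frame_duration + 1e-9),
         trials$n_frames)
}

# list of per-trial fluctuation vectors, aligned to frame 0
fluctuation_list <- function(trials, frames, mean_separation = 90) {
  key_f <- paste(frames$participant, frames$trial, sep = "\r")
  ord <- order(frames$participant, frames$trial, frames$frame)
  frames <- frames[ord, ]
  key_f <- key_f[ord]
  fl <- split(data.frame(l = frames$dots_left, r = frames$dots_right),
              factor(key_f, levels = unique(key_f)))
  key_t <- paste(trials$participant, trials$trial, sep = "\r")
  idx <- match(key_t, names(fl))
  lapply(seq_len(nrow(trials)), function(i) {
    f <- fl[[idx[i]]]
    evidence_fluctuations(f$l, f$r, trials$response[i],
                          trials$correct_side[i], mean_separation)
  })
}

# trials x lags matrix of response-aligned fluctuations (lag 1 = final
# whole frame before the response), NA where a trial is too short
lagged_fluctuations <- function(trials, frames, frame_duration,
                                max_lag = 12, mean_separation = 90) {
  fl <- fluctuation_list(trials, frames, mean_separation)
  W <- n_whole_frames(trials, frame_duration)
  out <- matrix(NA_real_, nrow(trials), max_lag)
  for (i in seq_len(nrow(trials))) {
    w <- min(W[i], length(fl[[i]]))
    if (w < 1) next
    lags <- seq_len(min(max_lag, w))
    out[i, lags] <- fl[[i]][w - lags + 1]
  }
  out
}

#' Estimate the pipeline duration from the choice kernel
#'
#' Averages the evidence fluctuations for choice over the 12 frames
#' preceding responses (free-response trials) and fits a step function by
#' exhaustive search: an initial value over the early lags that drops to
#' zero at a lag between 1 and 10 frames before the response, minimizing
#' root-mean-square error.  The drop lag estimates the number of frames in
#' sensory and motor processing pipelines; ties are broken toward the
#' smallest drop lag.
#'
#' @param trials,frames Free-response trials of one participant with their
#'   frames table.
#' @param frame_duration Frame length, seconds.
#' @param mean_separation Generating separation, dots.
#' @return List with `n_pipeline_frames`, `initial_value` (dots),
#'   `rms_error`, and the 12-lag `kernel`.
#' @export
estimate_pipeline_frames <- function(trials, frames, frame_duration = 0.05,
                                     mean_separation = 90) {
  trials <- trials[trials$condition == "free_response", , drop = FALSE]
  if (nrow(trials) < 50) stop("need at least 50 free-response trials")
  lagm <- lagged_fluctuations(trials, frames, frame_duration, 12,
                              mean_separation)
  full <- complete.cases(lagm)
  if (!any(full)) stop("no trial has 12 whole frames before the response (insufficient data)")
  kernel <- colMeans(lagm[full, , drop = FALSE])  # index = lag
  best <- NULL
  for (drop_at in 1:10) {
    v <- mean(kernel[(drop_at + 1):12])
    pred <- c(rep(0, drop_at), rep(v, 12 - drop_at))
    rmse <- sqrt(mean((kernel - pred)^2))
    if (is.null(best) || rmse < best$rms_error - 1e-12)
      best <- list(n_pipeline_frames = drop_at, initial_value = v,
                   rms_error = rmse)
  }
  c(best, list(kernel = kernel))
}

#' Psychophysical kernels
#'
#' `choice_kernel()` gives the mean evidence fluctuation in the direction of
#' the choice at each frame lag; `confidence_kernel()` gives the rank
#' correlation (Kendall's tau, tie-corrected) between the fluctuation and
#' the confidence report.  Both are computed per participant and then
#' averaged with the SEM across participants; lags with fewer than 10
#' trials for a participant are dropped.
#'
#' @param trials,frames Trials and frames tables (any number of
#'   participants; compute per condition by subsetting beforehand).
#' @param frame_duration Frame length, seconds.
#' @param alignment `"response"` (lag 1 = final whole frame before the
#'   response / stimulus offset) or `"onset"` (lag 1 = first frame).
#' @param max_lag Number of lags.
#' @param mean_separation Generating separation, dots.
#' @param confidence Column name of the confidence measure for the
#'   confidence kernel.
#' @return List with `per_participant` (participant x lag matrix) and
#'   `summary` (lag, mean, sem, n).
#' @export
choice_kernel <- function(trials, frames, frame_duration = 0.05,
                          alignment = c("response", "onset"), max_lag = 12,
                          mean_separation = 90) {
  alignment <- match.arg(alignment)
  kernel_engine(trials, frames, frame_duration, alignment, max_lag,
                mean_separation, statistic = "mean")
}

#' @rdname choice_kernel
#' @export
confidence_kernel <- function(trials, frames, frame_duration = 0.05,
                              alignment = c("response", "onset"),
                              max_lag = 12, mean_separation = 90,
                              confidence = "confidence_raw") {
  alignment <- match.arg(alignment)
  kernel_engine(trials, frames, frame_duration, alignment, max_lag,
                mean_separation, statistic = "tau", conf_col = confidence)
}

kernel_engine <- function(trials, frames, frame_duration, alignment,
                          max_lag, mean_separation, statistic,
                          conf_col = NULL) {
  parts <- unique(trials$participant)
  per <- matrix(NA_real_, length(parts), max_lag,
                dimnames = list(parts, NULL))
  for (j in seq_along(parts)) {
    tp <- trials[trials$participant == parts[j], , drop = FALSE]
    fp <- frames[frames$participant == parts[j], , drop = FALSE]
    if (alignment == "response") {
      lagm <- lagged_fluctuations(tp, fp, frame_duration, max_lag,
                                  mean_separation)
    } else {
      fl <- fluctuation_list(tp, fp, mean_separation)
      W <- pmin(n_whole_frames(tp, frame_duration), lengths(fl))
      lagm <- matrix(NA_real_, nrow(tp), max_lag)
      for (i in seq_len(nrow(tp))) {
        idx <- seq_len(min(max_lag, W[i]))
        lagm[i, idx] <- fl[[i]][idx]
      }
    }
    for (l in seq_len(max_lag)) {
      ok <- !is.na(lagm[, l])
      if (sum(ok) < 10) next
      per[j, l] <- if (statistic == "mean") mean(lagm[ok, l])
      else {
        cf <- tp[[conf_col]][ok]
        if (length(unique(cf)) < 2) NA_real_
        else cor(lagm[ok, l], cf, method = "kendall")
      }
    }
  }
  n <- colSums(!is.na(per))
  m <- colMeans(per, na.rm = TRUE)
  s <- apply(per, 2, sd, na.rm = TRUE) / sqrt(pmax(n, 1))
  list(per_participant = per,
       summary = data.frame(lag = seq_len(max_lag), mean = m, sem = s,
                            n = n))
}

#' Goodman and Kruskal's gamma
#'
#' Rank correlation for ordinal pairs: `(concordant - discordant) /
#' (concordant + discordant)`, ties excluded.
#'
#' @param x,y Vectors of equal length (>= 2).
#' @return Gamma in `[-1, 1]`, or `NA` when there are no untied pairs.
#' @export
goodman_kruskal_gamma <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  tab <- table(x, y)
  r <- nrow(tab); cc <- ncol(tab)
  conc <- disc <- 0
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    n_ij <- tab[i, j]
    if (n_ij == 0) next
    if (i < r && j < cc)
      conc <- conc + n_ij * sum(tab[(i + 1):r, (j + 1):cc])
    if (i < r && j > 1)
      disc <- disc + n_ij * sum(tab[(i + 1):r, 1:(j - 1)])
  }
  if (conc + disc == 0) return(NA_real_)
  (conc - disc) / (conc + disc)
}

#' Equal-count quantile binning
#'
#' Bins values at their empirical quantiles (type 7, linear interpolation)
#' with approximately equal counts; tied values all go to the lower bin.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins.
#' @return Integer bin indices in `1..n_bins` (fewer when ties collapse
#'   bins; all-identical input yields a single bin with a warning).
#' @export
quantile_bin <- function(values, n_bins) {
  if (length(values) < n_bins) stop("need at least n_bins values")
  if (length(unique(values)) == 1) {
    warning("all values identical; single degenerate bin")
    return(rep(1L, length(values)))
  }
  br <- unique(quantile(values, seq(0, 1, length.out = n_bins + 1), type = 7))
  as.integer(cut(values, br, include.lowest = TRUE, right = TRUE))
}

#' Ordinal probit regression of binned confidence
#'
#' Maximum-likelihood cumulative-probit fit of an ordered outcome
#' (quantile-binned confidence) on a set of predictors, optionally z-scored
#' with the slopes back-transformed to raw units (`slope_raw = slope_z /
#' sd(predictor)`).
#'
#' @param outcome Ordinal outcome (integer codes or ordered factor).
#' @param predictors Data frame of numeric predictors.
#' @param z_score Standardize predictors before fitting.
#' @return List with `coef_z`, `coef_raw`, `intercepts` (`n_levels - 1`),
#'   `means`, `sds`, `converged`, `n`, and `condition_number` (2-norm, of
#'   the z-scored predictor matrix).
#' @export
ordinal_probit_fit <- function(outcome, predictors, z_score = TRUE) {
  stopifnot(is.data.frame(predictors), nrow(predictors) == length(outcome))
  means <- vapply(predictors, mean, 0)
  sds <- vapply(predictors, sd, 0)
  if (any(sds == 0)) stop("constant predictor")
  X <- if (z_score) as.data.frame(scale(predictors)) else predictors
  kappa2 <- kappa(as.matrix(scale(predictors)), exact = TRUE)
  yf <- factor(outcome, ordered = TRUE)
  if (nlevels(yf) == 2) {
    # two categories: the cumulative probit reduces to ordinary probit
    dat <- cbind(y = as.integer(yf) - 1L, X)
    fit <- tryCatch(stats::glm(y ~ ., data = dat,
                               family = stats::binomial("probit")),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(list(coef_z = NULL, coef_raw = NULL, intercepts = NULL,
                  means = means, sds = sds, converged = FALSE,
                  n = length(outcome), condition_number = kappa2))
    cz <- coef(fit)[-1]
    zeta <- c("1|2" = unname(-coef(fit)[1]))
  } else {
    dat <- cbind(y = yf, X)
    # polr's internal probit start fit routinely warns about fitted
    # probabilities of 0/1 on well-separated data; convergence is checked
    # explicitly below
    fit <- tryCatch(suppressWarnings(MASS::polr(y ~ ., data = dat,
                                                method = "probit")),
                    error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0)
      return(list(coef_z = NULL, coef_raw = NULL, intercepts = NULL,
                  means = means, sds = sds, converged = FALSE,
                  n = length(outcome), condition_number = kappa2))
    cz <- coef(fit)
    zeta <- fit$zeta
  }
  list(coef_z = cz,
       coef_raw = if (z_score) cz / sds[names(cz)] else cz,
       intercepts = zeta, means = means, sds = sds, converged = TRUE,
       n = length(outcome), condition_number = kappa2)
}

# per-trial predecision/pipeline raw-dot evidence sums given a pipeline
# estimate in frames
evidence_predictors <- function(trials, frames, n_pipe, frame_duration = 0.05,
                                mean_separation = 90) {
  fl <- fluctuation_list(trials, frames, mean_separation)
  W <- pmin(n_whole_frames(trials, frame_duration), lengths(fl))
  pre <- pipe <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    w <- W[i]
    p_lo <- max(w - n_pipe + 1, 1)
    pipe[i] <- if (w >= 1) sum(fl[[i]][p_lo:w]) else 0
    pre[i] <- if (p_lo > 1) sum(fl[[i]][1:(p_lo - 1)]) else 0
  }
  data.frame(rt = trials$rt, predecision = pre, pipeline = pipe,
             accuracy = as.integer(trials$response == trials$correct_side))
}

#' Apply the preregistered exclusion rules
#'
#' Trial level: drop trials without a confidence report and trials on which
#' the number of whole frames before the response is at most the
#' participant's pipeline estimate.  Participant level (evaluated per
#' condition on included trials; failing in either condition excludes the
#' participant): (a) accuracy below 60%; (b) any single raw confidence value
#' reported on more than 30% of trials; (c) any 5-quantile confidence bin
#' containing under 5% of trials; (d) fewer than 70 included trials; (e)
#' 2-norm condition number of the z-scored predictor matrix above 1000.
#'
#' @param trials,frames Trials and frames tables.
#' @param pipeline_estimates Named vector (participant -> frames).
#' @param frame_duration,mean_separation Task constants.
#' @return List with filtered `trials`, `frames`, the per-participant
#'   `report`, and `excluded` participant ids.
#' @export
apply_exclusions <- function(trials, frames, pipeline_estimates,
                             frame_duration = 0.05, mean_separation = 90) {
  keep <- !is.na(trials$confidence_bin)
  W <- n_whole_frames(trials, frame_duration)
  n_pipe <- pipeline_estimates[as.character(trials$participant)]
  keep <- keep & (W > n_pipe)
  tr <- trials[keep, , drop = FALSE]
  rep_rows <- list()
  excluded <- c()
  for (p in unique(trials$participant)) {
    for (cond in c("free_response", "interrogation")) {
      tp <- tr[tr$participant == p & tr$condition == cond, , drop = FALSE]
      n_inc <- nrow(tp)
      acc <- if (n_inc) mean(tp$response == tp$correct_side) else NA
      conf <- if ("confidence_raw" %in% names(tp) &&
                  !all(is.na(tp$confidence_raw))) tp$confidence_raw
              else tp$confidence_bin
      max_prop <- if (n_inc) max(table(conf)) / n_inc else NA
      min_bin_prop <- if (n_inc >= 5) {
        b <- quantile_bin(conf, 5)
        min(tabulate(b, max(b))) / n_inc
      } else NA
      cond_num <- if (n_inc >= 10) {
        fp <- frames[frames$participant == p, , drop = FALSE]
        pred <- evidence_predictors(tp, fp,
                                    unname(pipeline_estimates[as.character(p)]),
                                    frame_duration, mean_separation)
        ok <- vapply(pred, sd, 0) > 0
        if (all(ok)) kappa(as.matrix(scale(pred)), exact = TRUE) else Inf
      } else NA
      fails <- c(a = !is.na(acc) && acc < 0.60,
                 b = !is.na(max_prop) && max_prop > 0.30,
                 c = !is.na(min_bin_prop) && min_bin_prop < 0.05,
                 d = is.na(n_inc) || n_inc < 70,
                 e = !is.na(cond_num) && cond_num > 1000)
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        participant = p, condition = cond, n_included = n_inc,
        accuracy = acc, max_conf_prop = max_prop,
        min_bin_prop = min_bin_prop, condition_number = cond_num,
        excluded = any(fails),
        criteria = paste(names(fails)[fails], collapse = ""))
      if (any(fails)) excluded <- union(excluded, p)
    }
  }
  tr <- tr[!tr$participant %in% excluded, , drop = FALSE]
  list(trials = tr,
       frames = frames[frames$participant %in% unique(tr$participant), ,
                       drop = FALSE],
       report = do.call(rbind, rep_rows), excluded = excluded)
}

#' Per-participant, per-condition confidence regressions
#'
#' For each participant: estimate the pipeline duration from the
#' free-response choice kernel, build the trial-level predictors (response
#' time, predecision evidence, pipeline evidence, accuracy), quantile-bin
#' confidence into five categories per condition, and fit the ordinal
#' probit regression with z-scored predictors.
#'
#' @param trials,frames Trials and frames tables (post-exclusion).
#' @param pipeline_estimates Named vector (participant -> frames).
#' @param frame_duration,mean_separation Task constants.
#' @param confidence Column holding the (continuous) confidence report.
#' @return Data frame, one row per participant x condition, with the raw
#'   (back-transformed) coefficients and a convergence flag.
#' @export
participant_regressions <- function(trials, frames, pipeline_estimates,
                                    frame_duration = 0.05,
                                    mean_separation = 90,
                                    confidence = "confidence_raw") {
  rows <- list()
  for (p in unique(trials$participant)) {
    n_pipe <- unname(pipeline_estimates[as.character(p)])
    fp <- frames[frames$participant == p, , drop = FALSE]
    for (cond in c("free_response", "interrogation")) {
      tp <- trials[trials$participant == p & trials$condition == cond, ,
                   drop = FALSE]
      if (nrow(tp) < 30) next
      pred <- evidence_predictors(tp, fp, n_pipe, frame_duration,
                                  mean_separation)
      outcome <- quantile_bin(tp[[confidence]], 5)
      fit <- ordinal_probit_fit(outcome, pred, z_score = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, condition = cond, converged = fit$converged,
        rt = if (fit$converged) fit$coef_raw[["rt"]] else NA,
        predecision = if (fit$converged) fit$coef_raw[["predecision"]] else NA,
        pipeline = if (fit$converged) fit$coef_raw[["pipeline"]] else NA,
        accuracy = if (fit$converged) fit$coef_raw[["accuracy"]] else NA)
    }
  }
  do.call(rbind, rows)
}

cohens_d <- function(x) mean(x) / sd(x)

#' The four preregistered tests on the regression coefficients
#'
#' Test I: the free-response response-time coefficient is negative
#' (one-sample t, one-tailed).  Test II: it is more negative than the
#' interrogation response-time coefficient (paired, one-tailed).  Test III:
#' within free response, the predecision-evidence coefficient is smaller
#' than the pipeline-evidence coefficient (paired, one-tailed).  Test IV:
#' the predecision coefficient, baselined by the pipeline coefficient, is
#' smaller in free response than in interrogation (paired, one-tailed).
#' Effect sizes are the one-sample Cohen's d of the values under test.
#'
#' @param reg Output of [participant_regressions()].
#' @return Data frame with one row per test: `t`, `df`, `p` (one-tailed),
#'   `d`, and the number of participants used.
#' @export
run_preregistered_tests <- function(reg) {
  reg <- reg[reg$converged, , drop = FALSE]
  fr <- reg[reg$condition == "free_response", ]
  it <- reg[reg$condition == "interrogation", ]
  common <- intersect(fr$participant, it$participant)
  if (length(common) < 2) stop("need >= 2 participants with converged fits in both conditions")
  fr <- fr[match(common, fr$participant), ]
  it <- it[match(common, it$participant), ]
  one <- function(id, x) {
    tt <- t.test(x, alternative = "less")
    data.frame(test = id, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, d = cohens_d(x),
               n = length(x))
  }
  rbind(one("I", fr$rt),
        one("II", fr$rt - it$rt),
        one("III", fr$predecision - fr$pipeline),
        one("IV", (fr$predecision - fr$pipeline) -
                  (it$predecision - it$pipeline)))
}

#' Plot-ready equal-count binned summary
#'
#' Bins `x` per participant into equal-count bins; the summary x-location
#' is the across-participant mean of per-participant bin means, the
#' y-value the across-participant mean of per-bin y means, with SEM.
#'
#' @param x,y Numeric vectors.
#' @param participant Grouping vector.
#' @param n_bins Number of x bins.
#' @return Data frame: `bin`, `x`, `y`, `sem`, `n_participants`.
#' @export
binned_summary <- function(x, y, participant, n_bins = 6) {
  parts <- unique(participant)
  xs <- ys <- matrix(NA_real_, length(parts), n_bins)
  for (j in seq_along(parts)) {
    sel <- participant == parts[j]
    b <- quantile_bin(x[sel], n_bins)
    xs[j, seq_len(max(b))] <- tapply(x[sel], b, mean)
    ys[j, seq_len(max(b))] <- tapply(y[sel], b, mean)
  }
  n <- colSums(!is.na(ys))
  data.frame(bin = seq_len(n_bins), x = colMeans(xs, na.rm = TRUE),
             y = colMeans(ys, na.rm = TRUE),
             sem = apply(ys, 2, sd, na.rm = TRUE) / sqrt(pmax(n, 1)),
             n_participants = n)
}

#' Quantile probability summary of response times
#'
#' Per participant, condition and accuracy cell: the 0.1/0.3/0.5/0.7/0.9
#' response-time quantiles and the cell's response proportion within its
#' condition; then averaged across participants.
#'
#' @param trials Trials table.
#' @return Data frame: condition, accuracy, response proportion (x), the
#'   five mean quantiles, participants contributing, and a flag for cells
#'   with under 5 trials in any participant.
#' @export
quantile_probability_summary <- function(trials) {
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  trials$accuracy <- as.integer(trials$response == trials$correct_side)
  rows <- list()
  for (cond in unique(trials$condition)) for (acc in 0:1) {
    qs <- c(); pr <- c(); small <- FALSE
    for (p in unique(trials$participant)) {
      tc <- trials[trials$participant == p & trials$condition == cond, ]
      cell <- tc[tc$accuracy == acc, ]
      if (nrow(cell) == 0) next
      if (nrow(cell) < 5) small <- TRUE
      qs <- rbind(qs, quantile(cell$rt, probs, type = 7, names = FALSE))
      pr <- c(pr, nrow(cell) / nrow(tc))
    }
    if (is.null(qs)) next
    q_mean <- colMeans(qs)
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, accuracy = acc, prop = mean(pr),
      q10 = q_mean[1], q30 = q_mean[2], q50 = q_mean[3], q70 = q_mean[4],
      q90 = q_mean[5], n_participants = nrow(qs), small_cells = small)
  }
  do.call(rbind, rows)
}

#' Run the full model-free battery on a dataset
#'
#' Pipeline-duration estimation per participant, preregistered exclusions,
#' per-participant ordinal probit regressions, and Tests I-IV.
#'
#' @param dataset A `ddm_dataset` (or list with `trials` and `frames`).
#' @param frame_duration,mean_separation Task constants.
#' @return List: `pipeline` (per-participant estimates), `exclusions`,
#'   `regressions`, `tests`.
#' @export
analyze_dataset <- function(dataset, frame_duration = 0.05,
                            mean_separation = 90) {
  trials <- dataset$trials; frames <- dataset$frames
  parts <- unique(trials$participant)
  pipe <- vapply(parts, function(p) {
    estimate_pipeline_frames(trials[trials$participant == p, ],
                             frames[frames$participant == p, ],
                             frame_duration, mean_separation)$n_pipeline_frames
  }, 0)
  names(pipe) <- as.character(parts)
  exc <- apply_exclusions(trials, frames, pipe, frame_duration,
                          mean_separation)
  reg <- participant_regressions(exc$trials, exc$frames, pipe,
                                 frame_duration, mean_separation)
  tests <- run_preregistered_tests(reg)
  list(pipeline = pipe, exclusions = exc, regressions = reg, tests = tests)
}
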