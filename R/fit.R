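#' Fitting configuration
#'
#' Multi-start maximum-likelihood settings.  A single fit evaluates the
#' likelihood at `n_random_starts` random parameter sets, refines the best
#' by a bounded quasi-Newton search, and repeats the whole process
#' `n_repeats` times; the best repeat is kept and all repeat maxima are
#' retained for convergence heuristics.  The `"full"` profile matches the
#' reference procedure (200 starts, 40 repeats); `"fast"` (50 starts, 5
#' repeats) is the desk-scale profile used in tests and recovery studies.
#'
#' @param profile `"full"` or `"fast"`.
#' @param n_random_starts,n_repeats Override the profile's counts.
#' @param n_nodes Quadrature nodes for the interrogation likelihood.
#' @param rel_tol Relative convergence tolerance of the local optimizer.
#' @param iter_max Iteration cap of the local optimizer.
#' @return An object of class `ddm_fit_config`.
#' @export
fit_config <- function(profile = c("full", "fast"), n_random_starts = NULL,
                       n_repeats = NULL, n_nodes = 32, rel_tol = 1e-8,
                       iter_max = 200) {
  profile <- match.arg(profile)
  def <- if (profile == "full") c(200L, 40L) else c(50L, 5L)
  ns <- if (is.null(n_random_starts)) def[1] else as.integer(n_random_starts)
  nr <- if (is.null(n_repeats)) def[2] else as.integer(n_repeats)
  if (ns < 1 || nr < 1) stop("n_random_starts and n_repeats must be >= 1")
  structure(list(profile = profile, n_random_starts = ns, n_repeats = nr,
                 n_nodes = n_nodes, rel_tol = rel_tol, iter_max = iter_max),
            class = "ddm_fit_config")
}

# Transformed optimization space: scale parameters on the log scale and the
# bin bounds as (d1, log-increments) so ordering is enforced by construction.
theta_names <- function(spec) {
  nm <- c("log_sigma_acc", "sigma_m", "log_a", "I", "lambda",
          "d1", "log_inc2", "log_inc3")
  if (spec$drift_variability) nm <- c(nm, "sigma_phi")
  if (spec$collapsing_bound) nm <- c(nm, "b")
  if (spec$readout == "bayes_miscalibrated") nm <- c(nm, "Gamma")
  nm
}

theta_bounds <- function(spec, max_rt) {
  lower <- c(log(1e-2), 0, log(1), 0, 0, -1e3, log(1e-6), log(1e-6))
  upper <- c(log(1e3), 1e3, log(1e3), 1, 0.5, 1e3, log(1e3), log(1e3))
  if (spec$drift_variability) { lower <- c(lower, 0); upper <- c(upper, 3) }
  if (spec$collapsing_bound) {
    lower <- c(lower, 0); upper <- c(upper, 1e3 / max_rt)
  }
  if (spec$readout == "bayes_miscalibrated") {
    lower <- c(lower, -10); upper <- c(upper, 10)
  }
  list(lower = setNames(lower, theta_names(spec)),
       upper = setNames(upper, theta_names(spec)))
}

theta_to_natural <- function(theta, spec) {
  th <- setNames(as.numeric(theta), theta_names(spec))
  d1 <- th[["d1"]]
  d2 <- d1 + exp(th[["log_inc2"]])
  d3 <- d2 + exp(th[["log_inc3"]])
  v <- c(sigma_acc = exp(th[["log_sigma_acc"]]), sigma_m = th[["sigma_m"]],
         a = exp(th[["log_a"]]), I = th[["I"]], lambda = th[["lambda"]],
         d1 = d1, d2 = d2, d3 = d3)
  if (spec$drift_variability) v <- c(v, sigma_phi = th[["sigma_phi"]])
  if (spec$collapsing_bound) v <- c(v, b = th[["b"]])
  if (spec$readout == "bayes_miscalibrated") v <- c(v, Gamma = th[["Gamma"]])
  v
}

natural_to_theta <- function(v, spec) {
  th <- c(log_sigma_acc = log(v[["sigma_acc"]]), sigma_m = v[["sigma_m"]],
          log_a = log(v[["a"]]), I = v[["I"]], lambda = v[["lambda"]],
          d1 = v[["d1"]], log_inc2 = log(v[["d2"]] - v[["d1"]]),
          log_inc3 = log(v[["d3"]] - v[["d2"]]))
  if (spec$drift_variability) th <- c(th, sigma_phi = v[["sigma_phi"]])
  if (spec$collapsing_bound) th <- c(th, b = v[["b"]])
  if (spec$readout == "bayes_miscalibrated") th <- c(th, Gamma = v[["Gamma"]])
  unname(th[theta_names(spec)])
}

# 11-slot compiled-likelihood layout straight from theta (hot path)
theta_to_cpar <- function(theta, spec, stats) {
  d1 <- theta[6]; d2 <- d1 + exp(theta[7]); d3 <- d2 + exp(theta[8])
  i <- 9
  sphi <- 0; b <- 0; gamma <- 0
  if (spec$drift_variability) { sphi <- theta[i]; i <- i + 1 }
  if (spec$collapsing_bound) { b <- theta[i]; i <- i + 1 }
  sacc <- exp(theta[1])
  if (spec$readout == "bayes_miscalibrated") gamma <- plogis(theta[i])
  else if (spec$readout == "bayes_calibrated") {
    num <- sphi^2 * stats$mean_rate^2
    gamma <- if (num > 0) num / (num + sacc^2 + stats$stim_var) else 0
  }
  c(sacc, theta[2], exp(theta[3]), theta[4], theta[5], d1, d2, d3,
    sphi, b, gamma)
}

# random multi-start draws in theta space; scale parameters log-uniform
sample_starts <- function(spec, n, max_rt) {
  a_s <- exp(runif(n, log(30), log(900)))
  scale <- a_s
  th <- cbind(log_sigma_acc = runif(n, log(10), log(600)),
              sigma_m = exp(runif(n, log(0.5), log(300))),
              log_a = log(a_s),
              I = runif(n, 0, 1),
              lambda = runif(n, 0, 0.3),
              d1 = runif(n, -0.3, 0.6) * scale,
              log_inc2 = log(exp(runif(n, log(0.02), log(0.6))) * scale),
              log_inc3 = log(exp(runif(n, log(0.02), log(0.6))) * scale))
  if (spec$drift_variability) th <- cbind(th, sigma_phi = runif(n, 0, 1.5))
  if (spec$collapsing_bound)
    th <- cbind(th, b = runif(n, 0, 0.5) * a_s / max_rt)
  if (spec$readout == "bayes_miscalibrated")
    th <- cbind(th, Gamma = runif(n, -3, 3))
  th
}

make_objective <- function(encoded, spec, stats, n_nodes) {
  gl <- gl_rule(n_nodes)
  max_rt <- max(encoded$rt[encoded$cond == 0], 0)
  function(theta) {
    cpar <- theta_to_cpar(theta, spec, stats)
    # keep the collapsing bound positive over the observed decision times
    if (cpar[10] > 0 && cpar[3] - cpar[10] * max_rt <= 0) return(1e10)
    ll <- sum(cpp_trial_loglik(encoded$cond, encoded$R, encoded$t_acc,
                               encoded$rt, encoded$bin, encoded$offset,
                               encoded$nframes, encoded$frames, encoded$dt,
                               cpar, gl$nodes, gl$weights))
    if (!is.finite(ll)) 1e10 else -ll
  }
}

#' Fit a model variant by multi-start maximum likelihood
#'
#' @param encoded Encoded dataset from [encode_trials()] (one participant).
#' @param spec A `ddm_spec`.
#' @param config A [fit_config()].
#' @param stats A [task_stats()] (calibrated readouts use it).
#' @param min_trials Minimum number of confidence trials required.
#' @return An object of class `ddm_fit`: fitted `params`, `logLik`, `AIC`,
#'   `BIC`, `evidence` (`-BIC/2`), `n_trials`, `k`, and the per-repeat maxima
#'   in `repeats`.
#' @export
fit_model <- function(encoded, spec, config = fit_config("fast"),
                      stats = task_stats(), min_trials = 70) {
  n <- encoded$n
  if (n < min_trials)
    stop("fewer than ", min_trials, " confidence trials (degenerate data)")
  obj <- make_objective(encoded, spec, stats, config$n_nodes)
  max_rt <- max(encoded$rt[encoded$cond == 0], 1)
  bb <- theta_bounds(spec, max_rt)
  best <- NULL
  repeats <- data.frame(repeat_id = seq_len(config$n_repeats),
                        logLik = NA_real_, convergence = NA_integer_)
  for (r in seq_len(config$n_repeats)) {
    starts <- sample_starts(spec, config$n_random_starts, max_rt)
    vals <- apply(starts, 1, obj)
    if (all(!is.finite(vals) | vals >= 1e10))
      stop("all random starts gave a non-finite likelihood (degenerate data)")
    th0 <- starts[which.min(vals), ]
    opt <- nlminb(th0, obj, lower = bb$lower, upper = bb$upper,
                  control = list(rel.tol = config$rel_tol,
                                 iter.max = config$iter_max,
                                 eval.max = 4 * config$iter_max))
    repeats$logLik[r] <- -opt$objective
    repeats$convergence[r] <- opt$convergence
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  k <- length(param_names(spec))
  ll <- -best$objective
  params <- params_from_vector(theta_to_natural(best$par, spec), spec)
  structure(list(spec = spec, params = params, logLik = ll, n_trials = n,
                 k = k, AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll,
                 evidence = -(k * log(n) - 2 * ll) / 2,
                 repeats = repeats, config = config),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("ML fit, variant ", x$spec$name, ": logLik = ", signif(x$logLik, 6),
      " (n = ", x$n_trials, ", k = ", x$k, "), AIC = ", signif(x$AIC, 6),
      ", BIC = ", signif(x$BIC, 6), "\n", sep = "")
  invisible(x)
}

# subset an encoded dataset by trial index
subset_encoded <- function(encoded, idx) {
  frames <- lapply(idx, function(i)
    encoded$frames[encoded$offset[i] + seq_len(encoded$nframes[i])])
  nframes <- lengths(frames)
  list(cond = encoded$cond[idx], R = encoded$R[idx],
       t_acc = encoded$t_acc[idx], rt = encoded$rt[idx],
       bin = encoded$bin[idx],
       offset = as.integer(c(0L, cumsum(nframes))[seq_along(idx)]),
       nframes = as.integer(nframes),
       frames = unlist(frames, use.names = FALSE),
       dt = encoded$dt, n = length(idx),
       condition = encoded$condition[idx],
       participant = encoded$participant[idx])
}

# condition-stratified fold assignment
cv_folds <- function(encoded, k) {
  fold <- integer(encoded$n)
  for (cond in unique(encoded$condition)) {
    idx <- which(encoded$condition == cond)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Five-fold cross-validated model evaluation
#'
#' Random fold assignment stratified by condition; each fold is fitted on
#' the remaining trials and scored by the mean negative log likelihood per
#' held-out trial.  The mean across folds is the `-LLcv` used for model
#' comparison (lower is better).
#'
#' @inheritParams fit_model
#' @param k Number of folds.
#' @return An object of class `ddm_cv` with `fold_nll`, `mean_nll`, the
#'   fold assignment, and the per-fold fits.
#' @export
crossvalidate <- function(encoded, spec, config = fit_config("fast"),
                          stats = task_stats(), k = 5) {
  if (encoded$n < 10 * k) stop("too few trials for ", k, "-fold CV")
  fold <- cv_folds(encoded, k)
  fold_nll <- numeric(k)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    train <- subset_encoded(encoded, which(fold != f))
    test <- subset_encoded(encoded, which(fold == f))
    fit <- fit_model(train, spec, config, stats,
                     min_trials = min(70, train$n))
    fits[[f]] <- fit
    fold_nll[f] <- -dataset_log_likelihood(test, fit$params, spec, stats,
                                           config$n_nodes) / test$n
  }
  structure(list(fold_nll = fold_nll, mean_nll = mean(fold_nll),
                 folds = fold, fits = fits, spec = spec),
            class = "ddm_cv")
}

#' @export
print.ddm_cv <- function(x, ...) {
  cat(length(x$fold_nll), "-fold CV, variant ", x$spec$name,
      ": mean -LLcv per trial = ",
      signif(x$mean_nll, 6), "\n", sep = "")
  invisible(x)
}
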