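#' Fixed-effects model comparison from cross-validated likelihoods
#'
#' Identifies the model with the lowest mean `-LLcv` across participants and
#' reports, per model, the mean paired difference to that best model with a
#' bootstrap 95% confidence interval, plus per-participant best-model
#' counts.
#'
#' @param cv Numeric matrix of mean `-LLcv`, participants x models, with
#'   model names as column names.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @return An object of class `ddm_comparison`: `best_model`, `mean_nll`,
#'   `table` (model, mean difference, CI bounds, best counts).
#' @export
compare_fixed_effects <- function(cv, n_boot = 10000) {
  cv <- as.matrix(cv)
  if (is.null(colnames(cv))) stop("cv must have model names as column names")
  mean_nll <- colMeans(cv)
  best <- names(which.min(mean_nll))
  diffs <- cv - cv[, best]
  mean_diff <- colMeans(diffs)
  np <- nrow(cv)
  ci <- t(apply(diffs, 2, function(d) {
    bm <- colMeans(matrix(d[sample.int(np, np * n_boot, replace = TRUE)],
                          nrow = np))
    quantile(bm, c(0.025, 0.975), names = FALSE)
  }))
  counts <- table(factor(colnames(cv)[apply(cv, 1, which.min)],
                         levels = colnames(cv)))
  structure(list(best_model = best, mean_nll = mean_nll,
                 table = data.frame(model = colnames(cv),
                                    mean_diff = mean_diff,
                                    ci_lower = ci[, 1], ci_upper = ci[, 2],
                                    n_best = as.integer(counts),
                                    row.names = NULL)),
            class = "ddm_comparison")
}

#' @export
print.ddm_comparison <- function(x, ...) {
  cat("Fixed-effects comparison; best model:", x$best_model, "\n")
  print(x$table, digits = 4)
  invisible(x)
}

# one sweep of Dirichlet samples, returning frequencies
rdirichlet_mat <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants: a
#' Dirichlet prior over model frequencies is inverted by the standard
#' variational scheme (iterating participant-wise model responsibilities
#' `u_nk` proportional to `exp(evidence_nk + digamma(alpha_k) -
#' digamma(sum(alpha)))` and `alpha = prior + sum_n u_nk`).  Exceedance
#' probabilities (the probability a model is the most frequent in the
#' population) are estimated from Dirichlet samples.
#'
#' @param evidence Numeric matrix, participants x models, of log model
#'   evidence (here `-BIC/2`); model names as column names.  May include the
#'   prediction-duplicate variants `C` and `DC`.
#' @param prior_count Dirichlet prior count per model (1 = uniform prior).
#' @param n_samples Dirichlet samples for exceedance probabilities.
#' @param tol,max_iter Convergence controls of the variational iteration.
#' @return An object of class `ddm_bms`: `alpha`, `freq` (expected model
#'   frequencies), `xp` (exceedance probabilities), `u` (responsibilities).
#' @export
bms_random_effects <- function(evidence, prior_count = 1, n_samples = 1e5,
                               tol = 1e-8, max_iter = 500) {
  evidence <- as.matrix(evidence)
  if (any(!is.finite(evidence))) stop("evidence must be finite")
  K <- ncol(evidence)
  prior <- rep_len(prior_count, K)
  alpha <- prior
  for (it in seq_len(max_iter)) {
    lu <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    u <- exp(lu - apply(lu, 1, max))
    u <- u / rowSums(u)
    alpha_new <- prior + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  freq <- alpha / sum(alpha)
  r <- rdirichlet_mat(n_samples, alpha)
  xp <- tabulate(max.col(r), K) / n_samples
  names(freq) <- names(xp) <- names(alpha) <- colnames(evidence)
  structure(list(alpha = alpha, freq = freq, xp = xp, u = u,
                 prior = prior),
            class = "ddm_bms")
}

#' @export
print.ddm_bms <- function(x, ...) {
  cat("Random-effects model comparison\n")
  print(data.frame(model = names(x$freq), freq = round(x$freq, 3),
                   xp = round(x$xp, 3), row.names = NULL))
  invisible(x)
}

#' Family-level random-effects comparison
#'
#' Reruns the Dirichlet scheme with the prior mass spread uniformly over
#' model families (each model's prior count is `1 / family size`, so every
#' family carries equal prior weight), then aggregates frequencies and
#' exceedance probabilities within families.
#'
#' @param evidence As in [bms_random_effects()].
#' @param families Named list partitioning the model names into disjoint
#'   families.
#' @param n_samples Dirichlet samples for family exceedance.
#' @return List with `freq` and `xp` per family, plus the model-level `bms`.
#' @export
family_comparison <- function(evidence, families, n_samples = 1e5) {
  evidence <- as.matrix(evidence)
  models <- colnames(evidence)
  all_members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_members) || !setequal(all_members, models))
    stop("families must partition the model set (invalid partition)")
  prior <- setNames(numeric(length(models)), models)
  for (f in names(families)) prior[families[[f]]] <- 1 / length(families[[f]])
  bms <- bms_random_effects(evidence, prior_count = prior[models],
                            n_samples = n_samples)
  fam_of <- setNames(rep(names(families), lengths(families)), all_members)
  fam_id <- factor(fam_of[models], levels = names(families))
  freq <- setNames(as.numeric(tapply(bms$freq, fam_id, sum)),
                   names(families))
  r <- rdirichlet_mat(n_samples, bms$alpha)
  fam_r <- sapply(names(families),
                  function(f) rowSums(r[, models %in% families[[f]], drop = FALSE]))
  xp <- tabulate(max.col(fam_r), length(families)) / n_samples
  names(xp) <- names(families)
  list(freq = freq, xp = xp, bms = bms)
}

model_features <- function(name) {
  if (name == "0") character(0)
  else intersect(strsplit(name, "")[[1]], c("V", "D", "C", "M"))
}

#' Model recovery study
#'
#' Simulates data from each generating variant, fits every candidate variant
#' to the full data of each simulated participant, and tabulates the AIC and
#' BIC winners.  A recovery is feature-safe when the winner never contains a
#' feature (V/D/C/M) absent from the generator.
#'
#' @param generators Character vector of generating variant names.
#' @param candidates Character vector of candidate variant names.
#' @param n_participants Simulated participants per generator.
#' @param config A [task_config()]; use fewer blocks for desk-scale runs.
#' @param fit_cfg A [fit_config()].
#' @param stats A [task_stats()].
#' @return An object of class `ddm_recovery`: per-participant winners and a
#'   feature-confusion summary.
#' @export
model_recovery <- function(generators, candidates, n_participants = 6,
                           config = task_config(), fit_cfg = fit_config("fast"),
                           stats = task_stats()) {
  rows <- list()
  for (g in generators) {
    gspec <- model_spec(g)
    ds <- simulate_dataset(config, sample_participant_params(gspec, n_participants),
                           gspec)
    for (p in seq_len(n_participants)) {
      enc <- encode_trials(ds$trials[ds$trials$participant == p, ],
                           ds$frames[ds$frames$participant == p, ],
                           config$frame_duration)
      aic <- bic <- setNames(numeric(length(candidates)), candidates)
      for (m in candidates) {
        fit <- fit_model(enc, model_spec(m), fit_cfg, stats)
        aic[m] <- fit$AIC; bic[m] <- fit$BIC
      }
      rows[[length(rows) + 1]] <- data.frame(
        generator = g, participant = p,
        winner_aic = names(which.min(aic)),
        winner_bic = names(which.min(bic)))
    }
  }
  res <- do.call(rbind, rows)
  res$spurious_feature_bic <- mapply(function(g, w)
    length(setdiff(model_features(w), model_features(g))) > 0,
    res$generator, res$winner_bic)
  structure(list(results = res), class = "ddm_recovery")
}

#' @export
print.ddm_recovery <- function(x, ...) {
  print(table(x$results$generator, x$results$winner_bic))
  invisible(x)
}
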