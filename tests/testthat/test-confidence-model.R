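test_that("the miscalibration transform is the logistic map", {
  expect_equal(gamma_from_Gamma(0), 0.5)
  expect_equal(gamma_from_Gamma(2), 1 / (1 + exp(-2)))
  expect_lt(gamma_from_Gamma(-30), 1e-12)
  g <- gamma_from_Gamma(seq(-5, 5, 0.5))
  expect_true(all(diff(g) > 0))
})

test_that("calibrated observers without drift variability apply no time penalty", {
  spec <- model_spec("VC")
  p0 <- ddm_params(spec, 190, 30, 280, 0.3, 0.05, c(60, 110, 170),
                   sigma_phi = 0)
  expect_equal(calibrated_gamma(p0), 0)
  # gamma -> 1 as the other noise sources vanish
  p1 <- ddm_params(spec, 1e-6, 30, 280, 0.3, 0.05, c(60, 110, 170),
                   sigma_phi = 1)
  st <- structure(list(mean_rate = 90, stim_var = 1e-12,
                       frame_duration = 0.05), class = "ddm_task_stats")
  expect_gt(calibrated_gamma(p1, st), 1 - 1e-6)
  # increasing drift variability raises the penalty weight
  g <- sapply(c(0.1, 0.3, 0.6, 1), function(sp)
    calibrated_gamma(ddm_params(spec, 190, 30, 280, 0.3, 0.05,
                                c(60, 110, 170), sigma_phi = sp)))
  expect_true(all(diff(g) > 0))
})

test_that("the readout divides accumulated evidence by the time penalty", {
  specM <- model_spec("M"); spec0 <- model_spec("0")
  expect_equal(readout(4, 3, specM, gamma = 0.5), 2)
  expect_equal(readout(7.3, 11, specM, gamma = 0), 7.3)
  expect_equal(readout(7.3, 11, spec0), 7.3)
  expect_equal(readout(0, 5, specM, gamma = 0.9), 0)
  # monotone: decreasing in t for X > 0, gamma > 0; increasing in X
  ts <- seq(0.5, 6, 0.5)
  expect_true(all(diff(readout(5, ts, specM, gamma = 0.7)) < 0))
  xs <- seq(-5, 5, 0.5)
  expect_true(all(diff(readout(xs, 2, specM, gamma = 0.7)) > 0))
})

test_that("evidence splits at rt - I with fractional frame overlap", {
  diffs <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  st <- fixed_stimulus(diffs)
  ev <- split_evidence(st, rt = 0.5, I = 0.3)
  expect_equal(ev$t_dec, 0.2)
  expect_equal(ev$E_pre, 0.05 * sum(diffs[1:4]))
  expect_equal(ev$E_pipe, 0.05 * sum(diffs[5:10]))
  # I = 0: everything is predecision
  ev0 <- split_evidence(st, rt = 0.5, I = 0)
  expect_equal(ev0$E_pipe, 0)
  expect_equal(ev0$E_pre, 0.05 * sum(diffs))
  # a frame straddling t_dec contributes fractionally
  evf <- split_evidence(st, rt = 0.47, I = 0.3)
  expect_equal(evf$t_dec, 0.17)
  expect_equal(evf$E_pre, 0.05 * sum(diffs[1:3]) + 0.02 * diffs[4])
  expect_equal(evf$E_pipe, 0.03 * diffs[4] + 0.05 * sum(diffs[5:9]) +
                 0.02 * diffs[10])
  # rt <= I flags a certain lapse
  evl <- split_evidence(st, rt = 0.25, I = 0.3)
  expect_true(evl$lapse_certain)
  expect_equal(evl$E_pre, 0)
})

test_that("the drift-scaling posterior reduces to the prior without information", {
  spec <- model_spec("VM")
  p <- ddm_params(spec, 190, 30, 280, 0.3, 0.05, c(60, 110, 170),
                  sigma_phi = 0.5, Gamma = 1.4)
  post <- posterior_drift_scaling(0, 1, 280, p)
  expect_equal(post$mean, 1)
  expect_equal(post$variance, 0.25)
  p0 <- ddm_params(spec, 190, 30, 280, 0.3, 0.05, c(60, 110, 170),
                   sigma_phi = 0, Gamma = 1.4)
  post0 <- posterior_drift_scaling(100, 1, 280, p0)
  expect_equal(post0$mean, 1)
  expect_equal(post0$variance, 0)
  expect_error(posterior_drift_scaling(100, -0.1, 280, p), "t_dec")
})

test_that("the drift-scaling posterior matches path simulation at a crossing", {
  # paths crossing the upper bound near a fixed decision time; the endpoint
  # approximation ignores non-absorption, so agreement is close but not exact
  spec <- model_spec("V")
  sigma_phi <- 0.5; sigma_acc <- 190; a <- 280; I <- 0.3
  p <- ddm_params(spec, sigma_acc, 0, a, I, 0, c(60, 110, 170),
                  sigma_phi = sigma_phi)
  st <- fixed_stimulus(rep(90, 400))
  set.seed(201)
  paths <- ddmconf:::cpp_free_paths(stimulus_evidence(st), 0.05, 60000L,
                                    sigma_phi, sigma_acc, a, 0, I, 0.001, 18)
  t_target <- 1.5
  keep <- !paths$censored & paths$response == 1 &
    abs(paths$decision_time - t_target) < 0.05
  expect_gt(sum(keep), 500)
  phis <- paths$phi[keep]
  E_pre <- 90 * t_target
  post <- posterior_drift_scaling(E_pre, t_target, a, p)
  expect_lt(abs(mean(phis) - post$mean), 0.1)
  expect_lt(abs(sd(phis) - sqrt(post$variance)), 0.1)
})

test_that("the free-response final state has the stated degenerate limits", {
  # no pipeline evidence: the state sits at the crossing with variance
  # sigma_acc^2 I
  spec <- model_spec("VM")
  p <- ddm_params(spec, 190, 30, 280, 0.3, 0.05, c(60, 110, 170),
                  sigma_phi = 0.7, Gamma = 1.4)
  st <- fixed_stimulus(c(rep(80, 14), rep(0, 6)))  # nothing after t_dec
  fs <- final_state_free(st, 1, rt = 1.0, p)
  expect_equal(fs$mean, 280)
  expect_equal(fs$variance, 190^2 * 0.3)
  # core model with I = 0: a point mass exactly at the threshold
  spec0 <- model_spec("0")
  p0 <- ddm_params(spec0, 190, 30, 280, 0, 0.05, c(60, 110, 170))
  st2 <- fixed_stimulus(rep(80, 20))
  fs0 <- final_state_free(st2, -1, rt = 1.0, p0)
  expect_equal(fs0$mean, -280)
  expect_equal(fs0$variance, 0)
  # collapsing bound enters through the crossing value
  specD <- model_spec("DM")
  pD <- ddm_params(specD, 190, 30, 280, 0.3, 0.05, c(60, 110, 170),
                   b = 50, Gamma = 1.4)
  fsD <- final_state_free(st, 1, rt = 1.0, pD)
  expect_equal(fsD$mean, 280 - 50 * 0.7)
  expect_error(final_state_free(st2, 1, rt = 1.0,
                                ddm_params(specD, 190, 30, 20, 0.3, 0.05,
                                           c(60, 110, 170), b = 50,
                                           Gamma = 1.4)),
               "degenerate")
})

test_that("the interrogation final state is Gaussian around the summed evidence", {
  spec <- model_spec("0")
  p <- ddm_params(spec, 190, 30, 280, 0.3, 0.05, c(60, 110, 170))
  st <- fixed_stimulus(rep(60, 16), condition = "interrogation")
  fs <- final_state_interrogation(st, p)
  expect_equal(fs$mean, 60 * 0.8)
  expect_equal(fs$variance, 190^2 * 0.8)
  specV <- model_spec("VM")
  pV <- ddm_params(specV, 190, 30, 280, 0.3, 0.05, c(60, 110, 170),
                   sigma_phi = 0.5, Gamma = 1.4)
  fsV <- final_state_interrogation(st, pV)
  expect_equal(fsV$variance, 0.25 * 48^2 + 190^2 * 0.8)
})

test_that("bin probabilities are exactly uniform under certain lapses", {
  p <- params_for("M")
  p$lambda <- 1
  st <- fixed_stimulus(rep(90, 30))
  tr <- behavioral_trial(st, 1, rt = 1.2, confidence_bin = 2)
  pr <- confidence_bin_probabilities(tr, p)
  expect_equal(pr$p, rep(0.25, 4))
  expect_equal(trial_log_likelihood(tr, p), log(0.25))
  # free-response rt <= I: certain lapse even at lambda < 1
  p2 <- params_for("M")
  tr2 <- behavioral_trial(st, 1, rt = 0.2)
  pr2 <- confidence_bin_probabilities(tr2, p2)
  expect_equal(pr2$p, rep(0.25, 4))
  expect_equal(pr2$lapse_component, 1)
})

test_that("bin probabilities normalize to one across conditions and variants", {
  set.seed(202)
  cfg <- task_config()
  for (name in c("0", "VD", "DM", "VM", "VDC")) {
    p <- params_for(name)
    for (i in 1:6) {
      if (i %% 2 == 0) {
        st <- sample_stimulus(cfg, "interrogation", sample(c(1, -1), 1),
                              runif(1, 0.3, 2.5))
        tr <- behavioral_trial(st, sample(c(1, -1), 1),
                               st$planned_duration + 0.4)
      } else {
        st <- sample_stimulus(cfg, "free_response", sample(c(1, -1), 1), 4)
        tr <- behavioral_trial(st, sample(c(1, -1), 1), runif(1, 0.5, 3.5))
      }
      pr <- confidence_bin_probabilities(tr, p)
      expect_true(all(pr$p >= 0))
      expect_lt(abs(sum(pr$p) - 1), 1e-10)
    }
  }
})

test_that("interrogation bin masses agree with an independent quadrature", {
  p <- params_for("VM")
  st <- fixed_stimulus(rep(70, 24), condition = "interrogation")
  for (resp in c(1, -1)) {
    tr <- behavioral_trial(st, resp, st$planned_duration + 0.3)
    fs <- final_state_interrogation(st, p)
    gam <- gamma_from_Gamma(p$Gamma)
    k <- 1 / (1 - gam + gam * st$planned_duration)
    muW <- resp * fs$mean; sdW <- sqrt(fs$variance)
    d4 <- c(-Inf, p$d, Inf)
    Z <- integrate(function(w) dnorm(w, muW, sdW), 0, Inf,
                   rel.tol = 1e-12)$value
    ref <- sapply(1:4, function(i) integrate(function(w)
      dnorm(w, muW, sdW) * (pnorm((d4[i + 1] - k * w) / p$sigma_m) -
                              pnorm((d4[i] - k * w) / p$sigma_m)),
      0, Inf, rel.tol = 1e-12)$value / Z)
    ref <- (1 - p$lambda) * ref + p$lambda / 4
    got <- confidence_bin_probabilities(tr, p)$p
    expect_lt(max(abs(got - ref)), 1e-8)
  }
})

test_that("metacognitive-noise-free readouts use half-open bins", {
  # core model, I = 0, sigma_m = 0: the free-response readout is a point
  # mass exactly at the threshold; with d2 = a it must fall in bin 3,
  # i.e. bins are half-open [d_i, d_{i+1})
  pd <- ddm_params(model_spec("0"), 190, 0, 110, 0, 0, d = c(60, 110, 170))
  st <- fixed_stimulus(rep(90, 30))
  tr <- behavioral_trial(st, 1, 1.0)
  pr <- confidence_bin_probabilities(tr, pd)
  expect_equal(pr$p, c(0, 0, 1, 0))
})

test_that("calibrated variants duplicate their non-Bayesian twins exactly", {
  set.seed(203)
  cfg <- small_config()
  ds <- simulate_dataset(cfg, default_params(model_spec("M")),
                         model_spec("M"), seed = 31)
  enc <- encode_trials(ds$trials, ds$frames, cfg$frame_duration)
  d <- ds$participants[[1]]$params$d
  p0 <- ddm_params(model_spec("0"), 190, 30, 280, 0.3, 0.05, d)
  pC <- ddm_params(model_spec("C"), 190, 30, 280, 0.3, 0.05, d)
  expect_identical(dataset_log_likelihood(enc, p0),
                   dataset_log_likelihood(enc, pC))
  pD <- ddm_params(model_spec("D"), 190, 30, 280, 0.3, 0.05, d, b = 20)
  pDC <- ddm_params(model_spec("DC"), 190, 30, 280, 0.3, 0.05, d, b = 20)
  expect_identical(dataset_log_likelihood(enc, pD),
                   dataset_log_likelihood(enc, pDC))
})

test_that("the trial log likelihood is floored and sums over trials", {
  p <- params_for("M")
  st <- fixed_stimulus(rep(90, 30))
  # absurd readout far outside all bins still scores at least log(lambda/4)
  tr <- behavioral_trial(st, 1, rt = 1.2, confidence_bin = 1)
  expect_gte(trial_log_likelihood(tr, p), log(p$lambda / 4))
  set.seed(204)
  cfg <- small_config()
  ds <- simulate_dataset(cfg, default_params(model_spec("M")),
                         model_spec("M"), seed = 32)
  enc <- encode_trials(ds$trials, ds$frames, cfg$frame_duration)
  pt <- ds$participants[[1]]$params
  per <- dataset_log_likelihood(enc, pt, per_trial = TRUE)
  expect_equal(sum(per), dataset_log_likelihood(enc, pt))
  expect_true(all(is.finite(per)))
})
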