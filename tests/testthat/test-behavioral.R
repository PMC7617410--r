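# synthetic trials/frames tables with exact control over the per-frame
# fluctuations: response = 1, correct_side = 1, so fluctuation = diff - 90
make_table_trials <- function(n_trials, diffs_fun, rt = 0.85,
                              participant = 1, condition = "free_response",
                              confidence = NULL, accuracy = NULL) {
  n_frames <- length(diffs_fun(1))
  trials <- data.frame(participant = participant,
                       trial = seq_len(n_trials) + 1000 * participant,
                       condition = condition, correct_side = 1,
                       response = 1, rt = rt,
                       stimulus_duration = if (condition == "interrogation")
                         n_frames * 0.05 else rt,
                       n_frames = n_frames,
                       confidence_bin = 2L,
                       confidence_raw = if (is.null(confidence))
                         runif(n_trials) else confidence)
  if (!is.null(accuracy)) trials$response <- ifelse(accuracy, 1, -1)
  frames <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    d <- diffs_fun(i)
    data.frame(participant = participant, trial = trials$trial[i],
               frame = seq_along(d) - 1L,
               dots_left = as.integer(1000 + d / 2),
               dots_right = as.integer(1000 - d / 2))
  }))
  list(trials = trials, frames = frames)
}

test_that("evidence fluctuations are centred on the generating means", {
  # a frame exactly at both means fluctuates by zero
  expect_equal(evidence_fluctuations(1045, 955, 1, 1), 0)
  expect_equal(evidence_fluctuations(1045, 955, -1, 1), 0)
  # centring removes the 90-dot signal regardless of the choice
  expect_equal(evidence_fluctuations(1060, 950, 1, 1), 20)
  expect_equal(evidence_fluctuations(1060, 950, -1, 1), -20)
  expect_equal(evidence_fluctuations(1000, 1000, 1, -1), 90)
})

test_that("the step estimator recovers a noiseless pipeline exactly", {
  # fluctuation 4 dots at lags 12..7, 0 at lags 6..1 (17 whole frames)
  diffs_fun <- function(i) {
    d <- rep(90, 17)
    d[6:11] <- 94  # frame indices 6..11 are lags 12..7
    d
  }
  tab <- make_table_trials(60, diffs_fun)
  est <- estimate_pipeline_frames(tab$trials, tab$frames)
  expect_equal(est$n_pipeline_frames, 6)
  expect_equal(est$initial_value, 4)
  expect_equal(est$rms_error, 0)
  expect_equal(est$kernel, c(rep(0, 6), rep(4, 6)), ignore_attr = TRUE)
})

test_that("an all-zero kernel ties toward the smallest drop lag", {
  tab <- make_table_trials(60, function(i) rep(90, 17))
  est <- estimate_pipeline_frames(tab$trials, tab$frames)
  expect_equal(est$n_pipeline_frames, 1)
  expect_error(estimate_pipeline_frames(tab$trials[1:10, ], tab$frames),
               "at least 50")
})

test_that("Goodman-Kruskal gamma matches brute-force pair counting", {
  expect_equal(goodman_kruskal_gamma(c(1, 2), c(0, 1)), 1)
  expect_equal(goodman_kruskal_gamma(c(2, 1), c(0, 1)), -1)
  expect_true(is.na(goodman_kruskal_gamma(c(1, 1, 1), c(0, 1, 0))))
  brute <- function(x, y) {
    conc <- disc <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) {
      if (i >= j) next
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    if (conc + disc == 0) NA_real_ else (conc - disc) / (conc + disc)
  }
  set.seed(301)
  for (rep in 1:5) {
    x <- sample(1:4, 50, replace = TRUE)
    y <- sample(0:1, 50, replace = TRUE)
    g <- goodman_kruskal_gamma(x, y)
    expect_identical(g, brute(x, y))
    expect_true(is.na(g) || (g >= -1 && g <= 1))
  }
})

test_that("quantile binning gives equal counts and sends ties down", {
  set.seed(302)
  x <- sample(rnorm(100))  # distinct
  b <- quantile_bin(x, 4)
  expect_equal(unname(table(b)), rep(25L, 4), ignore_attr = TRUE)
  # brute-force assignment oracle under heavy ties
  brute_bin <- function(v, n_bins) {
    br <- unique(quantile(v, seq(0, 1, length.out = n_bins + 1), type = 7))
    vapply(v, function(vi) {
      b <- 1L
      for (j in seq_len(length(br) - 1)) if (vi > br[j + 1]) b <- j + 1L
      b
    }, 0L)
  }
  y <- sample(rep(c(1, 2, 2, 2, 3, 7, 7, 9), 20))
  expect_equal(quantile_bin(y, 5), brute_bin(y, 5))
  expect_warning(quantile_bin(rep(3, 10), 2), "identical")
})

test_that("binary ordinal probit reduces to ordinary probit regression", {
  set.seed(303)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, pnorm(-0.3 + 0.8 * x1 - 0.5 * x2)) + 1
  fit <- ordinal_probit_fit(y, data.frame(x1 = x1, x2 = x2), z_score = FALSE)
  ref <- glm(I(y - 1) ~ x1 + x2, family = binomial("probit"))
  expect_true(fit$converged)
  expect_equal(unname(fit$coef_raw), unname(coef(ref)[2:3]), tolerance = 1e-3)
  expect_equal(unname(-fit$intercepts), unname(coef(ref)[1]), tolerance = 1e-3)
})

test_that("the cumulative-probit fit recovers a known generator", {
  set.seed(304)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 0.9 * x1 - 0.4 * x2 + rnorm(n)
  y <- findInterval(eta, qnorm(c(0.2, 0.4, 0.6, 0.8)) * sd(eta)) + 1
  fit <- ordinal_probit_fit(y, data.frame(x1 = x1, x2 = x2))
  expect_true(fit$converged)
  # slopes recovered up to the probit scale factor; check ratio and signs
  expect_equal(unname(fit$coef_z[1] / fit$coef_z[2]), 0.9 / -0.4,
               tolerance = 0.15)
  expect_gt(fit$coef_z[[1]], 0)
  expect_lt(fit$coef_z[[2]], 0)
  # null predictors carry no slope
  y0 <- sample(y)
  fit0 <- ordinal_probit_fit(y0, data.frame(x1 = x1, x2 = x2))
  expect_lt(max(abs(fit0$coef_z)), 4 * 1.5 / sqrt(n))
})

test_that("back-transformed slopes equal the un-z-scored refit", {
  set.seed(305)
  n <- 1500
  x1 <- rnorm(n, 5, 40); x2 <- rnorm(n, -2, 0.3)
  eta <- 0.02 * x1 + 1.5 * x2 + rnorm(n)
  y <- findInterval(eta, quantile(eta, c(0.25, 0.5, 0.75))) + 1
  fz <- ordinal_probit_fit(y, data.frame(x1 = x1, x2 = x2), z_score = TRUE)
  fr <- ordinal_probit_fit(y, data.frame(x1 = x1, x2 = x2), z_score = FALSE)
  expect_equal(unname(fz$coef_raw), unname(fr$coef_raw), tolerance = 1e-3)
})

test_that("exclusion rules fire at their preregistered boundaries", {
  set.seed(306)
  mk <- function(participant, accuracy_rate, n_per_cond = 100) {
    out <- list()
    for (cond in c("free_response", "interrogation")) {
      acc <- rep(c(TRUE, FALSE),
                 c(round(accuracy_rate * n_per_cond),
                   n_per_cond - round(accuracy_rate * n_per_cond)))
      tab <- make_table_trials(n_per_cond,
                               function(i) as.integer(90 + round(rnorm(17, 0, 40))),
                               rt = runif(n_per_cond, 0.71, 0.849),
                               participant = participant, condition = cond,
                               confidence = rnorm(n_per_cond),
                               accuracy = sample(acc))
      out[[cond]] <- tab
    }
    list(trials = rbind(out[[1]]$trials, out[[2]]$trials),
         frames = rbind(out[[1]]$frames, out[[2]]$frames))
  }
  good <- mk(1, 0.75)
  bad_acc <- mk(2, 0.59)
  trials <- rbind(good$trials, bad_acc$trials)
  frames <- rbind(good$frames, bad_acc$frames)
  pipe <- c("1" = 6, "2" = 6)
  exc <- apply_exclusions(trials, frames, pipe)
  expect_true(2 %in% exc$excluded)
  expect_false(1 %in% exc$excluded)
  rep2 <- exc$report[exc$report$participant == 2 & exc$report$excluded, ]
  expect_true(all(grepl("a", rep2$criteria)))
  # boundary of rule (d): 71 included trials per condition are retained
  brd <- mk(3, 0.8, n_per_cond = 71)
  exc2 <- apply_exclusions(brd$trials, brd$frames, c("3" = 6))
  expect_false(3 %in% exc2$excluded)
  brd2 <- mk(4, 0.8, n_per_cond = 69)
  exc3 <- apply_exclusions(brd2$trials, brd2$frames, c("4" = 6))
  expect_true(4 %in% exc3$excluded)
})

test_that("kernels vanish for flat stimuli and constant confidence", {
  tab <- make_table_trials(40, function(i) rep(90, 17),
                           confidence = rep(1.5, 40))
  ck <- choice_kernel(tab$trials, tab$frames)
  expect_true(all(ck$summary$mean[ck$summary$n > 0] == 0))
  fk <- confidence_kernel(tab$trials, tab$frames)
  expect_true(all(is.na(fk$per_participant)))
})

test_that("kernel and regression outputs are invariant to trial order", {
  set.seed(307)
  cfg <- small_config(n_blocks = 2, trials_per_block = 30)
  ds <- simulate_dataset(cfg, default_params(model_spec("M")),
                         model_spec("M"), seed = 61)
  perm <- sample(nrow(ds$trials))
  tr2 <- ds$trials[perm, ]
  ck1 <- choice_kernel(ds$trials, ds$frames)
  ck2 <- choice_kernel(tr2, ds$frames)
  expect_equal(ck1$summary, ck2$summary)
})

test_that("binned summaries follow the per-participant averaging rule", {
  x <- c(1:10, 1:10)
  y <- c(2 * (1:10), 2 * (1:10))
  part <- rep(1:2, each = 10)
  bs <- binned_summary(x, y, part, n_bins = 5)
  expect_equal(bs$x, c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_equal(bs$y, 2 * bs$x)
  expect_equal(bs$sem, rep(0, 5))  # identical participants
  one <- binned_summary(1:10, (1:10)^2, rep(1, 10), n_bins = 5)
  expect_equal(one$x, tapply(1:10, rep(1:5, each = 2), mean),
               ignore_attr = TRUE)
})

test_that("quantile probability summaries match a sort-based oracle", {
  set.seed(308)
  trials <- data.frame(participant = 1, trial = 1:200,
                       condition = "free_response", correct_side = 1,
                       response = sample(c(1, -1), 200, TRUE,
                                         prob = c(0.8, 0.2)),
                       rt = rlnorm(200, 0, 0.4))
  qp <- quantile_probability_summary(trials)
  cor_rt <- sort(trials$rt[trials$response == 1])
  # type-7 quantile oracle by direct interpolation
  q7 <- function(v, p) {
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[pmin(lo + 1, length(v))] - v[lo])
  }
  row <- qp[qp$accuracy == 1, ]
  expect_equal(unname(unlist(row[c("q10", "q30", "q50", "q70", "q90")])),
               q7(cor_rt, c(0.1, 0.3, 0.5, 0.7, 0.9)), tolerance = 1e-12)
  expect_equal(row$prop, mean(trials$response == 1))
  # degenerate: all RTs equal gives five identical quantiles
  trials$rt <- 1.25
  qp2 <- quantile_probability_summary(trials)
  expect_true(all(qp2[, c("q10", "q30", "q50", "q70", "q90")] == 1.25))
})
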