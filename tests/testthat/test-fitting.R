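test_that("simulated subjects are model predictions plus decision noise", {
  task <- small_task(seed = 51)
  pred <- task_predictions("node2", c(0.2, 0.9, 0.4), task)

  s0 <- simulate_subject("node2", c(0.2, 0.9, 0.4), task, sigma_n = 0,
                         seed = 1)
  expect_equal(s0$prediction, pred, tolerance = 1e-12)

  s5 <- simulate_subject("node2", c(0.2, 0.9, 0.4), task, sigma_n = 5,
                         seed = 2)
  s15 <- simulate_subject("node2", c(0.2, 0.9, 0.4), task, sigma_n = 15,
                          seed = 2)
  expect_gt(mean(abs(s15$prediction - pred)),
            mean(abs(s5$prediction - pred)))
  expect_true(all(s15$prediction >= 0 & s15$prediction <= 300))

  # residuals are consistent with the Gaussian noise model
  big <- generate_task(task_config(n_trials = 500), 1, seed = 53)
  sb <- simulate_subject("node1", 0.7, big, sigma_n = 6, seed = 3)
  resid <- sb$prediction - task_predictions("node1", 0.7, big)
  ks <- stats::ks.test(resid, "pnorm", 0, 6)
  expect_gt(ks$p.value, 0.01)
})

test_that("model predictions never condition on the subject's reports", {
  task <- small_task(seed = 55)
  s1 <- simulate_subject("full", 0.1, task, sigma_n = 8, seed = 4)
  s2 <- s1
  s2$prediction <- rev(s2$prediction)   # mangle the reports
  expect_identical(task_predictions("full", 0.1, s1),
                   task_predictions("full", 0.1, s2))
})

test_that("log likelihood matches its closed forms", {
  task <- small_task(seed = 57)
  pred <- task_predictions("node1", 0.6, task)
  subj <- task
  subj$prediction <- pred

  # zero residuals: logL = -T log(sigma_n sqrt(2 pi))
  T <- nrow(subj)
  for (s in c(2, 7)) {
    expect_equal(subject_loglik("node1", 0.6, s, subj),
                 -T * log(s * sqrt(2 * pi)), tolerance = 1e-10)
  }

  # profiled noise maximizes the likelihood at the residual RMS
  subj$prediction <- pred + rnorm(T, 0, 4)
  rms <- sqrt(mean((subj$prediction - pred)^2))
  ll_at <- function(s) subject_loglik("node1", 0.6, s, subj)
  expect_gt(ll_at(rms), ll_at(rms * 0.8))
  expect_gt(ll_at(rms), ll_at(rms * 1.25))
  prof <- deltamix:::profiled_loglik(pred, subj$prediction)
  expect_equal(prof$sigma_n, rms, tolerance = 1e-12)
  expect_equal(prof$logL, ll_at(rms), tolerance = 1e-8)
})

test_that("the one-node likelihood surface matches a brute-force grid", {
  task <- small_task(seed = 59)
  subj <- simulate_subject("node1", 0.55, task, sigma_n = 6, seed = 5)
  alphas <- seq(0.2, 0.95, by = 0.05)
  noises <- c(4, 6, 9)
  grid_ll <- outer(alphas, noises, Vectorize(function(a, s) {
    pred <- delta_rule_predictions_task(a, subj)
    sum(stats::dnorm(subj$prediction, pred, s, log = TRUE))
  }))
  pkg_ll <- outer(alphas, noises, Vectorize(function(a, s) {
    subject_loglik("node1", a, s, subj)
  }))
  expect_equal(pkg_ll, grid_ll, tolerance = 1e-8)

  fit <- fit_subject("node1", subj)
  expect_gte(max(pkg_ll), max(pkg_ll) - 1e-9)
  expect_gt(fit$logL, max(pkg_ll) - 1e-6)  # MLE at least as good as grid
})

test_that("fits recover generating parameters on single subjects", {
  task <- generate_task(task_config(), 2, seed = 61)   # 400 trials

  subj <- simulate_subject("node1", 0.65, task, sigma_n = 6, seed = 6)
  fit <- fit_subject("node1", subj)
  expect_lt(abs(fit$params[["alpha1"]] - 0.65), 0.05)
  expect_lt(abs(fit$params[["sigma_n"]] - 6), 1.5)
  expect_equal(fit$k, 2L)
  expect_equal(fit$bic, -2 * fit$logL + 2 * log(400), tolerance = 1e-10)

  subj <- simulate_subject("full", 0.12, task, sigma_n = 7, seed = 7)
  fit <- fit_subject("full", subj)
  expect_lt(abs(fit$params[["h"]] - 0.12), 0.08)
  expect_equal(fit$k, 2L)
})

test_that("BIC penalizes parameters that do not earn their keep", {
  task <- generate_task(task_config(), 2, seed = 63)
  subj <- simulate_subject("node1", 0.7, task, sigma_n = 6, seed = 8)
  f1 <- fit_subject("node1", subj)
  f2 <- fit_subject("node2", subj, n_starts = 4)
  expect_gte(f2$logL, f1$logL - 0.5)   # larger model fits at least as well
  expect_lt(f1$bic, f2$bic)            # but BIC prefers the generator
})

test_that("group model selection behaves at its fixed points", {
  # identical evidence: everything uniform
  lme <- matrix(-100, 6, 2)
  res <- group_bms(lme, seed = 1)
  expect_equal(res$model_prob, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(sum(res$exceedance), 1, tolerance = 1e-12)
  expect_equal(res$exceedance[1], 0.5, tolerance = 0.02)

  # one model dominating by 10 log units for every subject
  lme <- cbind(rep(0, 8), rep(-10, 8), rep(-12, 8))
  res <- group_bms(lme, seed = 2)
  expect_gt(res$model_prob[1], 0.8)
  expect_gt(res$exceedance[1], 0.99)
  expect_equal(sum(res$model_prob), 1, tolerance = 1e-12)
  expect_equal(rowSums(res$per_subject), rep(1, 8), tolerance = 1e-12)
  expect_error(group_bms(lme[1, , drop = FALSE]), "at least 2")
})

test_that("parameter pools cover each model's free parameters", {
  for (id in c("full", "node1", "node2", "node3")) {
    p <- sample_task_params(id, 5, seed = 3)
    info <- deltamix:::model_par_info(id)
    expect_setequal(names(p), c(info$names, "sigma_n"))
    expect_true(all(p$sigma_n > 0))
    if (id %in% c("node2", "node3")) {
      a <- as.matrix(p[, grep("alpha", names(p))])
      expect_true(all(diff(t(a)) < 0))   # rates ordered fast to slow
    }
  }
  expect_error(sample_task_params("bogus"), "unknown model")
})
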