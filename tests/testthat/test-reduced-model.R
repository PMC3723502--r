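test_that("a single node is exactly a plain Delta rule", {
  set.seed(2)
  x <- rnorm(500, 10, 2)
  nu0 <- 1e-9
  m <- reduced_model(ef_gaussian_mean(2), 0, nu0, h = 0.3, nodes = 4)
  fr <- filter_run(m, x)
  ref <- delta_rule_predictions(x, 1 / (4 + nu0), mu0 = 0)
  expect_equal(fr$pred_mean, ref, tolerance = 1e-14)
  expect_true(all(abs(attr(filter_run(reduced_model(
    ef_gaussian_mean(2), 0, nu0, 0.3, 4), x, keep_weights = TRUE),
    "weights") - 1) < 1e-15))
})

test_that("two nodes match the hand-coded explicit recursion", {
  set.seed(4)
  ds <- sample_dataset(ef_gaussian_mean(0.5), 0, 0.25, 0.1, T = 1000,
                       seed = 44)
  l1 <- 2; l2 <- 12; chi0 <- 0; nu0 <- 0.25; h <- 0.1
  ref <- two_node_reference(ds$x, 0.5, h, l1, l2, chi0, nu0)
  m <- reduced_model(ef_gaussian_mean(0.5), chi0, nu0, h, c(l1, l2))
  for (t in seq_len(nrow(ds))) {
    m <- step_obs(m, ds$x[t])
    expect_lt(max(abs(model_weights(m) - ref[t, c("w1", "w2")])), 1e-12)
    expect_lt(max(abs(node_means(m) - ref[t, c("mu1", "mu2")])), 1e-12)
  }
})

test_that("transition prior matches the unit-growth construction", {
  tp <- transition_prior(node_set(c(1, 2)), h = 0.1)
  expect_equal(tp$p_advance, 1)          # spacing 1 -> advance surely
  w <- deltamix:::propagate_weights(matrix(c(1, 0), 1), tp)
  expect_equal(c(w), c(0.1, 0.9))        # change 0.1, advance 0.9

  # spacing 2: advance probability 1/2, expected run-length increase 1
  tp <- transition_prior(node_set(c(1, 3)), h = 0)
  expect_equal(tp$p_advance, 0.5)
  s <- diff(c(1, 3))
  expect_equal(tp$p_advance * s, 1)

  # sub-unit spacing: advance capped at 1
  tp <- transition_prior(node_set(c(1, 1.5)), h = 0)
  expect_equal(tp$p_advance, 1)

  # single node: everything returns to it
  w <- deltamix:::propagate_weights(
    matrix(1, 1), transition_prior(node_set(3), h = 0.2))
  expect_equal(c(w), 1)

  expect_error(node_set(c(3, 2)), "strictly increasing")
  expect_error(node_set(c(0, 2)), "positive")
})

test_that("expected run-length growth is exactly one for spacing >= 1", {
  nodes <- node_set(c(1, 2.5, 7, 30))
  tp <- transition_prior(nodes, h = 0)
  s <- diff(nodes$l)
  for (i in seq_along(s)) {
    expect_equal(tp$p_advance[i] * s[i], 1, tolerance = 1e-15)
  }
})

test_that("delta updates and weight normalization hold stepwise", {
  m <- reduced_model(ef_gaussian_mean(1), 0, 1e-6, 0.1, c(2, 10))
  m$en$MU[1, ] <- 0
  m$en$alpha <- c(0.5, 0.1)
  m <- step_obs(m, 10)
  expect_equal(node_means(m), c(5, 1), tolerance = 1e-12)

  ds <- sample_dataset(ef_bernoulli(), 1, 2, 0.05, T = 400, seed = 6)
  m <- reduced_model(ef_bernoulli(), 1, 2, 0.05, log_spaced_nodes(18))
  for (t in seq_len(nrow(ds))) {
    m <- step_obs(m, ds$x[t])
    expect_lt(abs(sum(model_weights(m)) - 1), 1e-12)
  }
})

test_that("prediction is the propagated weighted sum of node means", {
  set.seed(7)
  m <- reduced_model(ef_gaussian_mean(1), 0, 0.5, 0.2, c(1, 5, 20))
  m <- step_obs(m, rnorm(50, 3))
  wp <- deltamix:::propagate_weights(matrix(model_weights(m), 1), m$tp)
  expect_equal(predict_next(m)$mean, sum(wp * node_means(m)),
               tolerance = 1e-12)

  # identical node means: prediction equals that mean for any weights
  m$en$MU[1, ] <- 7
  expect_equal(predict_next(m)$mean, 7, tolerance = 1e-12)
})

test_that("weight shifts to the fast node after a change and returns", {
  # long stable stretches around a jump 5 -> 15 at t = 40, prior centred
  # on the pre-change mean
  T <- 100
  cp <- rep(FALSE, T)
  cp[c(1, 40)] <- TRUE
  nu0 <- 0.25
  ds <- sample_dataset(ef_gaussian_mean(0.5), 5 * nu0, nu0, 0.1, T = T,
                       seed = 9, cp = cp, theta = c(5, 15))
  m <- reduced_model(ef_gaussian_mean(0.5), 5 * nu0, nu0, 0.1, c(2, 10))
  fr <- filter_run(m, ds$x, keep_weights = TRUE)
  w1 <- attr(fr, "weights")[, 1]
  expect_lt(w1[39], 0.5)          # stable: mass mostly on the slow node
  expect_gt(max(w1[40:46]), 0.9)  # change: abrupt reversal to fast node
  expect_lt(w1[100], 0.5)         # stability restored

  # effective learning rate rises after the change
  alpha <- effective_learning_rate(fr$pred_mean, ds$x)
  expect_gt(alpha[40], stats::median(alpha[20:38], na.rm = TRUE))
})

test_that("step is memoryless: state carries only means and weights", {
  en <- deltamix:::reduced_engine_init(1L, ef_gaussian_mean(1), 0, 0.5,
                                       node_set(c(1, 5)))
  expect_setequal(names(en), c("fam", "chi0", "nu0", "alpha", "nu_node",
                               "MU", "W", "n"))
  # stepping twice from the same (MU, W) gives identical results
  tp <- transition_prior(node_set(c(1, 5)), 0.1)
  a <- deltamix:::reduced_engine_step(en, 2.5, tp)
  b <- deltamix:::reduced_engine_step(en, 2.5, tp)
  expect_identical(a$MU, b$MU)
  expect_identical(a$W, b$W)
})

test_that("node means are exponentially weighted averages of the data", {
  set.seed(10)
  x <- rnorm(300, 2, 1)
  m <- reduced_model(ef_gaussian_mean(1), 0, 1e-12, 0.1, c(5, 25))
  m <- step_obs(m, x)
  for (j in 1:2) {
    a <- m$en$alpha[j]
    kernel <- a * (1 - a)^(rev(seq_along(x)) - 1)
    expect_equal(node_means(m)[j], sum(kernel * x),
                 tolerance = 1e-10)
  }
})

test_that("dense nodes reproduce the full model closely", {
  ds <- sample_dataset(ef_gaussian_mean(5), 0, 0.04, 0.05, T = 600,
                       seed = 15)
  full <- deltamix:::full_filter_mat(matrix(ds$x, 1), ef_gaussian_mean(5),
                                     0, 0.04, 0.05, r_max = 60)
  red <- deltamix:::reduced_filter_mat(matrix(ds$x, 1), ef_gaussian_mean(5),
                                       0, 0.04, 0.05, node_set(1:60))
  expect_gt(stats::cor(c(full$pred), c(red$pred)), 0.95)
})

test_that("effective learning rate inverts the Delta rule", {
  set.seed(12)
  x <- rnorm(100, 5, 2)
  pred <- delta_rule_predictions(x, 0.2, mu0 = 0)
  alpha <- effective_learning_rate(pred, x)
  expect_equal(alpha, rep(0.2, 99), tolerance = 1e-10)

  # a prediction jumping fully onto the outcome has rate one
  pred2 <- c(0, x[-100])
  alpha2 <- effective_learning_rate(pred2, x)
  expect_equal(alpha2, rep(1, 99), tolerance = 1e-10)

  # near-zero prediction errors are flagged as missing
  expect_true(is.na(effective_learning_rate(c(1, 1, 1), c(1, 5, 5))[1]))
})
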