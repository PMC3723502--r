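# Independent reference implementations used as oracles.

# Exhaustive posterior over change-point configurations: every subset of
# {2..T} may be a change-point with prior probability h each; theta is
# redrawn at every change-point, so within-epoch data are scored by
# sequential conjugate predictives.  Returns the run-length distribution
# after x_T (r = number of observations in the final epoch), the filtered
# estimate, and the one-step-ahead predictive mean.
enum_posterior <- function(fam, chi0, nu0, h, x) {
  T <- length(x)
  configs <- expand.grid(rep(list(c(FALSE, TRUE)), T - 1L))
  logpost <- numeric(nrow(configs))
  r_last <- integer(nrow(configs))
  est_last <- numeric(nrow(configs))
  for (k in seq_len(nrow(configs))) {
    cp <- c(TRUE, as.logical(configs[k, ]))
    lp <- sum(ifelse(cp[-1L], log(h), log(1 - h)))
    st <- conj_state(chi0, nu0)
    for (t in seq_len(T)) {
      if (cp[t]) st <- conj_state(chi0, nu0)
      lp <- lp + conj_log_predictive(fam, st, x[t])
      st <- conj_update(fam, st, x[t])
    }
    logpost[k] <- lp
    r_last[k] <- T - max(which(cp)) + 1L
    est_last[k] <- conj_mean(fam, st)
  }
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  prior_est <- fam$stat_to_param(chi0 / nu0)
  list(rl = vapply(seq_len(T), function(r) sum(w[r_last == r]),
                   numeric(1L)),
       est = sum(w * est_last),
       pred = sum(w * (h * prior_est + (1 - h) * est_last)))
}

# Plain Delta rule trajectory: predictions made before each observation.
delta_rule_predictions <- function(x, alpha, mu0) {
  mu <- mu0
  pred <- numeric(length(x))
  for (t in seq_along(x)) {
    pred[t] <- mu
    mu <- mu + alpha * (x[t] - mu)
  }
  pred
}

# Hand-coded two-node Gaussian-mean recursion: two independent Delta
# rules, weights updated from the explicit two-node messages (change mass
# h to node 1; no-change mass advancing with probability 1/(l2 - l1),
# capped at 1) times each node's Gaussian predictive likelihood.
two_node_reference <- function(x, sigma, h, l1, l2, chi0, nu0) {
  a1 <- min(1 / (l1 + nu0), 1)
  a2 <- min(1 / (l2 + nu0), 1)
  s <- l2 - l1
  p1 <- if (s >= 1) 1 / s else 1
  sd1 <- sigma * sqrt(1 + 1 / (nu0 + l1))
  sd2 <- sigma * sqrt(1 + 1 / (nu0 + l2))
  mu1 <- mu2 <- chi0 / nu0
  w1 <- 1
  w2 <- 0
  T <- length(x)
  out <- matrix(0, T, 4L, dimnames = list(NULL, c("w1", "w2", "mu1", "mu2")))
  for (t in seq_len(T)) {
    lik1 <- stats::dnorm(x[t], mu1, sd1)
    lik2 <- stats::dnorm(x[t], mu2, sd2)
    m1 <- (h + (1 - h) * (1 - p1) * w1) * lik1
    m2 <- (1 - h) * (p1 * w1 + w2) * lik2
    w1 <- m1 / (m1 + m2)
    w2 <- 1 - w1
    mu1 <- mu1 + a1 * (x[t] - mu1)
    mu2 <- mu2 + a2 * (x[t] - mu2)
    out[t, ] <- c(w1, w2, mu1, mu2)
  }
  out
}

# One-node task observer re-implemented directly (per-block Delta rule
# with the prior folded into the effective rate), for likelihood-grid
# oracles.
delta_rule_predictions_task <- function(alpha, task) {
  prior <- deltamix:::task_prior()
  pred <- numeric(nrow(task))
  for (b in unique(task$block)) {
    i <- which(task$block == b)
    nu0 <- task$noise_sd[i[1]]^2 / prior$sigma_p^2
    l <- max(1 / alpha - nu0, 1e-6)
    a_eff <- min(1 / (l + nu0), 1)
    pred[i] <- delta_rule_predictions(task$x[i], a_eff, prior$mu_p)
  }
  pred
}

# Small task used across fitting tests.
small_task <- function(seed = 1L, n_trials = 150L, n_blocks = 2L) {
  generate_task(task_config(n_trials = n_trials), n_blocks, seed = seed)
}
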