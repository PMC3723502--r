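#' Exact (truncated) Bayesian run-length filter
#'
#' Maintains a posterior over run-lengths `r = 0..r_max` (the number of
#' observations since the last change-point, inclusive) together with the
#' conjugate sufficient statistics for each run-length, and updates both
#' recursively as data arrive.  A change-point at time `t` resamples the
#' generative parameter from the prior, so the change message carries the
#' prior predictive of the new datum and routes to run-length 1; the
#' no-change message grows each run-length by one.  At the truncation
#' bound `r_max` the growth message self-accumulates, preserving
#' normalisation; the statistics kept there summarise the most recent
#' `r_max` observations.  All weight arithmetic is in log space.
#'
#' @param fam An `ef_family` object.
#' @param chi0,nu0 Conjugate prior hyperparameters.
#' @param h Hazard rate in `[0, 1]`.
#' @param r_max Maximum run-length retained (`>= 1`).
#' @return A `full_model` object.
#' @examples
#' m <- full_model(ef_bernoulli(), 1, 2, h = 0.05, r_max = 50)
#' m <- step_obs(m, c(1, 1, 0, 1))
#' predict_next(m)$mean
#' @seealso [reduced_model()] for the mixture-of-Delta-rules
#'   approximation.
#' @export
full_model <- function(fam, chi0, nu0, h, r_max = 100L) {
  stopifnot(inherits(fam, "ef_family"))
  if (!fam$check_prior(chi0, nu0))
    stop_config("invalid prior for family '", fam$id, "'")
  if (!is.numeric(h) || h < 0 || h > 1)
    stop_config("hazard `h` must be in [0, 1]")
  r_max <- as.integer(r_max)
  if (r_max < 1L) stop_config("`r_max` must be at least 1")
  en <- full_engine_init(1L, fam, chi0, nu0, r_max)
  structure(list(fam = fam, chi0 = chi0, nu0 = nu0, h = h,
                 r_max = r_max, en = en, t = 0L),
            class = "full_model")
}

#' Advance a model by one or more observations
#'
#' @param model A [full_model()] or [reduced_model()] object.
#' @param x Observation(s); vectors are processed in order.
#' @return The updated model object.
#' @export
step_obs <- function(model, x) UseMethod("step_obs")

#' @export
step_obs.full_model <- function(model, x) {
  for (xi in x) {
    model$en <- full_engine_step(model$en, xi, model$h)
    model$t <- model$t + 1L
  }
  model
}

#' One-step-ahead prediction
#'
#' Propagates the current run-length (or node-weight) distribution
#' through the change-point prior and mixes the per-component predictive
#' means and densities.
#'
#' @param model A [full_model()] or [reduced_model()] object.
#' @return A list with `mean` (predictive mean of the tracked parameter)
#'   and `density` (a vectorised function evaluating the predictive
#'   density/mass of the next observation).
#' @export
predict_next <- function(model) UseMethod("predict_next")

#' @export
predict_next.full_model <- function(model) {
  en <- model$en
  fam <- model$fam
  h <- model$h
  w <- exp(en$LW[1L, ])
  est_r <- fam$stat_to_param(en$CHI[1L, ] / en$nu)
  prior_est <- fam$stat_to_param(model$chi0 / model$nu0)
  mean_hat <- h * prior_est + (1 - h) * sum(w * est_r)
  chi <- en$CHI[1L, ]
  nu <- en$nu
  chi0 <- model$chi0
  nu0 <- model$nu0
  density <- function(xnew) {
    vapply(xnew, function(xi) {
      h * exp(fam$log_predictive(chi0, nu0, xi)) +
        (1 - h) * sum(w * exp(fam$log_predictive(chi, nu, xi)))
    }, numeric(1L))
  }
  list(mean = mean_hat, density = density)
}

#' Filtered estimate of the tracked parameter
#'
#' The posterior-mean estimate given all data observed so far (no
#' propagation through the change-point prior).
#'
#' @param model A fitted-state model object.
#' @return A scalar estimate.
#' @export
estimate <- function(model) UseMethod("estimate")

#' @export
estimate.full_model <- function(model) {
  en <- model$en
  w <- exp(en$LW[1L, ])
  sum(w * model$fam$stat_to_param(en$CHI[1L, ] / en$nu))
}

#' Current weight vector
#'
#' The run-length distribution of a [full_model()] (over `r = 0..r_max`)
#' or the node-weight vector of a [reduced_model()].
#'
#' @param model A model object.
#' @return A numeric probability vector.
#' @export
model_weights <- function(model) UseMethod("model_weights")

#' @export
model_weights.full_model <- function(model) exp(model$en$LW[1L, ])

#' @export
print.full_model <- function(x, ...) {
  cat("<full_model>", x$fam$id, " h =", x$h, " r_max =", x$r_max,
      " t =", x$t, "\n")
  invisible(x)
}

#' Run a filter over a whole sequence
#'
#' @param model A freshly constructed [full_model()] or
#'   [reduced_model()].
#' @param x Observation sequence.
#' @param keep_weights Keep the per-step weight matrix as an attribute?
#' @return A data frame with columns `t`, `x`, `pred_mean` (the
#'   one-step-ahead prediction of the tracked parameter made *before*
#'   observing `x[t]`) and `estimate` (the filtered estimate after
#'   observing `x[t]`).  With `keep_weights = TRUE` the per-step weights
#'   are attached as attribute `"weights"` (steps in rows).
#' @export
filter_run <- function(model, x, keep_weights = FALSE) {
  T <- length(x)
  pred <- est <- numeric(T)
  rows <- list()
  for (t in seq_len(T)) {
    pred[t] <- predict_next(model)$mean
    model <- step_obs(model, x[t])
    est[t] <- estimate(model)
    if (keep_weights) rows[[t]] <- model_weights(model)
  }
  out <- data.frame(t = seq_len(T), x = x, pred_mean = pred,
                    estimate = est)
  if (keep_weights) attr(out, "weights") <- do.call(rbind, rows)
  attr(out, "final_model") <- model
  out
}

# ---- vectorised engine ----------------------------------------------------
# State for n sequences filtered in parallel: LW is the n x (r_max + 1)
# matrix of log run-length weights (column j <-> run-length j - 1), CHI the
# matching sufficient-statistic accumulators, nu the per-column
# pseudo-counts nu0 + r.

full_engine_init <- function(n, fam, chi0, nu0, r_max) {
  R1 <- r_max + 1L
  LW <- matrix(-Inf, n, R1)
  LW[, 1L] <- 0
  list(fam = fam, chi0 = chi0, nu0 = nu0, r_max = r_max,
       LW = LW, CHI = matrix(chi0, n, R1), nu = nu0 + 0:r_max,
       n = n, evals = 0)
}

# Pairwise log-sum-exp that tolerates -Inf.
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- -Inf
  out
}

full_engine_step <- function(en, x, h) {
  fam <- en$fam
  if (!fam$check_x(x))
    stop("observation outside the support of family '", fam$id, "'",
         call. = FALSE)
  n <- en$n
  R1 <- en$r_max + 1L
  LP <- matrix(fam$log_predictive(c(en$CHI), rep(en$nu, each = n),
                                  rep(x, times = R1)), n, R1)
  en$evals <- en$evals + R1 + 1
  lp0 <- fam$log_predictive(en$chi0, en$nu0, x)
  lh <- if (h > 0) log(h) else -Inf
  l1h <- if (h < 1) log1p(-h) else -Inf
  grow <- en$LW + LP + l1h                      # message r -> r + 1
  new_LW <- matrix(-Inf, n, R1)
  # run-length 1 receives the change message (prior predictive; total
  # donor mass is 1) plus growth out of the empty r = 0 slot
  new_LW[, 2L] <- lse2(lh + lp0, grow[, 1L])
  if (R1 > 2L) new_LW[, 3:R1] <- grow[, 2:(R1 - 1L), drop = FALSE]
  # truncation: mass that would outgrow r_max stays there
  new_LW[, R1] <- lse2(new_LW[, R1], grow[, R1])
  norm <- row_logsumexp(new_LW)
  if (any(!is.finite(norm)))
    stop("run-length filter update is non-normalizable (all predictive ",
         "likelihoods vanished); check the data against the family ",
         "support", call. = FALSE)
  en$LW <- new_LW - norm
  en$CHI <- cbind(rep(en$chi0, n),
                  en$CHI[, -R1, drop = FALSE] + fam$u(x))
  en
}

full_engine_estimate <- function(en) {
  M <- en$fam$stat_to_param(en$CHI / matrix(en$nu, en$n, en$r_max + 1L,
                                            byrow = TRUE))
  rowSums(exp(en$LW) * M)
}

full_engine_predict <- function(en, h) {
  prior_est <- en$fam$stat_to_param(en$chi0 / en$nu0)
  h * prior_est + (1 - h) * full_engine_estimate(en)
}

# Filter a matrix of sequences (rows) and return the per-step predictions
# and filtered estimates.
full_filter_mat <- function(X, fam, chi0, nu0, h, r_max) {
  n <- nrow(X)
  T <- ncol(X)
  en <- full_engine_init(n, fam, chi0, nu0, r_max)
  PRED <- EST <- matrix(0, n, T)
  for (t in seq_len(T)) {
    PRED[, t] <- full_engine_predict(en, h)
    en <- full_engine_step(en, X[, t], h)
    EST[, t] <- full_engine_estimate(en)
  }
  list(pred = PRED, est = EST, engine = en)
}
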