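#' Node sets for the reduced model
#'
#' The reduced model keeps `N` nodes with fixed (possibly non-integer)
#' run-lengths `l_1 < ... < l_N`.  Node `i` runs a Delta rule on the mean
#' sufficient statistic with fixed learning rate
#' `alpha_i = min(1 / (l_i + nu0), 1)`: the prior pseudo-count is folded
#' into the node so that a single node with the vague-prior limit
#' `nu0 -> 0` is exactly a plain Delta rule with rate `1 / l_1`.
#'
#' @param run_lengths Strictly increasing vector of positive run-lengths.
#' @return A `node_set` object.
#' @export
node_set <- function(run_lengths) {
  l <- as.numeric(run_lengths)
  if (length(l) < 1L || any(!is.finite(l)) || any(l <= 0))
    stop_config("run-lengths must be positive and finite")
  if (length(l) > 1L && any(diff(l) <= 0))
    stop_config("run-lengths must be strictly increasing")
  structure(list(l = l, n = length(l)), class = "node_set")
}

#' @rdname node_set
#' @param n Number of nodes.
#' @param l_min,l_max Smallest and largest run-length.
#' @export
log_spaced_nodes <- function(n, l_min = 1, l_max = 100) {
  node_set(exp(seq(log(l_min), log(l_max), length.out = n)))
}

node_alphas <- function(nodes, nu0) pmin(1 / (nodes$l + nu0), 1)

#' Run-length transition prior over a node set
#'
#' Between change-points the full model's run-length grows by exactly 1
#' per step.  With sparsely placed nodes this is approximated by a
#' stochastic advance: node `i < N` moves to node `i + 1` with
#' probability `p_i = 1 / (l_{i+1} - l_i)` when the spacing is at least
#' 1 (so the expected run-length increase is exactly 1) and with
#' probability 1 when the spacing is smaller (the expected increase is
#' then under-matched); otherwise the node keeps its run-length.  The
#' last node always self-transitions.  A change-point (probability `h`)
#' always routes to node 1.
#'
#' @param nodes A [node_set()].
#' @param h Hazard rate in `[0, 1]`.
#' @return A `transition_prior`: list with `h`, `p_advance` (length
#'   `N - 1`), and the implied per-node no-change advance/self split.
#' @examples
#' transition_prior(node_set(c(1, 3)), h = 0)$p_advance  # 1/2
#' @export
transition_prior <- function(nodes, h) {
  stopifnot(inherits(nodes, "node_set"))
  if (!is.numeric(h) || h < 0 || h > 1)
    stop_config("hazard `h` must be in [0, 1]")
  s <- diff(nodes$l)
  p <- ifelse(s >= 1, 1 / s, 1)
  structure(list(h = h, p_advance = p, n = nodes$n, l = nodes$l),
            class = "transition_prior")
}

# Propagate a weight matrix W (rows = parallel sequences) one step through
# the transition prior: change mass h to node 1, no-change mass split
# between self and advance.
propagate_weights <- function(W, tp) {
  n_nodes <- tp$n
  h <- tp$h
  out <- matrix(0, nrow(W), n_nodes)
  if (n_nodes == 1L) {
    out[, 1L] <- 1      # change and self both land on the only node
    return(out)
  }
  p <- tp$p_advance
  stay <- c(1 - p, 1)   # last node always self-transitions
  out <- W %*% diag(stay, n_nodes) * (1 - h)
  adv <- W[, -n_nodes, drop = FALSE] *
    matrix(p, nrow(W), n_nodes - 1L, byrow = TRUE) * (1 - h)
  out[, -1L] <- out[, -1L, drop = FALSE] + adv
  out[, 1L] <- out[, 1L] + h
  out
}

#' Reduced model: a mixture of fixed-learning-rate Delta rules
#'
#' Approximates the full run-length filter with `N` nodes.  Each node
#' independently tracks the mean sufficient statistic with its own fixed
#' learning rate; the node weights approximate the run-length
#' distribution and are updated by passing the current weights through
#' the [transition_prior()] and rescaling by each node's predictive
#' likelihood of the new datum (evaluated from the conjugate predictive
#' with effective pseudo-count `nu0 + l_i` and accumulator implied by the
#' node mean).
#'
#' Node means start at the prior mean and the weights start with all mass
#' on node 1 (change-points route there, making it the natural initial
#' state).
#'
#' @param fam An `ef_family` object.
#' @param chi0,nu0 Conjugate prior hyperparameters.
#' @param h Hazard rate in `[0, 1]`.
#' @param nodes A [node_set()], or a numeric vector of run-lengths.
#' @return A `reduced_model` object.
#' @examples
#' m <- reduced_model(ef_gaussian_mean(1), 0, 1e-4, h = 0.1,
#'                    nodes = c(2, 20))
#' m <- step_obs(m, rnorm(5, 10))
#' predict_next(m)$mean
#' @export
reduced_model <- function(fam, chi0, nu0, h, nodes) {
  stopifnot(inherits(fam, "ef_family"))
  if (!fam$check_prior(chi0, nu0))
    stop_config("invalid prior for family '", fam$id, "'")
  if (!inherits(nodes, "node_set")) nodes <- node_set(nodes)
  tp <- transition_prior(nodes, h)
  en <- reduced_engine_init(1L, fam, chi0, nu0, nodes)
  structure(list(fam = fam, chi0 = chi0, nu0 = nu0, h = h,
                 nodes = nodes, tp = tp, en = en, t = 0L),
            class = "reduced_model")
}

#' @export
step_obs.reduced_model <- function(model, x) {
  for (xi in x) {
    model$en <- reduced_engine_step(model$en, xi, model$tp)
    model$t <- model$t + 1L
  }
  model
}

#' @export
predict_next.reduced_model <- function(model) {
  en <- model$en
  fam <- model$fam
  wp <- propagate_weights(en$W, model$tp)[1L, ]
  est_i <- fam$stat_to_param(en$MU[1L, ])
  mu <- en$MU[1L, ]
  nu_node <- en$nu_node
  density <- function(xnew) {
    vapply(xnew, function(xi) {
      sum(wp * exp(fam$log_predictive(mu * nu_node, nu_node, xi)))
    }, numeric(1L))
  }
  list(mean = sum(wp * est_i), density = density)
}

#' @export
estimate.reduced_model <- function(model) {
  sum(model$en$W[1L, ] * model$fam$stat_to_param(model$en$MU[1L, ]))
}

#' @export
model_weights.reduced_model <- function(model) model$en$W[1L, ]

#' Node means of a reduced model
#'
#' @param model A [reduced_model()].
#' @return Numeric vector of per-node Delta-rule means (mean sufficient
#'   statistic scale).
#' @export
node_means <- function(model) model$en$MU[1L, ]

#' @export
print.reduced_model <- function(x, ...) {
  cat("<reduced_model>", x$fam$id, " h =", x$h, " nodes:",
      paste(signif(x$nodes$l, 4), collapse = ", "), " t =", x$t, "\n")
  invisible(x)
}

#' Effective learning rate of a prediction trajectory
#'
#' Inverts the Delta rule: `alpha_t = (pred_{t+1} - pred_t) /
#' (x_t - pred_t)`.  Steps whose prediction error is smaller than `tol`
#' in absolute value are returned as `NA`.
#'
#' @param pred Predictions `pred_t` for trials `1..T` (each made before
#'   observing `x_t`).
#' @param x Observations for trials `1..T`.
#' @param tol Minimum absolute prediction error.
#' @return Numeric vector of length `T - 1`.
#' @export
effective_learning_rate <- function(pred, x, tol = 1e-8) {
  T <- length(x)
  if (length(pred) != T) stop_config("`pred` and `x` must align")
  err <- x[-T] - pred[-T]
  alpha <- (pred[-1L] - pred[-T]) / err
  alpha[abs(err) < tol] <- NA_real_
  alpha
}

# ---- vectorised engine ----------------------------------------------------
# MU: n x N matrix of node means (mean sufficient-statistic scale),
# W: n x N node weights.  step() touches only (MU, W) and the current
# observation -- the model is memoryless by construction.

reduced_engine_init <- function(n, fam, chi0, nu0, nodes) {
  N <- nodes$n
  W <- matrix(0, n, N)
  W[, 1L] <- 1
  list(fam = fam, chi0 = chi0, nu0 = nu0,
       alpha = node_alphas(nodes, nu0), nu_node = nu0 + nodes$l,
       MU = matrix(chi0 / nu0, n, N), W = W, n = n)
}

reduced_engine_step <- function(en, x, tp) {
  fam <- en$fam
  if (!fam$check_x(x))
    stop("observation outside the support of family '", fam$id, "'",
         call. = FALSE)
  n <- en$n
  N <- length(en$alpha)
  inc <- propagate_weights(en$W, tp)
  LL <- matrix(fam$log_predictive(c(en$MU) * rep(en$nu_node, each = n),
                                  rep(en$nu_node, each = n),
                                  rep(x, times = N)), n, N)
  LL <- LL - apply(LL, 1L, max)
  Wn <- inc * exp(LL)
  z <- rowSums(Wn)
  if (any(!is.finite(z)) || any(z <= 0))
    stop("reduced-model weight update is non-normalizable (all node ",
         "likelihoods vanished); check the data against the family ",
         "support", call. = FALSE)
  en$W <- Wn / z
  U <- matrix(fam$u(x), n, N)
  en$MU <- en$MU + matrix(en$alpha, n, N, byrow = TRUE) * (U - en$MU)
  en
}

reduced_engine_estimate <- function(en) {
  rowSums(en$W * en$fam$stat_to_param(en$MU))
}

reduced_engine_predict <- function(en, tp) {
  rowSums(propagate_weights(en$W, tp) * en$fam$stat_to_param(en$MU))
}

# Filter a matrix of sequences (rows); returns one-step-ahead predictions
# and filtered estimates, as full_filter_mat().
reduced_filter_mat <- function(X, fam, chi0, nu0, h, nodes) {
  if (!inherits(nodes, "node_set")) nodes <- node_set(nodes)
  tp <- transition_prior(nodes, h)
  n <- nrow(X)
  T <- ncol(X)
  en <- reduced_engine_init(n, fam, chi0, nu0, nodes)
  PRED <- EST <- matrix(0, n, T)
  for (t in seq_len(T)) {
    PRED[, t] <- reduced_engine_predict(en, tp)
    en <- reduced_engine_step(en, X[, t], tp)
    EST[, t] <- reduced_engine_estimate(en)
  }
  list(pred = PRED, est = EST, engine = en)
}
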