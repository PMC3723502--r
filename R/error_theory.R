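#' Monte-Carlo estimate of the reduced model's error against ground truth
#'
#' Simulates change-point sequences from the family's generative process,
#' runs the reduced model, and averages the squared difference between
#' the one-step-ahead predictive mean and the true generative parameter
#' at that step, over time and replicates.  The relative error `E_rel`
#' divides by the closed-form prior variance of the parameter, so it
#' equals 1 for an algorithm that always predicts the prior mean (the
#' limit of a vanishing learning rate).
#'
#' @param nodes A [node_set()] or numeric vector of run-lengths.
#' @param fam An `ef_family` object.
#' @param chi0,nu0 Conjugate prior hyperparameters.
#' @param h Hazard rate.
#' @param T Steps per replicate sequence.
#' @param n_reps Number of replicate sequences (`>= 1`).
#' @param seed Integer seed (common random numbers: the same seed always
#'   yields the same simulated sequences).
#' @param burn_in Number of initial steps excluded from the average
#'   (useful for steady-state comparisons).
#' @return A list of class `error_estimate`: `E` (mean squared error),
#'   `E_rel`, `mc_se` (Monte-Carlo standard error of `E` across
#'   replicates), `var_prior`, `n_reps`, `T`.
#' @export
estimate_error <- function(nodes, fam, chi0, nu0, h, T = 1000L,
                           n_reps = 50L, seed = 1L, burn_in = 0L) {
  if (n_reps < 1L) stop_config("`n_reps` must be at least 1")
  sim <- sim_sequences(fam, chi0, nu0, h, T, n_reps, seed)
  error_on_sequences(nodes, fam, chi0, nu0, h, sim, burn_in)
}

# Draw n_reps change-point sequences as matrices (rows = replicates).
sim_sequences <- function(fam, chi0, nu0, h, T, n_reps, seed) {
  with_seed(seed, {
    X <- THETA <- matrix(0, n_reps, T)
    for (r in seq_len(n_reps)) {
      cp <- c(TRUE, stats::runif(T - 1L) < h)
      epoch <- cumsum(cp)
      th <- fam$sample_theta(chi0, nu0, epoch[T])[epoch]
      THETA[r, ] <- th
      X[r, ] <- fam$sample_x(th, T)
    }
    list(X = X, THETA = THETA)
  })
}

# THETA holds the generative parameter on the family's natural scale
# (rate, mean, or standard deviation); predictions are on the same scale.
error_on_sequences <- function(nodes, fam, chi0, nu0, h, sim, burn_in = 0L) {
  fit <- reduced_filter_mat(sim$X, fam, chi0, nu0, h, nodes)
  keep <- seq_len(ncol(sim$X)) > burn_in
  se <- (fit$pred[, keep, drop = FALSE] -
           sim$THETA[, keep, drop = FALSE])^2
  rep_means <- rowMeans(se)
  E <- mean(rep_means)
  vp <- fam$prior_param_var(chi0, nu0)
  structure(list(E = E, E_rel = E / vp,
                 mc_se = stats::sd(rep_means) / sqrt(length(rep_means)),
                 var_prior = vp, n_reps = nrow(sim$X), T = ncol(sim$X),
                 burn_in = burn_in),
            class = "error_estimate")
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf("<error_estimate> E = %.5g  E_rel = %.4g  (mc_se %.2g, %d reps x T = %d)\n",
              x$E, x$E_rel, x$mc_se, x$n_reps, x$T))
  invisible(x)
}

# Map learning rates (sorted decreasing) to a valid strictly increasing
# run-length vector: l = 1/alpha - nu0, floored at a small positive value
# and nudged apart where degenerate.
alphas_to_run_lengths <- function(alphas, nu0, l_floor = 1e-6) {
  a <- sort(as.numeric(alphas), decreasing = TRUE)
  l <- pmax(1 / a - nu0, l_floor)
  if (length(l) > 1L) {
    for (i in 2:length(l)) {
      if (l[i] <= l[i - 1L])
        l[i] <- l[i - 1L] * (1 + 1e-8) + 1e-8
    }
  }
  l
}

#' Optimise node learning rates by Monte-Carlo search
#'
#' Minimises [estimate_error()] over the node learning rates
#' `alpha in (0, 1]` (equivalently run-lengths `l = 1/alpha - nu0`) for a
#' fixed hazard rate, using common random numbers: the simulated
#' sequences are drawn once from `seed`, making the objective a
#' deterministic function of the learning rates.  Multi-start local
#' search (Nelder-Mead on a logistic reparameterisation; golden-section
#' for one node) guards against the multiple local minima that occur
#' with three nodes at low hazard rates.
#'
#' @inheritParams estimate_error
#' @param n_nodes Number of nodes (1, 2 or 3 supported).
#' @param alpha_bounds Search range for the learning rates.
#' @param n_starts Number of optimisation starts (`>= 1`).
#' @param init_alphas Optional list of additional starting learning-rate
#'   vectors (each of length `n_nodes`), e.g. the optimum of a smaller
#'   model padded with an extra rate.
#' @return A list of class `node_opt`: `alphas` (decreasing),
#'   `run_lengths` (increasing), `E`, `E_rel`, `mc_se`, `converged`.
#' @export
optimize_nodes <- function(n_nodes, fam, chi0, nu0, h, T = 1000L,
                           n_reps = 50L, seed = 1L,
                           alpha_bounds = c(0.005, 1), n_starts = 8L,
                           init_alphas = NULL, burn_in = 0L) {
  if (!n_nodes %in% 1:3)
    stop_config("`n_nodes` must be 1, 2 or 3")
  lo <- alpha_bounds[1]
  hi <- alpha_bounds[2]
  if (lo <= 0 || hi > 1 || lo >= hi)
    stop_config("`alpha_bounds` must satisfy 0 < lo < hi <= 1")
  sim <- sim_sequences(fam, chi0, nu0, h, T, n_reps, seed)

  obj_alpha <- function(a) {
    l <- alphas_to_run_lengths(a, nu0)
    err <- error_on_sequences(l, fam, chi0, nu0, h, sim, burn_in)
    err$E
  }

  if (n_nodes == 1L) {
    grid <- exp(seq(log(lo), log(hi), length.out = max(n_starts, 5L)))
    vals <- vapply(grid, obj_alpha, numeric(1L))
    i <- which.min(vals)
    lo_i <- grid[max(i - 1L, 1L)]
    hi_i <- grid[min(i + 1L, length(grid))]
    o <- stats::optimize(obj_alpha, c(lo_i, hi_i), tol = 1e-4)
    best <- list(par = o$minimum, value = o$objective, conv = TRUE)
    if (vals[i] < best$value) best <- list(par = grid[i], value = vals[i],
                                           conv = TRUE)
  } else {
    to_alpha <- function(z) lo + (hi - lo) * stats::plogis(z)
    to_z <- function(a) stats::qlogis(pmin(pmax((a - lo) / (hi - lo),
                                                1e-6), 1 - 1e-6))
    obj_z <- function(z) obj_alpha(to_alpha(z))
    starts <- default_alpha_starts(n_nodes, lo, hi, n_starts, seed)
    for (ia in init_alphas %||% list())
      starts <- c(starts, list(sort(rep_len(ia, n_nodes),
                                    decreasing = TRUE)))
    best <- NULL
    conv_any <- FALSE
    for (a0 in starts) {
      o <- stats::optim(to_z(a0), obj_z, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-7))
      conv_any <- conv_any || o$convergence == 0L
      if (is.null(best) || o$value < best$value)
        best <- list(par = to_alpha(o$par), value = o$value,
                     conv = o$convergence == 0L)
    }
    best$conv <- best$conv || conv_any
  }

  a_opt <- sort(pmin(pmax(best$par, lo), hi), decreasing = TRUE)
  l_opt <- alphas_to_run_lengths(a_opt, nu0)
  err <- error_on_sequences(l_opt, fam, chi0, nu0, h, sim, burn_in)
  structure(list(alphas = a_opt, run_lengths = l_opt, E = err$E,
                 E_rel = err$E_rel, mc_se = err$mc_se,
                 converged = isTRUE(best$conv), h = h,
                 n_reps = n_reps, T = T),
            class = "node_opt")
}

default_alpha_starts <- function(n_nodes, lo, hi, n_starts, seed) {
  base <- list()
  anchors <- exp(seq(log(max(lo, 0.02)), log(hi * 0.95),
                     length.out = 4L))
  combs <- utils::combn(anchors, n_nodes, simplify = FALSE)
  base <- lapply(combs, sort, decreasing = TRUE)
  if (length(base) < n_starts) {
    extra <- with_seed(substream_seed(seed, 99L), {
      lapply(seq_len(n_starts - length(base)), function(i)
        sort(exp(stats::runif(n_nodes, log(lo), log(hi))),
             decreasing = TRUE))
    })
    base <- c(base, extra)
  }
  base[seq_len(max(n_starts, 1L))]
}

#' @export
print.node_opt <- function(x, ...) {
  cat(sprintf("<node_opt> h = %.3g  alphas = %s  E_rel = %.4g (mc_se %.2g)\n",
              x$h, paste(signif(x$alphas, 3), collapse = ", "),
              x$E_rel, x$mc_se))
  invisible(x)
}

#' Optimised error across nested node counts
#'
#' Runs [optimize_nodes()] for `n = 1..n_max` nodes at a fixed hazard,
#' seeding each search with the previous optimum (padded with an extra
#' fast rate) so the fitted error is monotone in the node count up to
#' Monte-Carlo noise.
#'
#' @inheritParams optimize_nodes
#' @param n_max Largest node count (at most 3).
#' @return A list of `node_opt` results indexed by node count.
#' @export
optimize_nodes_path <- function(n_max, fam, chi0, nu0, h, T = 1000L,
                                n_reps = 50L, seed = 1L,
                                alpha_bounds = c(0.005, 1),
                                n_starts = 8L, burn_in = 0L) {
  out <- vector("list", n_max)
  prev <- NULL
  for (n in seq_len(n_max)) {
    init <- NULL
    if (!is.null(prev)) {
      pad_hi <- min(max(prev$alphas) * 2, alpha_bounds[2] * 0.99)
      pad_lo <- max(min(prev$alphas) / 2, alpha_bounds[1] * 1.01)
      init <- list(c(prev$alphas, pad_hi), c(prev$alphas, pad_lo))
    }
    out[[n]] <- optimize_nodes(n, fam, chi0, nu0, h, T, n_reps, seed,
                               alpha_bounds, n_starts,
                               init_alphas = init, burn_in = burn_in)
    prev <- out[[n]]
  }
  out
}
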