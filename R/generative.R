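#' Hazard specification for change-point processes
#'
#' A constant per-step change probability `h`, optionally with a
#' refractory period: for `refractory` steps after each change-point the
#' hazard is forced to zero (the predictive-inference task uses `h = 0.1`
#' with a 3-trial refractory period).
#'
#' @param h Change probability per step, in `[0, 1]`.
#' @param refractory Non-negative integer count of post-change steps with
#'   zero hazard.
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(h, refractory = 0L) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 || h > 1)
    stop_config("hazard `h` must be a single number in [0, 1]")
  if (!is.numeric(refractory) || length(refractory) != 1L ||
      refractory < 0 || refractory != round(refractory))
    stop_config("`refractory` must be a non-negative integer")
  structure(list(h = h, refractory = as.integer(refractory)),
            class = "hazard_spec")
}

as_hazard <- function(hz) {
  if (inherits(hz, "hazard_spec")) hz else hazard_spec(hz)
}

#' Sample change-point locations
#'
#' Draws a Bernoulli sequence of change-point indicators.  Position 1 is
#' always an epoch start; each later position is a change-point with
#' probability `hz$h`, except that the `hz$refractory` positions following
#' any change-point (including the start) are forced to `FALSE`.
#'
#' @param T Sequence length (`>= 1`).
#' @param hz A [hazard_spec()] (a bare number is promoted).
#' @param seed Optional integer seed.
#' @return Logical vector of length `T`; element 1 is `TRUE`.
#' @export
sample_changepoints <- function(T, hz, seed = NULL) {
  hz <- as_hazard(hz)
  T <- as.integer(T)
  if (T < 1L) stop_config("`T` must be at least 1")
  with_seed(seed, {
    cp <- logical(T)
    cp[1L] <- TRUE
    if (T == 1L) return(cp)
    if (hz$refractory == 0L) {
      cp[2:T] <- stats::runif(T - 1L) < hz$h
    } else {
      since <- 0L
      for (t in 2:T) {
        if (since < hz$refractory) {
          since <- since + 1L
        } else if (stats::runif(1L) < hz$h) {
          cp[t] <- TRUE
          since <- 0L
        } else {
          since <- since + 1L
        }
      }
    }
    cp
  })
}

#' Simulate a change-point dataset
#'
#' The generative parameter is drawn from the family's conjugate prior at
#' the first step and redrawn at every change-point; within an epoch it is
#' constant and observations are sampled i.i.d. from the family's
#' likelihood.  The first epoch's parameter comes from the same prior as
#' post-change epochs.
#'
#' @param fam An `ef_family` object.
#' @param chi0,nu0 Conjugate prior hyperparameters (must be valid for the
#'   family).
#' @param hz A [hazard_spec()] or bare hazard rate.
#' @param T Number of time steps.
#' @param seed Optional integer seed.
#' @param cp Optional logical vector of forced change-point locations
#'   (overrides sampling from `hz`).
#' @param theta Optional vector of forced per-epoch parameter values,
#'   recycled over epochs in order.
#' @return A `cp_dataset`: a data frame with columns `t`, `x`,
#'   `theta_true`, `cp` and attributes `family_id` and `fixed` (the
#'   family's fixed parameters).
#' @examples
#' ds <- sample_dataset(ef_bernoulli(), 1, 2, hazard_spec(0.05),
#'                      T = 200, seed = 1)
#' table(ds$cp)
#' @export
sample_dataset <- function(fam, chi0, nu0, hz, T, seed = NULL,
                           cp = NULL, theta = NULL) {
  stopifnot(inherits(fam, "ef_family"))
  if (!fam$check_prior(chi0, nu0))
    stop_config("prior (chi0 = ", chi0, ", nu0 = ", nu0,
                ") is not valid for family '", fam$id, "'")
  hz <- as_hazard(hz)
  T <- as.integer(T)
  with_seed(seed, {
    if (is.null(cp)) cp <- sample_changepoints(T, hz)
    stopifnot(length(cp) == T, isTRUE(cp[1L]))
    epoch <- cumsum(cp)
    n_epochs <- epoch[T]
    theta_e <- if (is.null(theta)) {
      fam$sample_theta(chi0, nu0, n_epochs)
    } else {
      rep_len(theta, n_epochs)
    }
    theta_true <- theta_e[epoch]
    x <- fam$sample_x(theta_true, T)
    new_cp_dataset(data.frame(t = seq_len(T), x = x,
                              theta_true = theta_true, cp = cp),
                   fam)
  })
}

new_cp_dataset <- function(df, fam) {
  structure(df, family_id = fam$id, fixed = fam$fixed,
            class = c("cp_dataset", "data.frame"))
}

#' @export
print.cp_dataset <- function(x, ...) {
  cat("<cp_dataset> family:", attr(x, "family_id"),
      " T:", nrow(x), " change-points:", sum(x$cp) - 1L, "\n")
  NextMethod()
}

#' Configuration of the predictive-inference task
#'
#' Numbers between `sample_bounds[1]` and `sample_bounds[2]` are generated
#' from a Gaussian change-point process whose mean is uniform on
#' `mean_range` and whose standard deviation is constant within a block
#' (cycling through `noise_sd` across blocks).  Samples falling outside
#' the bounds are redrawn.  The hazard is 0.1 with a 3-trial refractory
#' period after each change-point.
#'
#' @param n_trials Trials per block.
#' @param noise_sd Vector of block noise standard deviations, recycled
#'   across blocks.
#' @param mean_range Range of the uniform distribution of epoch means;
#'   must lie within `sample_bounds`.
#' @param sample_bounds Allowed range of generated samples.
#' @param hazard A [hazard_spec()].
#' @return A `task_config` list.
#' @export
task_config <- function(n_trials = 200L, noise_sd = c(5, 10),
                        mean_range = c(40, 260),
                        sample_bounds = c(0, 300),
                        hazard = hazard_spec(0.1, 3L)) {
  if (mean_range[1] < sample_bounds[1] || mean_range[2] > sample_bounds[2])
    stop_config("`mean_range` must lie within `sample_bounds`")
  if (any(noise_sd <= 0)) stop_config("`noise_sd` must be positive")
  structure(list(n_trials = as.integer(n_trials), noise_sd = noise_sd,
                 mean_range = mean_range, sample_bounds = sample_bounds,
                 hazard = as_hazard(hazard)),
            class = "task_config")
}

#' Generate predictive-inference task sequences
#'
#' @param cfg A [task_config()].
#' @param n_blocks Number of blocks; block `b` uses
#'   `cfg$noise_sd[(b - 1) %% length(noise_sd) + 1]`.
#' @param seed Optional integer seed.
#' @param max_tries Safety cap on resampling an out-of-bounds sample.
#' @return A `cp_dataset` data frame with additional columns `block` and
#'   `noise_sd`.
#' @export
generate_task <- function(cfg = task_config(), n_blocks = 1L, seed = NULL,
                          max_tries = 1e4) {
  stopifnot(inherits(cfg, "task_config"))
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      sd_b <- cfg$noise_sd[(b - 1L) %% length(cfg$noise_sd) + 1L]
      cp <- sample_changepoints(cfg$n_trials, cfg$hazard)
      epoch <- cumsum(cp)
      mu_e <- stats::runif(epoch[cfg$n_trials],
                           cfg$mean_range[1], cfg$mean_range[2])
      mu <- mu_e[epoch]
      x <- stats::rnorm(cfg$n_trials, mu, sd_b)
      out <- x < cfg$sample_bounds[1] | x > cfg$sample_bounds[2]
      tries <- 0L
      while (any(out)) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("exceeded ", max_tries, " resampling attempts for ",
               "out-of-bounds task samples", call. = FALSE)
        x[out] <- stats::rnorm(sum(out), mu[out], sd_b)
        out <- x < cfg$sample_bounds[1] | x > cfg$sample_bounds[2]
      }
      data.frame(t = seq_len(cfg$n_trials), x = x, theta_true = mu,
                 cp = cp, block = b, noise_sd = sd_b)
    })
    df <- do.call(rbind, blocks)
    df$t <- seq_len(nrow(df))
    new_cp_dataset(df, ef_gaussian_mean(cfg$noise_sd[1]))
  })
}

#' Task performance benchmarks
#'
#' The lower benchmark (LB) is the mean absolute difference between
#' successive outcomes — the error of always predicting the previous
#' outcome.  The higher benchmark (HB) is the mean absolute difference
#' between the generative mean on the previous trial and the current
#' outcome — the error of an observer who knows the generative mean.
#'
#' @param x Observation sequence (length `>= 2`).
#' @param theta_true Generative mean sequence aligned with `x`.
#' @return A list with elements `LB` and `HB`.
#' @export
benchmarks <- function(x, theta_true) {
  n <- length(x)
  if (n < 2L) stop_config("benchmarks need at least 2 observations")
  if (length(theta_true) != n)
    stop_config("`x` and `theta_true` must have equal length")
  list(LB = mean(abs(diff(x))),
       HB = mean(abs(theta_true[-n] - x[-1L])))
}

#' Read or write a change-point dataset as CSV
#'
#' Datasets are stored with header columns `t`, `x`, `theta_true`, `cp`
#' (plus any extras such as `block`, `noise_sd`).
#'
#' @param ds A `cp_dataset` (or plain data frame with the same columns).
#' @param path File path.
#' @param family_id Family to attach on reading.
#' @param sigma,mu Fixed family parameters used when reconstructing the
#'   family on read.
#' @return `read_dataset()` returns a `cp_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, family_id = "gaussian_mean",
                         sigma = 5, mu = 0) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "theta_true", "cp")
  if (!all(need %in% names(df)))
    stop_config("dataset CSV must have columns: ",
                paste(need, collapse = ", "))
  df$cp <- as.logical(df$cp)
  new_cp_dataset(df, ef_family_by_id(family_id, sigma, mu))
}
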