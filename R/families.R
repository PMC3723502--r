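#' Conjugate exponential-family specifications
#'
#' The three observation families used throughout the package, each paired
#' with its conjugate prior expressed through two hyperparameters: an
#' accumulator `chi` for the transformed data (the sufficient statistic
#' `u(x)`) and a pseudo-count `nu`.  After observing a datum the posterior
#' hyperparameters are `chi + u(x)` and `nu + 1`, so the posterior mean of
#' the tracked sufficient statistic is always `chi / nu` and follows a
#' Delta rule with a decaying learning rate `1 / nu`.
#'
#' * `ef_bernoulli()`: binary data with unknown rate; `(chi, nu)` is the
#'   Beta(`chi`, `nu - chi`) parameterisation, so the uniform prior is
#'   `chi0 = 1, nu0 = 2`.
#' * `ef_gaussian_mean(sigma)`: Gaussian data with known standard deviation
#'   `sigma` and unknown mean; the conjugate Gaussian prior with mean
#'   `mu_p` and standard deviation `sigma_p` corresponds to
#'   `nu0 = sigma^2 / sigma_p^2`, `chi0 = mu_p * nu0` (see
#'   [gaussian_mean_prior()]).
#' * `ef_gaussian_scale(mu)`: Gaussian data with known mean `mu` and
#'   unknown scale; `u(x) = (x - mu)^2` and the prior is a Gamma
#'   distribution on the precision with shape `nu0 / 2` and rate
#'   `chi0 / 2`.  The tracked statistic `chi / nu` estimates the variance;
#'   the reported parameter is the standard deviation `sqrt(chi / nu)`.
#'
#' @param sigma Known observation standard deviation (`> 0`).
#' @param mu Known observation mean.
#' @return An object of class `ef_family` with the family's sufficient
#'   statistic transform, log predictive density, samplers and
#'   prior-moment formulas.
#' @examples
#' fam <- ef_bernoulli()
#' st <- conj_state(1, 2)                 # uniform prior
#' st <- conj_update(fam, st, 1)
#' conj_mean(fam, st)                     # 2/3, Laplace's rule
#' @export
ef_bernoulli <- function() {
  new_family(
    id = "bernoulli",
    fixed = list(),
    u = function(x) x,
    check_x = function(x) all(x %in% c(0, 1)),
    # Beta-Bernoulli posterior predictive mass, log scale.
    log_predictive = function(chi, nu, x) {
      p <- chi / nu
      x * log(p) + (1 - x) * log1p(-p)
    },
    stat_to_param = function(m) m,
    sample_x = function(theta, n) stats::rbinom(n, 1L, theta),
    sample_theta = function(chi0, nu0, n) stats::rbeta(n, chi0, nu0 - chi0),
    check_prior = function(chi0, nu0) nu0 > 0 && chi0 > 0 && chi0 < nu0,
    prior_param_mean = function(chi0, nu0) chi0 / nu0,
    prior_param_var = function(chi0, nu0) {
      a <- chi0
      b <- nu0 - chi0
      a * b / ((a + b)^2 * (a + b + 1))
    }
  )
}

#' @rdname ef_bernoulli
#' @export
ef_gaussian_mean <- function(sigma = 5) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_config("`sigma` must be a single positive number")
  new_family(
    id = "gaussian_mean",
    fixed = list(sigma = sigma),
    u = function(x) x,
    check_x = function(x) all(is.finite(x)),
    # Marginal of x under the Gaussian posterior on the mean: the posterior
    # mean carries variance sigma^2 / nu on top of the observation noise.
    log_predictive = function(chi, nu, x) {
      stats::dnorm(x, chi / nu, sigma * sqrt(1 + 1 / nu), log = TRUE)
    },
    stat_to_param = function(m) m,
    sample_x = function(theta, n) stats::rnorm(n, theta, sigma),
    sample_theta = function(chi0, nu0, n) {
      stats::rnorm(n, chi0 / nu0, sigma / sqrt(nu0))
    },
    check_prior = function(chi0, nu0) nu0 > 0 && is.finite(chi0),
    prior_param_mean = function(chi0, nu0) chi0 / nu0,
    prior_param_var = function(chi0, nu0) sigma^2 / nu0
  )
}

#' @rdname ef_bernoulli
#' @export
ef_gaussian_scale <- function(mu = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop_config("`mu` must be a single finite number")
  new_family(
    id = "gaussian_scale",
    fixed = list(mu = mu),
    u = function(x) (x - mu)^2,
    check_x = function(x) all(is.finite(x)),
    # Precision ~ Gamma(nu/2, chi/2) marginalises to a scaled Student-t
    # with nu degrees of freedom and scale sqrt(chi/nu).
    log_predictive = function(chi, nu, x) {
      s <- sqrt(chi / nu)
      stats::dt((x - mu) / s, df = nu, log = TRUE) - log(s)
    },
    stat_to_param = function(m) sqrt(m),
    sample_x = function(theta, n) stats::rnorm(n, mu, theta),
    sample_theta = function(chi0, nu0, n) {
      1 / sqrt(stats::rgamma(n, shape = nu0 / 2, rate = chi0 / 2))
    },
    check_prior = function(chi0, nu0) nu0 > 0 && chi0 > 0,
    # Moments of the standard deviation under the prior (needs nu0 > 2).
    prior_param_mean = function(chi0, nu0) {
      sqrt(chi0 / 2) * exp(lgamma((nu0 - 1) / 2) - lgamma(nu0 / 2))
    },
    prior_param_var = function(chi0, nu0) {
      if (nu0 <= 2) stop_config("prior variance of the scale needs nu0 > 2")
      e2 <- chi0 / (nu0 - 2)
      e1 <- sqrt(chi0 / 2) * exp(lgamma((nu0 - 1) / 2) - lgamma(nu0 / 2))
      e2 - e1^2
    }
  )
}

new_family <- function(id, fixed, u, check_x, log_predictive, stat_to_param,
                       sample_x, sample_theta, check_prior,
                       prior_param_mean, prior_param_var) {
  structure(
    list(id = id, fixed = fixed, u = u, check_x = check_x,
         log_predictive = log_predictive, stat_to_param = stat_to_param,
         sample_x = sample_x, sample_theta = sample_theta,
         check_prior = check_prior, prior_param_mean = prior_param_mean,
         prior_param_var = prior_param_var),
    class = "ef_family"
  )
}

#' @export
print.ef_family <- function(x, ...) {
  cat("<ef_family>", x$id, "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

ef_family_by_id <- function(id, sigma = 5, mu = 0) {
  switch(id,
    bernoulli = ef_bernoulli(),
    gaussian_mean = ef_gaussian_mean(sigma),
    gaussian_scale = ef_gaussian_scale(mu),
    stop_config("unknown family id: ", id)
  )
}

#' Conjugate posterior state
#'
#' A pair `(chi, nu)`: the accumulated sufficient statistic and the
#' pseudo-count.  `conj_update()` applies one observation, `conj_mean()`
#' returns the posterior mean of the tracked parameter (rate, mean, or
#' standard deviation depending on the family) and `conj_log_predictive()`
#' evaluates the log marginal likelihood of a datum under the current
#' posterior.
#'
#' @param chi,nu Hyperparameters; `nu` must be positive for `conj_mean()`.
#' @param fam An [ef_bernoulli()]-style family object.
#' @param state A `conj_state`.
#' @param x Observation(s) in the family's support.
#' @return `conj_state()` and `conj_update()` return a `conj_state`;
#'   `conj_mean()` a scalar; `conj_log_predictive()` a numeric vector.
#' @export
conj_state <- function(chi, nu) {
  if (!is.numeric(chi) || !is.numeric(nu) || length(chi) != 1L ||
      length(nu) != 1L || nu < 0)
    stop_config("conjugate state needs scalar chi and nu >= 0")
  structure(list(chi = chi, nu = nu), class = "conj_state")
}

#' @rdname conj_state
#' @export
conj_update <- function(fam, state, x) {
  stopifnot(inherits(fam, "ef_family"), inherits(state, "conj_state"))
  if (!fam$check_x(x))
    stop("observation outside the support of family '", fam$id, "'",
         call. = FALSE)
  for (xi in x) state <- conj_state(state$chi + fam$u(xi), state$nu + 1)
  state
}

#' @rdname conj_state
#' @export
conj_mean <- function(fam, state) {
  if (state$nu <= 0) stop_config("posterior mean undefined at nu = 0")
  fam$stat_to_param(state$chi / state$nu)
}

#' @rdname conj_state
#' @export
conj_log_predictive <- function(fam, state, x) {
  fam$log_predictive(state$chi, state$nu, x)
}

#' Map a Gaussian prior on the mean to conjugate hyperparameters
#'
#' For the known-variance Gaussian family, a Gaussian prior with mean
#' `mu_p` and standard deviation `sigma_p` is equivalent to the conjugate
#' pair `nu0 = sigma^2 / sigma_p^2`, `chi0 = mu_p * nu0`, under which the
#' posterior mean `chi / nu` follows the decaying-learning-rate Delta
#' rule.  `gaussian_mean_prior_inverse()` inverts the mapping.
#'
#' @param mu_p,sigma_p Prior mean and standard deviation of the unknown
#'   mean.
#' @param sigma Known observation standard deviation.
#' @param chi0,nu0 Conjugate hyperparameters.
#' @return A list with elements `chi0, nu0` (or `mu_p, sigma_p`).
#' @export
gaussian_mean_prior <- function(mu_p, sigma_p, sigma) {
  if (sigma_p <= 0 || sigma <= 0)
    stop_config("sigma_p and sigma must be positive")
  nu0 <- sigma^2 / sigma_p^2
  list(chi0 = mu_p * nu0, nu0 = nu0)
}

#' @rdname gaussian_mean_prior
#' @export
gaussian_mean_prior_inverse <- function(chi0, nu0, sigma) {
  list(mu_p = chi0 / nu0, sigma_p = sigma / sqrt(nu0))
}
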