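#' Candidate models for the predictive-inference task
#'
#' The fitting stack compares four observers on the Gaussian
#' predictive-inference task: the full run-length filter (`"full"`, free
#' hazard rate) and reduced models with one to three nodes (`"node1"`,
#' one free learning rate; `"node2"`/`"node3"`, a free hazard rate plus
#' two or three free learning rates).  Every model additionally has a
#' free decision-noise standard deviation `sigma_n`, which is profiled
#' out in closed form during fitting.
#'
#' @name task-models
#' @keywords internal
NULL

task_model_ids <- function() c("full", "node1", "node2", "node3")

model_par_info <- function(model_id) {
  switch(model_id,
    full  = list(names = "h", lower = 0.001, upper = 0.999),
    node1 = list(names = "alpha1", lower = 0.01, upper = 1),
    node2 = list(names = c("h", "alpha1", "alpha2"),
                 lower = c(0.001, 0.01, 0.01),
                 upper = c(0.999, 1, 1)),
    node3 = list(names = c("h", "alpha1", "alpha2", "alpha3"),
                 lower = c(0.001, rep(0.01, 3)),
                 upper = c(0.999, rep(1, 3))),
    stop_config("unknown model id: ", model_id)
  )
}

# Number of free parameters including decision noise.
model_k <- function(model_id) length(model_par_info(model_id)$names) + 1L

# Default conjugate prior over epoch means implied by the task design:
# means uniform on mean_range, moment-matched to a Gaussian.
task_prior <- function(cfg = task_config()) {
  list(mu_p = mean(cfg$mean_range),
       sigma_p = diff(cfg$mean_range) / sqrt(12))
}

#' Model predictions on a task sequence
#'
#' Deterministic one-step-ahead predictions of each candidate model for
#' every trial of a task sequence, conditioned only on the observed
#' outcomes (never on a subject's reports).  The filter state is reset
#' at each block boundary, and each block uses its own known noise
#' standard deviation.
#'
#' @param model_id One of `"full"`, `"node1"`, `"node2"`, `"node3"`.
#' @param params Named or positional numeric vector of model parameters
#'   (see `deltamix:::model_par_info`); decision noise is not part of it.
#' @param task A data frame with columns `x`, `block`, `noise_sd`
#'   (as produced by [generate_task()]).
#' @param prior List with `mu_p`, `sigma_p`: the Gaussian prior on epoch
#'   means.  Defaults to the moment-matched prior of [task_config()].
#' @param r_max Run-length truncation for the full model.
#' @return Numeric vector of predictions, one per trial; `pred[t]` is
#'   made before observing `task$x[t]`.
#' @export
task_predictions <- function(model_id, params, task,
                             prior = task_prior(), r_max = 120L) {
  info <- model_par_info(model_id)
  params <- as.numeric(params)
  if (length(params) != length(info$names))
    stop_config("model '", model_id, "' expects parameters: ",
                paste(info$names, collapse = ", "))
  if (any(params < info$lower - 1e-12) || any(params > info$upper + 1e-12))
    stop("parameters out of bounds for model '", model_id, "'",
         call. = FALSE)
  if (is.null(task$block)) task$block <- 1L
  if (is.null(task$noise_sd))
    stop_config("task data must carry a `noise_sd` column")
  pred <- numeric(nrow(task))
  for (b in unique(task$block)) {
    i <- which(task$block == b)
    sigma <- task$noise_sd[i[1L]]
    pred[i] <- switch(model_id,
      full = full_task_predict(task$x[i], sigma, params[1L],
                               prior$mu_p, prior$sigma_p, r_max),
      node1 = reduced_task_predict(task$x[i], sigma, h = 0,
                                   alphas = params[1L],
                                   prior$mu_p, prior$sigma_p),
      reduced_task_predict(task$x[i], sigma, h = params[1L],
                           alphas = params[-1L],
                           prior$mu_p, prior$sigma_p)
    )
  }
  pred
}

# Inlined Gaussian-mean run-length filter returning one-step-ahead
# predictions; identical math to full_filter_mat() but tuned for the
# single sequences hit thousands of times inside the likelihood.
full_task_predict <- function(x, sigma, h, mu_p, sigma_p, r_max = 120L) {
  nu0 <- sigma^2 / sigma_p^2
  chi0 <- mu_p * nu0
  R1 <- r_max + 1L
  nu <- nu0 + 0:r_max
  sds <- sigma * sqrt(1 + 1 / nu)
  lsds <- log(sds)
  lw <- c(0, rep(-Inf, r_max))
  chi <- rep(chi0, R1)
  lh <- if (h > 0) log(h) else -Inf
  l1h <- if (h < 1) log1p(-h) else -Inf
  T <- length(x)
  pred <- numeric(T)
  for (t in seq_len(T)) {
    m <- chi / nu
    pred[t] <- h * mu_p + (1 - h) * sum(exp(lw) * m)
    z <- (x[t] - m) / sds
    lp <- -0.5 * z * z - lsds
    grow <- lw + lp + l1h
    new_lw <- c(-Inf, grow[-R1])
    new_lw[2L] <- lse2(lh + lp[1L], grow[1L])
    new_lw[R1] <- lse2(new_lw[R1], grow[R1])
    mx <- max(new_lw)
    lw <- new_lw - (mx + log(sum(exp(new_lw - mx))))
    chi <- c(chi0, chi[-R1] + x[t])
  }
  pred
}

# Inlined reduced-model predictor for the task (Gaussian mean family).
reduced_task_predict <- function(x, sigma, h, alphas, mu_p, sigma_p) {
  nu0 <- sigma^2 / sigma_p^2
  l <- alphas_to_run_lengths(alphas, nu0)
  a <- pmin(1 / (l + nu0), 1)
  N <- length(l)
  if (N > 1L) {
    s <- diff(l)
    p_adv <- ifelse(s >= 1, 1 / s, 1)
    stay <- c(1 - p_adv, 1)
  }
  sds <- sigma * sqrt(1 + 1 / (nu0 + l))
  lsds <- log(sds)
  mu <- rep(mu_p, N)
  w <- c(1, rep(0, N - 1L))
  T <- length(x)
  pred <- numeric(T)
  for (t in seq_len(T)) {
    if (N == 1L) {
      inc <- 1
    } else {
      inc <- (1 - h) * stay * w
      inc[2:N] <- inc[2:N] + (1 - h) * p_adv * w[-N]
      inc[1L] <- inc[1L] + h
    }
    pred[t] <- sum(inc * mu)
    z <- (x[t] - mu) / sds
    ll <- -0.5 * z * z - lsds
    wn <- inc * exp(ll - max(ll))
    w <- wn / sum(wn)
    mu <- mu + a * (x[t] - mu)
  }
  pred
}

#' Simulate a subject performing the task
#'
#' Generates reported predictions as the model's deterministic
#' predictions plus i.i.d. Gaussian decision noise, clipped to the task
#' bounds.
#'
#' @inheritParams task_predictions
#' @param sigma_n Decision-noise standard deviation (`>= 0`).
#' @param seed Optional integer seed.
#' @param bounds Report bounds (task response range).
#' @return A `subject_data` data frame with columns `t`, `x`,
#'   `prediction`, `block`, `noise_sd`.
#' @export
simulate_subject <- function(model_id, params, task, sigma_n, seed = NULL,
                             prior = task_prior(), bounds = c(0, 300)) {
  if (sigma_n < 0) stop_config("`sigma_n` must be non-negative")
  pred <- task_predictions(model_id, params, task, prior)
  with_seed(seed, {
    rep <- pred + stats::rnorm(length(pred), 0, sigma_n)
    rep <- pmin(pmax(rep, bounds[1]), bounds[2])
    out <- data.frame(t = seq_len(nrow(task)), x = task$x,
                      prediction = rep, block = task$block %||% 1L,
                      noise_sd = task$noise_sd)
    class(out) <- c("subject_data", "data.frame")
    out
  })
}

#' Log likelihood of a subject's reports under a model
#'
#' The reports are modelled as the deterministic model predictions plus
#' Gaussian decision noise: `sum(dnorm(report, prediction, sigma_n,
#' log = TRUE))`.
#'
#' @inheritParams task_predictions
#' @param sigma_n Decision-noise standard deviation (`> 0`).
#' @param subject A `subject_data` data frame (columns `x`, `prediction`,
#'   `block`, `noise_sd`).
#' @return Scalar log likelihood.
#' @export
subject_loglik <- function(model_id, params, sigma_n, subject,
                           prior = task_prior()) {
  if (sigma_n <= 0) stop_config("`sigma_n` must be positive")
  pred <- task_predictions(model_id, params, subject, prior)
  sum(stats::dnorm(subject$prediction, pred, sigma_n, log = TRUE))
}

# Profiled log likelihood: sigma_n has the closed-form maximiser
# sqrt(mean squared residual).
profiled_loglik <- function(pred, reports) {
  n <- length(reports)
  rss <- mean((reports - pred)^2)
  rss <- max(rss, 1e-12)
  list(logL = -n / 2 * (log(2 * pi * rss) + 1), sigma_n = sqrt(rss))
}

#' Maximum-likelihood fit of one model to one subject
#'
#' Bounded multi-start maximisation of the subject log likelihood, with
#' the decision noise profiled out in closed form at every evaluation.
#' One-parameter models use golden-section search after a coarse grid;
#' multi-parameter models use Nelder-Mead on a logistic
#' reparameterisation from deterministic starting points.
#'
#' @inheritParams subject_loglik
#' @param n_starts Number of optimisation starts for multi-parameter
#'   models.
#' @param seed Seed for the jittered restarts (deterministic given the
#'   value).
#' @return A `fit_result` list: `model_id`, `params` (named, including
#'   `sigma_n`), `logL`, `bic`, `k`, `n_obs`, `converged`.
#' @export
fit_subject <- function(model_id, subject, prior = task_prior(),
                        n_starts = 6L, seed = 1L) {
  info <- model_par_info(model_id)
  n_par <- length(info$names)
  n_obs <- nrow(subject)
  if (n_obs < 10L * model_k(model_id))
    warning("subject has fewer than 10 observations per free parameter",
            call. = FALSE)
  reports <- subject$prediction
  nll <- function(par) {
    pred <- task_predictions(model_id, par, subject, prior)
    -profiled_loglik(pred, reports)$logL
  }
  if (n_par == 1L) {
    grid <- seq(info$lower, info$upper, length.out = 9L)[-c(1L, 9L)]
    vals <- vapply(grid, nll, numeric(1L))
    i <- which.min(vals)
    o <- stats::optimize(nll, c(grid[max(i - 1L, 1L)],
                                grid[min(i + 1L, length(grid))]),
                         tol = 1e-5)
    best_par <- o$minimum
    best_val <- o$objective
    if (vals[i] < best_val) {
      best_par <- grid[i]
      best_val <- vals[i]
    }
    converged <- TRUE
  } else {
    lo <- info$lower
    hi <- info$upper
    to_par <- function(z) lo + (hi - lo) * stats::plogis(z)
    to_z <- function(p) stats::qlogis(pmin(pmax((p - lo) / (hi - lo),
                                                1e-5), 1 - 1e-5))
    nll_z <- function(z) nll(to_par(z))
    starts <- fit_starts(model_id, n_starts, seed)
    best_par <- NULL
    best_val <- Inf
    converged <- FALSE
    for (p0 in starts) {
      o <- stats::optim(to_z(p0), nll_z, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-7))
      if (o$value < best_val) {
        best_val <- o$value
        best_par <- to_par(o$par)
        converged <- o$convergence == 0L
      }
    }
    # canonical order: learning rates decreasing
    best_par[-1L] <- sort(best_par[-1L], decreasing = TRUE)
  }
  pred <- task_predictions(model_id, best_par, subject, prior)
  prof <- profiled_loglik(pred, reports)
  k <- model_k(model_id)
  params <- c(stats::setNames(best_par, info$names),
              sigma_n = prof$sigma_n)
  structure(list(model_id = model_id, params = params, logL = prof$logL,
                 bic = -2 * prof$logL + k * log(n_obs), k = k,
                 n_obs = n_obs, converged = converged),
            class = "fit_result")
}

# Deterministic starting points spanning the box, plus seeded jitter.
fit_starts <- function(model_id, n_starts, seed) {
  base <- switch(model_id,
    node2 = list(c(0.1, 0.9, 0.4), c(0.3, 0.95, 0.6), c(0.05, 0.7, 0.2),
                 c(0.2, 0.99, 0.15)),
    node3 = list(c(0.1, 0.95, 0.7, 0.4), c(0.2, 0.9, 0.5, 0.2),
                 c(0.05, 0.99, 0.8, 0.5), c(0.3, 0.85, 0.6, 0.3)),
    list()
  )
  if (length(base) < n_starts) {
    info <- model_par_info(model_id)
    extra <- with_seed(substream_seed(seed, 17L), {
      lapply(seq_len(n_starts - length(base)), function(i) {
        p <- stats::runif(length(info$names), info$lower, info$upper)
        p[-1L] <- sort(p[-1L], decreasing = TRUE)
        p
      })
    })
    base <- c(base, extra)
  }
  base[seq_len(n_starts)]
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_id, " logL =", round(x$logL, 2),
      " BIC =", round(x$bic, 2), "\n  ",
      paste(names(x$params), signif(x$params, 3), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Random-effects group-level model selection
#'
#' Variational Dirichlet-multinomial estimation of the population
#' frequencies of a set of models from per-subject log model evidence
#' (here the BIC approximation, `-BIC/2`), following the random-effects
#' scheme of hierarchical group studies.  Returns the model probability
#' (the chance that a randomly chosen subject uses each model) and the
#' exceedance probability (the chance that each model is the most
#' frequent in the population), the latter estimated from Monte-Carlo
#' draws of the fitted Dirichlet.
#'
#' @param log_evidence Matrix of log evidences, subjects in rows, models
#'   in columns (`>= 2` of each).
#' @param alpha0 Prior Dirichlet concentration per model.
#' @param n_draws Dirichlet draws for the exceedance probabilities.
#' @param seed Optional seed for those draws.
#' @param max_iter,tol Convergence controls for the fixed-point
#'   iteration.
#' @return A `bms_result` list: `model_prob`, `exceedance`, `alpha`,
#'   `per_subject` (posterior model assignment probabilities).
#' @export
group_bms <- function(log_evidence, alpha0 = 1, n_draws = 1e5,
                      seed = NULL, max_iter = 500L, tol = 1e-9) {
  lme <- as.matrix(log_evidence)
  n <- nrow(lme)
  K <- ncol(lme)
  if (n < 2L || K < 2L)
    stop_config("group_bms needs at least 2 subjects and 2 models")
  alpha <- rep(alpha0, K)
  for (iter in seq_len(max_iter)) {
    lu <- sweep(lme, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1L, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  xp <- with_seed(seed, {
    g <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                n_draws, K)
    tabulate(max.col(g), nbins = K) / n_draws
  })
  structure(list(model_prob = alpha / sum(alpha), exceedance = xp,
                 alpha = alpha, per_subject = u),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n  model_prob: ",
      paste(signif(x$model_prob, 3), collapse = ", "),
      "\n  exceedance: ",
      paste(signif(x$exceedance, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Draw plausible generating parameters for a model
#'
#' Truncated-Gaussian draws centred on the group-mean parameter values
#' obtained when these models are fitted to human subjects on this task
#' (hazard rates of a few hundredths to a few tenths; the fastest
#' learning rate close to one with slower rates below it; decision noise
#' of order the observation noise), with across-subject spreads matching
#' the reported standard errors scaled to the group size.  Used as the
#' parameter pool for recovery and confusion studies.
#'
#' @param model_id Candidate model id.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A data frame with one row per draw (columns: the model's
#'   parameters plus `sigma_n`); learning rates are ordered fastest
#'   first.
#' @export
sample_task_params <- function(model_id, n = 1L, seed = NULL) {
  with_seed(seed, {
    # group mean and across-subject sd (sem * sqrt(30)), truncated
    rtn <- function(mean, sd, lo, hi) {
      q <- stats::runif(n, stats::pnorm(lo, mean, sd),
                        stats::pnorm(hi, mean, sd))
      stats::qnorm(q, mean, sd)
    }
    df <- switch(model_id,
      full  = data.frame(h = rtn(0.04, 0.055, 0.005, 0.5),
                         sigma_n = rtn(20.2, 2.9, 2, 40)),
      node1 = data.frame(alpha1 = rtn(0.88, 0.055, 0.4, 1),
                         sigma_n = rtn(8.7, 3.9, 2, 25)),
      node2 = data.frame(h = rtn(0.27, 0.22, 0.01, 0.8),
                         alpha1 = rtn(0.94, 0.055, 0.6, 1),
                         alpha2 = rtn(0.53, 0.16, 0.05, 0.9),
                         sigma_n = rtn(7.3, 3.6, 2, 25)),
      node3 = data.frame(h = rtn(0.12, 0.16, 0.01, 0.8),
                         alpha1 = rtn(0.96, 0.055, 0.6, 1),
                         alpha2 = rtn(0.82, 0.16, 0.3, 1),
                         alpha3 = rtn(0.52, 0.16, 0.05, 0.9),
                         sigma_n = rtn(7.0, 3.6, 2, 25)),
      stop_config("unknown model id: ", model_id)
    )
    a_cols <- grep("^alpha", names(df))
    if (length(a_cols) > 1L) {
      a <- t(apply(df[a_cols], 1L, sort, decreasing = TRUE))
      # keep rates distinct enough to name them
      for (j in 2:ncol(a)) a[, j] <- pmin(a[, j], a[, j - 1L] - 0.02)
      df[a_cols] <- pmax(a, 0.02)
    }
    df
  })
}

#' Model-recovery confusion matrices
#'
#' Simulates subjects from each candidate model (parameters drawn with
#' [sample_task_params()]), refits every candidate to every simulated
#' subject, and aggregates the BIC-approximated evidence per generating
#' model with [group_bms()].  Rows index the generating model, columns
#' the fitted model.
#'
#' @param model_ids Candidate model ids (default all four).
#' @param n_subjects Simulated subjects per generating model.
#' @param n_blocks Task blocks per subject.
#' @param cfg A [task_config()].
#' @param seed Master seed; every subject, parameter draw and fit is
#'   deterministically derived from it.
#' @param n_starts Optimisation starts per fit.
#' @return A list of class `confusion_result`: `model_probability` and
#'   `exceedance` matrices, plus `fits` (per generating model, the BIC
#'   log-evidence matrices).
#' @export
confusion_matrices <- function(model_ids = task_model_ids(),
                               n_subjects = 8L, n_blocks = 2L,
                               cfg = task_config(), seed = 1L,
                               n_starts = 4L) {
  if (n_subjects < 2L) stop_config("need at least 2 subjects per model")
  K <- length(model_ids)
  prior <- task_prior(cfg)
  mp <- xp <- matrix(NA_real_, K, K,
                     dimnames = list(generated = model_ids,
                                     fitted = model_ids))
  lme_all <- list()
  for (gi in seq_along(model_ids)) {
    gen <- model_ids[gi]
    pars <- sample_task_params(gen, n_subjects,
                               seed = substream_seed(seed, 1000L + gi))
    lme <- matrix(NA_real_, n_subjects, K)
    for (s in seq_len(n_subjects)) {
      sseed <- substream_seed(seed, gi * 1e4 + s)
      task <- generate_task(cfg, n_blocks, seed = sseed)
      p <- as.numeric(pars[s, setdiff(names(pars), "sigma_n")])
      subj <- simulate_subject(gen, p, task, pars$sigma_n[s],
                               seed = sseed + 1, prior = prior)
      for (fi in seq_along(model_ids)) {
        fit <- try(fit_subject(model_ids[fi], subj, prior,
                               n_starts = n_starts, seed = sseed),
                   silent = TRUE)
        if (!inherits(fit, "try-error")) lme[s, fi] <- -fit$bic / 2
      }
    }
    ok <- stats::complete.cases(lme)
    if (sum(ok) < n_subjects)
      warning(sum(!ok), " subject(s) dropped for generating model ",
              gen, call. = FALSE)
    bms <- group_bms(lme[ok, , drop = FALSE],
                     seed = substream_seed(seed, 2000L + gi))
    mp[gi, ] <- bms$model_prob
    xp[gi, ] <- bms$exceedance
    lme_all[[gen]] <- lme
  }
  structure(list(model_probability = mp, exceedance = xp,
                 fits = lme_all),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat("<confusion_result> model probability:\n")
  print(round(x$model_probability, 3))
  cat("exceedance probability:\n")
  print(round(x$exceedance, 3))
  invisible(x)
}
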