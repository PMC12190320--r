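#' Statistical model for population (mixed-effects) fitting
#'
#' Declares which structural parameters and observable scale factors are
#' estimated.  Every estimated parameter carries a log-normal (or, for
#' unit-interval parameters, logit-normal) random effect:
#' `theta_i = h(h^{-1}(theta_pop) + eta_i)`, `eta_i ~ N(0, omega^2)`.
#' Observation error is proportional: Gaussian on the log scale with one SD
#' per observable.
#'
#' @param random named numeric vector of initial random-effect SDs
#'   (transformed scale); the names select the estimated parameters, which
#'   may be structural parameters or the scale factors `c_si`,
#'   `c_sigma_beta`.
#' @param observables which observables enter the likelihood.
#' @param error_init initial log-scale error SD per observable.
#' @return a list of class `dmprog_stat`.
#' @export
stat_model <- function(random = c(gX1 = 0.2, gX2 = 0.2),
                       observables = c("fpg", "fpi", "matsuda", "igi"),
                       error_init = NULL) {
  observables <- match.arg(observables, c("fpg", "fpi", "matsuda", "igi"),
                           several.ok = TRUE)
  if (!length(names(random)) || any(!nzchar(names(random))))
    stop("random must be a named vector")
  if (any(random < 0)) stop("random-effect SDs must be >= 0")
  if (is.null(error_init))
    error_init <- stats::setNames(rep(0.15, length(observables)), observables)
  structure(list(random = random, observables = observables,
                 error_init = error_init),
            class = "dmprog_stat")
}

# --- subject construction ---------------------------------------------------

# A fit subject is list(y, predict): y is the matrix of log-observations
# (visits x observables, NA = missing); predict(theta) maps a named vector of
# natural-scale estimated-parameter values to the matching log-prediction
# matrix.
.make_fit_subject <- function(subject, spec, params, scales, stat) {
  v <- subject$visits
  obs <- stat$observables
  y <- log(as.matrix(v[obs]))
  vt <- v$t_days
  cov <- subject$cov
  age0 <- subject$age0
  g0 <- v$fpg[1]
  if (!is.finite(g0)) g0 <- 88
  g0 <- min(max(g0, 50), 300)
  X0 <- excess_ffa_index(pfat_at(cov, vt[1]))
  est <- names(stat$random)
  force(spec); force(params); force(scales)
  predict_fn <- function(theta) {
    p <- params; s <- scales
    for (k in names(theta)) {
      if (k %in% names(s)) s[[k]] <- theta[[k]] else p[[k]] <- theta[[k]]
    }
    # same set-point convention as the generator: anchor the growth-function
    # lower root at the subject's baseline glucose
    half <- p$G1 - beta_growth_roots(p)[1]
    p$G1 <- g0 + half
    p$Gb1 <- g0
    p$Gb2 <- g0 + 2 * half
    init <- .initial_state(spec, p, g0, X0, age0)
    times <- vt
    if (times[1] > 0) times <- c(0, times)
    traj <- integrate_model(spec, p, cov, times = times, init = init,
                            rtol = 1e-6, atol = 1e-6)
    ob <- model_to_observables(traj, vt, unlist(s))
    log(as.matrix(ob[obs]))
  }
  list(y = y, predict = predict_fn, id = subject$subject_id)
}

.loglik_obs <- function(pred, y, err_sd) {
  if (is.null(pred) || any(!is.finite(pred[!is.na(y)]))) return(-Inf)
  ll <- 0
  for (j in seq_len(ncol(y))) {
    ok <- !is.na(y[, j])
    if (any(ok))
      ll <- ll + sum(stats::dnorm(y[ok, j], pred[ok, j], err_sd[j], log = TRUE))
  }
  ll
}

.safe_predict <- function(subject, theta) {
  tryCatch(subject$predict(theta), error = function(e) NULL)
}

.theta_from_phi <- function(phi, est_names) {
  stats::setNames(vapply(seq_along(est_names),
                         function(r) phi_to_param(phi[r], est_names[r]),
                         numeric(1)), est_names)
}

# --- SAEM engine ------------------------------------------------------------

#' Control settings for the SAEM estimator
#'
#' @param n_burn exploration-phase iterations (step size 1, annealed
#'   variances).
#' @param n_smooth smoothing-phase iterations (step size `1/j`).
#' @param n_rw random-walk Metropolis passes per iteration.
#' @param n_mc importance-sampling draws per subject for the marginal
#'   log-likelihood.
#' @param seed RNG seed used for the whole fit.
#' @param adapt_every proposal-scale adaptation interval (iterations).
#' @param anneal variance annealing factor in the exploration phase.
#' @param min_omega floor for random-effect SDs.
#' @param verbose print progress.
#' @return list of class `dmprog_saem_control`.
#' @export
saem_control <- function(n_burn = 150, n_smooth = 100, n_rw = 1, n_mc = 500,
                         seed = 1, adapt_every = 20, anneal = 0.95,
                         min_omega = 1e-3, verbose = FALSE) {
  structure(as.list(environment()), class = "dmprog_saem_control")
}

#' SAEM fit of a nonlinear mixed-effects model (engine)
#'
#' Stochastic-approximation EM: per iteration, individual random effects are
#' refreshed by Metropolis-Hastings (an independent prior-proposal kernel
#' followed by adaptive component-wise random walks), sufficient statistics
#' are updated with the stochastic-approximation step, and the population
#' parameters, random-effect variances and error variances are updated in
#' closed form.  An exploration phase with simulated annealing of the
#' variances precedes the smoothing phase.
#'
#' This is the generic engine; [fit_population()] builds the ODE-model
#' subjects and calls it.  Subjects are lists with a log-observation matrix
#' `y` and a `predict(theta)` closure (see [stat_model()] for the parameter
#' conventions).
#'
#' @param subjects list of fit subjects.
#' @param phi_pop_init named initial population values (transformed scale).
#' @param omega_init named initial random-effect SDs.
#' @param err_init named initial error SDs (one per column of `y`).
#' @param control a [saem_control()].
#' @return list with population estimates (`phi_pop`, `theta_pop`, `omega`,
#'   `error_sd`), the per-subject last `eta` draws, convergence traces and
#'   diagnostics.
#' @export
saem_fit <- function(subjects, phi_pop_init, omega_init, err_init,
                     control = saem_control()) {
  set.seed(control$seed)
  est_names <- names(phi_pop_init)
  d <- length(est_names)
  n <- length(subjects)
  n_obs_col <- ncol(subjects[[1]]$y)
  n_iter <- control$n_burn + control$n_smooth

  phi_pop <- phi_pop_init
  omega <- pmax(omega_init[est_names], control$min_omega)
  err_sd <- pmax(err_init, 1e-4)

  eta <- matrix(0, n, d)
  step <- matrix(0.3, n, d)          # RW proposal scales, adapted
  acc <- matrix(0, n, d); prop <- matrix(0, n, d)
  cur_ll <- rep(NA_real_, n)
  cur_pred <- vector("list", n)

  # initialise likelihoods at eta = 0
  for (i in seq_len(n)) {
    pred <- .safe_predict(subjects[[i]], .theta_from_phi(phi_pop, est_names))
    cur_pred[[i]] <- pred
    cur_ll[i] <- .loglik_obs(pred, subjects[[i]]$y, err_sd)
  }

  H1 <- matrix(rep(phi_pop, each = n), n, d)
  H2 <- H1^2
  Rss <- stats::setNames(rep(0.02, n_obs_col), colnames(subjects[[1]]$y))
  n_per_col <- colSums(!is.na(do.call(rbind, lapply(subjects, `[[`, "y"))))

  trace_phi <- matrix(NA_real_, n_iter, d)
  trace_omega <- matrix(NA_real_, n_iter, d)

  for (k in seq_len(n_iter)) {
    gamma <- if (k <= control$n_burn) 1 else 1 / (k - control$n_burn)
    for (i in seq_len(n)) {
      y_i <- subjects[[i]]$y
      # kernel A: independent proposal from the prior
      eta_p <- stats::rnorm(d, 0, omega)
      pred_p <- .safe_predict(subjects[[i]],
                              .theta_from_phi(phi_pop + eta_p, est_names))
      ll_p <- .loglik_obs(pred_p, y_i, err_sd)
      if (is.finite(ll_p) && log(stats::runif(1)) < ll_p - cur_ll[i]) {
        eta[i, ] <- eta_p; cur_ll[i] <- ll_p; cur_pred[[i]] <- pred_p
      }
      # kernel B: component-wise random walks
      for (pass in seq_len(control$n_rw)) {
        for (r in seq_len(d)) {
          eta_p <- eta[i, ]
          eta_p[r] <- eta_p[r] + stats::rnorm(1, 0, step[i, r] * omega[r])
          pred_p <- .safe_predict(subjects[[i]],
                                  .theta_from_phi(phi_pop + eta_p, est_names))
          ll_new <- .loglik_obs(pred_p, y_i, err_sd)
          lp_new <- ll_new - 0.5 * sum((eta_p / omega)^2)
          lp_old <- cur_ll[i] - 0.5 * sum((eta[i, ] / omega)^2)
          prop[i, r] <- prop[i, r] + 1
          if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp_old) {
            eta[i, ] <- eta_p
            cur_ll[i] <- ll_new
            cur_pred[[i]] <- pred_p
            acc[i, r] <- acc[i, r] + 1
          }
        }
      }
      # SA sufficient statistics
      phi_i <- phi_pop + eta[i, ]
      H1[i, ] <- (1 - gamma) * H1[i, ] + gamma * phi_i
      H2[i, ] <- (1 - gamma) * H2[i, ] + gamma * phi_i^2
    }
    # residual sufficient statistic
    rss_k <- stats::setNames(numeric(n_obs_col), names(Rss))
    for (i in seq_len(n)) {
      y_i <- subjects[[i]]$y
      p_i <- cur_pred[[i]]
      if (is.null(p_i)) next
      for (j in seq_len(n_obs_col)) {
        ok <- !is.na(y_i[, j])
        rss_k[j] <- rss_k[j] + sum((y_i[ok, j] - p_i[ok, j])^2)
      }
    }
    Rss <- (1 - gamma) * Rss + gamma * rss_k

    # M-step (closed form)
    mu_new <- colMeans(H1)
    var_new <- pmax(colMeans(H2) - mu_new^2, control$min_omega^2)
    err_new <- sqrt(pmax(Rss / pmax(n_per_col, 1), 1e-8))
    if (k <= control$n_burn) {
      omega <- pmax(sqrt(var_new), control$anneal * omega)
      err_sd <- pmax(err_new, control$anneal * err_sd)
    } else {
      omega <- sqrt(var_new)
      err_sd <- err_new
    }
    # recompute current likelihoods under moved population parameters
    delta_phi <- mu_new - phi_pop
    phi_pop <- mu_new
    if (max(abs(delta_phi)) > 0) {
      for (i in seq_len(n)) {
        pred <- .safe_predict(subjects[[i]],
                              .theta_from_phi(phi_pop + eta[i, ], est_names))
        if (!is.null(pred)) {
          cur_pred[[i]] <- pred
          cur_ll[i] <- .loglik_obs(pred, subjects[[i]]$y, err_sd)
        }
      }
    }
    trace_phi[k, ] <- phi_pop
    trace_omega[k, ] <- omega
    if (k %% control$adapt_every == 0 && k <= control$n_burn) {
      rate <- ifelse(prop > 0, acc / prop, 0.3)
      step <- pmin(pmax(step * ifelse(rate > 0.45, 1.5,
                                      ifelse(rate < 0.15, 0.6, 1)), 0.02), 5)
      acc[] <- 0; prop[] <- 0
    }
    if (control$verbose && k %% 25 == 0)
      message(sprintf("SAEM iter %d/%d: %s", k, n_iter,
                      paste(sprintf("%s=%.3g", est_names,
                                    .theta_from_phi(phi_pop, est_names)),
                            collapse = " ")))
  }

  tail_rows <- max(control$n_burn + 1, n_iter - 49):n_iter
  drift <- apply(trace_phi[tail_rows, , drop = FALSE], 2,
                 function(x) diff(range(x)))
  list(phi_pop = stats::setNames(phi_pop, est_names),
       theta_pop = .theta_from_phi(phi_pop, est_names),
       omega = stats::setNames(omega, est_names),
       error_sd = err_sd,
       eta = eta, est_names = est_names,
       trace_phi = trace_phi, trace_omega = trace_omega,
       converged = all(drift < 0.1),
       accept_rate = ifelse(prop > 0, acc / prop, NA))
}

# --- population fit front end ----------------------------------------------

#' Fit a population model to a longitudinal cohort
#'
#' Estimates population parameters, random-effect variances and error
#' variances of a progression model from a cohort, either by SAEM
#' (`method = "saem"`) or, with random effects suppressed, by direct pooled
#' maximum likelihood (`method = "pooled"`, Nelder-Mead on the transformed
#' parameters with analytically profiled error variances).  The marginal
#' log-likelihood is then estimated by importance sampling around the
#' empirical-Bayes modes, and the Bayesian Information Criterion is
#' `-2 logL + k log(n)` with `n` the number of subjects (set
#' `bic_n = "observations"` for the total-observation convention).
#'
#' @param cohort a `dmprog_cohort`.
#' @param spec structural model.
#' @param stat a [stat_model()].
#' @param params frozen population parameters (estimated ones are
#'   initialised from here).
#' @param scales frozen/initial observable scale factors.
#' @param control a [saem_control()].
#' @param method `"saem"` or `"pooled"`.
#' @param bic_n sample-size convention for the BIC penalty.
#' @return a `dmprog_fit`: fixed effects (natural scale), `omega`,
#'   `error_sd`, `logL`, `logL_se`, `k`, `n`, `bic`, per-subject
#'   empirical-Bayes modes `eb`, convergence diagnostics.
#' @export
fit_population <- function(cohort, spec, stat = stat_model(),
                           params = default_params(),
                           scales = c(c_si = 3.4, c_sigma_beta = 2.4e-05),
                           control = saem_control(),
                           method = c("saem", "pooled"),
                           bic_n = c("subjects", "observations")) {
  method <- match.arg(method)
  bic_n <- match.arg(bic_n)
  if (length(cohort) < 2) stop("need at least 2 subjects")
  nv <- vapply(cohort, function(s) nrow(s$visits), integer(1))
  if (any(nv < 3)) stop("every subject needs at least 3 visits")
  est_names <- names(stat$random)
  n_obs_total <- sum(vapply(cohort, function(s)
    sum(!is.na(as.matrix(s$visits[stat$observables]))), integer(1)))
  if (length(est_names) * 2 + length(stat$observables) > n_obs_total)
    warning("more estimated parameters than observations; fit may be unidentifiable")

  subjects <- lapply(cohort, .make_fit_subject, spec = spec, params = params,
                     scales = scales, stat = stat)
  phi_init <- vapply(est_names, function(k) {
    v <- if (k %in% names(scales)) scales[[k]] else params[[k]]
    param_to_phi(v, k)
  }, numeric(1))
  names(phi_init) <- est_names

  if (method == "pooled") {
    res <- .pooled_fit(subjects, phi_init, stat, control)
    eta_hat <- matrix(0, length(subjects), length(est_names))
    omega <- stats::setNames(rep(0, length(est_names)), est_names)
    ll <- res$logL; ll_se <- 0
    k_par <- length(est_names) + length(stat$observables)
    err_sd <- res$error_sd
    theta_pop <- res$theta_pop
    converged <- res$converged
    traces <- NULL
  } else {
    res <- saem_fit(subjects, phi_init, stat$random, stat$error_init, control)
    theta_pop <- res$theta_pop
    omega <- res$omega
    err_sd <- res$error_sd
    k_par <- 2 * length(est_names) + length(stat$observables)
    converged <- res$converged
    traces <- list(phi = res$trace_phi, omega = res$trace_omega)
    eta_hat <- NULL   # filled below from EB modes
    ll <- NULL
  }

  fit <- structure(list(
    fixed = theta_pop, omega = omega, error_sd = err_sd,
    est_names = est_names, spec = spec, stat = stat,
    params = params, scales = scales,
    n = length(cohort), k = k_par, bic_n = bic_n,
    converged = converged, traces = traces, control = control),
    class = "dmprog_fit")

  if (method == "saem") {
    eb <- estimate_random_effects(fit, cohort)
    fit$eb <- eb
    lik <- log_likelihood(fit, cohort, n_mc = control$n_mc,
                          seed = control$seed + 1, eb = eb)
    fit$logL <- lik$logL; fit$logL_se <- lik$se
  } else {
    fit$eb <- eta_hat
    fit$logL <- ll; fit$logL_se <- ll_se
  }
  n_bic <- if (bic_n == "subjects") length(cohort) else n_obs_total
  fit$bic <- bic(fit$logL, fit$k, n_bic)
  if (!fit$converged)
    warning("fit flagged as non-converged; inspect traces")
  fit
}

.pooled_fit <- function(subjects, phi_init, stat, control) {
  est_names <- names(phi_init)
  nll <- function(phi) {
    theta <- .theta_from_phi(phi, est_names)
    rss <- stats::setNames(numeric(length(stat$observables)), stat$observables)
    nobs <- rss
    for (s in subjects) {
      pred <- .safe_predict(s, theta)
      if (is.null(pred)) return(1e10)
      for (j in seq_along(stat$observables)) {
        ok <- !is.na(s$y[, j])
        rss[j] <- rss[j] + sum((s$y[ok, j] - pred[ok, j])^2)
        nobs[j] <- nobs[j] + sum(ok)
      }
    }
    # profiled Gaussian likelihood per observable
    sum(nobs / 2 * (log(2 * pi * pmax(rss / nobs, 1e-12)) + 1))
  }
  if (length(phi_init) == 1) {
    o <- stats::optimize(function(p) nll(stats::setNames(p, est_names)),
                         phi_init + c(-4, 4), tol = 1e-10)
    opt <- list(par = stats::setNames(o$minimum, est_names),
                value = o$objective, convergence = 0L)
  } else {
    opt <- stats::optim(phi_init, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
  }
  theta <- .theta_from_phi(opt$par, est_names)
  # recover profiled error SDs
  rss <- stats::setNames(numeric(length(stat$observables)), stat$observables)
  nobs <- rss
  for (s in subjects) {
    pred <- .safe_predict(s, theta)
    for (j in seq_along(stat$observables)) {
      ok <- !is.na(s$y[, j])
      rss[j] <- rss[j] + sum((s$y[ok, j] - pred[ok, j])^2)
      nobs[j] <- nobs[j] + sum(ok)
    }
  }
  list(theta_pop = theta, error_sd = sqrt(rss / pmax(nobs, 1)),
       logL = -opt$value, converged = opt$convergence == 0)
}

# --- empirical Bayes and marginal likelihood --------------------------------

.eb_mode_subject <- function(subject, phi_pop, omega, err_sd, est_names) {
  d <- length(est_names)
  if (all(is.na(subject$y))) return(rep(0, d))
  if (all(omega <= 1e-8)) return(rep(0, d))
  neg_post <- function(eta) {
    pred <- .safe_predict(subject, .theta_from_phi(phi_pop + eta, est_names))
    ll <- .loglik_obs(pred, subject$y, err_sd)
    if (!is.finite(ll)) return(1e10)
    -ll + 0.5 * sum((eta / omega)^2)
  }
  if (d == 1) {
    opt <- stats::optimize(function(e) neg_post(e), c(-8, 8) * max(omega, 0.5),
                           tol = 1e-8)
    if (!is.finite(opt$objective) || opt$objective >= 1e10)
      warning("empirical-Bayes optimisation failed for subject ", subject$id)
    return(opt$minimum)
  }
  opt <- stats::optim(rep(0, d), neg_post, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  if (!is.finite(opt$value) || opt$value >= 1e10)
    warning("empirical-Bayes optimisation failed for subject ", subject$id)
  opt$par
}

#' Empirical-Bayes modes of the individual random effects
#'
#' With population parameters fixed, returns the per-subject posterior modes
#' of `eta_i` given the subject's observations.  A subject with no
#' observations gets the prior mode, zero.
#'
#' @param fit a `dmprog_fit`.
#' @param cohort the cohort (defaults must match the fit's structure).
#' @return matrix (subjects x estimated parameters) of modes.
#' @export
estimate_random_effects <- function(fit, cohort) {
  subjects <- lapply(cohort, .make_fit_subject, spec = fit$spec,
                     params = fit$params, scales = fit$scales, stat = fit$stat)
  phi_pop <- vapply(fit$est_names, function(k)
    param_to_phi(fit$fixed[[k]], k), numeric(1))
  eb <- do.call(rbind, lapply(subjects, .eb_mode_subject, phi_pop = phi_pop,
                              omega = fit$omega, err_sd = fit$error_sd,
                              est_names = fit$est_names))
  colnames(eb) <- fit$est_names
  eb
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

.num_hessian <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) for (j in i:d) {
    xi <- x; xi[i] <- xi[i] + h
    xj <- x; xj[j] <- xj[j] + h
    xij <- xi; xij[j] <- xij[j] + h
    H[i, j] <- H[j, i] <- (f(xij) - f(xi) - f(xj) + f0) / h^2
  }
  H
}

#' Importance-sampling marginal log-likelihood
#'
#' Estimates the marginal log-likelihood of a population fit by importance
#' sampling around each subject's empirical-Bayes mode, with a Gaussian
#' proposal whose covariance comes from the numerical Hessian of the
#' negative log-posterior (inflated for safety).  Returns the estimate and a
#' delta-method Monte-Carlo standard error, which shrinks like
#' `1/sqrt(n_mc)`.
#'
#' @param fit a `dmprog_fit`.
#' @param cohort the cohort.
#' @param n_mc importance draws per subject.
#' @param seed RNG seed.
#' @param eb optional precomputed matrix of empirical-Bayes modes.
#' @return list with `logL`, `se`, and the per-subject contributions.
#' @export
log_likelihood <- function(fit, cohort, n_mc = 1000, seed = 1, eb = NULL) {
  subjects <- lapply(cohort, .make_fit_subject, spec = fit$spec,
                     params = fit$params, scales = fit$scales, stat = fit$stat)
  phi_pop <- vapply(fit$est_names, function(k) param_to_phi(fit$fixed[[k]], k),
                    numeric(1))
  marginal_loglik(subjects, phi_pop, fit$omega, fit$error_sd, fit$est_names,
                  n_mc = n_mc, seed = seed, eb = eb)
}

#' @rdname log_likelihood
#' @param subjects engine-level fit subjects (see [saem_fit()]).
#' @param phi_pop named population values on the transformed scale.
#' @param omega random-effect SDs.
#' @param err_sd error SDs per observable column.
#' @param est_names names of the estimated parameters.
#' @export
marginal_loglik <- function(subjects, phi_pop, omega, err_sd, est_names,
                            n_mc = 1000, seed = 1, eb = NULL) {
  d <- length(est_names)
  omega <- pmax(omega, 0)
  if (is.null(eb))
    eb <- do.call(rbind, lapply(subjects, .eb_mode_subject, phi_pop = phi_pop,
                                omega = omega, err_sd = err_sd,
                                est_names = est_names))

  per <- vapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    # seed per subject id so the estimate is invariant to subject ordering
    sid <- suppressWarnings(as.integer(s$id))
    set.seed(seed + (if (is.na(sid)) i else sid))
    if (all(is.na(s$y))) return(c(0, 0))
    if (all(omega <= 1e-8)) {   # degenerate prior: ordinary log-likelihood
      pred <- .safe_predict(s, .theta_from_phi(phi_pop, est_names))
      return(c(.loglik_obs(pred, s$y, err_sd), 0))
    }
    mode <- eb[i, ]
    log_joint <- function(eta) {
      pred <- .safe_predict(s, .theta_from_phi(phi_pop + eta, est_names))
      ll <- .loglik_obs(pred, s$y, err_sd)
      if (!is.finite(ll)) return(-Inf)
      ll + sum(stats::dnorm(eta, 0, omega, log = TRUE))
    }
    H <- .num_hessian(function(e) -log_joint(e), mode)
    Sig <- tryCatch(solve(H), error = function(e) NULL)
    ok <- !is.null(Sig) && all(is.finite(Sig)) &&
      all(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values > 0)
    if (!ok) Sig <- diag(omega^2, d)
    Sig <- 1.5 * Sig                       # inflate proposal for tail cover
    L <- chol(Sig)
    z <- matrix(stats::rnorm(n_mc * d), n_mc, d)
    draws <- sweep(z %*% L, 2, mode, "+")
    log_q <- -0.5 * rowSums((z)^2) - sum(log(diag(L))) - d / 2 * log(2 * pi)
    log_w <- apply(draws, 1, log_joint) - log_q
    if (all(!is.finite(log_w)))
      stop("degenerate importance proposal for subject ", s$id,
           "; increase n_mc or check the fit")
    lw <- log_w[is.finite(log_w)]
    if (length(lw) < n_mc) log_w[!is.finite(log_w)] <- -Inf
    l_i <- .logsumexp(log_w) - log(n_mc)
    w_norm <- exp(log_w - .logsumexp(log_w))
    se_i <- sqrt(max(sum(w_norm^2) - 1 / n_mc, 0))
    c(l_i, se_i)
  }, numeric(2))

  list(logL = sum(per[1, ]), se = sqrt(sum(per[2, ]^2)),
       per_subject = per[1, ])
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 logL + k log(n)`.
#'
#' @param logL maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (subjects, by this package's default convention).
#' @return the criterion value.
#' @examples
#' bic(-100, 5, 17)   # 200 + 5 log 17
#' @export
bic <- function(logL, k, n) {
  stopifnot(n >= 1, k >= 0)
  -2 * logL + k * log(n)
}

#' @export
print.dmprog_fit <- function(x, ...) {
  cat("<dmprog population fit> n =", x$n, "subjects\n")
  cat("  fixed effects:\n")
  for (k in x$est_names)
    cat(sprintf("    %-14s %.4g  (omega %.3g)\n", k, x$fixed[[k]], x$omega[[k]]))
  cat("  error SD (log scale):",
      paste(sprintf("%s=%.3g", names(x$error_sd), x$error_sd), collapse = ", "), "\n")
  cat(sprintf("  logL %.2f (SE %.2f), k = %d, BIC %.2f\n",
              x$logL, x$logL_se, x$k, x$bic))
  invisible(x)
}
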