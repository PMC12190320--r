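#' Insulin-sensitivity forcing protocols
#'
#' A forcing multiplies the model's insulin-sensitivity function by a
#' prescribed time course: a transient step (`1 - drop` between `t_on` and
#' `t_off`) or a gradual exponential decline
#' `1 - drop * (1 - exp(-t/tau))` that approaches `1 - drop`.
#'
#' @param mode `"step"` or `"exponential"` (or `"none"`).
#' @param drop fractional drop in \[0, 1).
#' @param t_on,t_off step window (days).
#' @param tau exponential time constant (days).
#' @return an object of class `dmprog_forcing`.
#' @export
si_forcing <- function(mode = c("none", "step", "exponential"), drop = 0,
                       t_on = 10, t_off = 12, tau = 600) {
  mode <- match.arg(mode)
  if (drop < 0 || drop >= 1) stop("drop must lie in [0, 1)")
  if (mode == "step" && t_off <= t_on) stop("t_off must exceed t_on")
  if (mode == "exponential" && tau <= 0) stop("tau must be > 0")
  structure(list(mode = mode, drop = drop, t_on = t_on, t_off = t_off, tau = tau),
            class = "dmprog_forcing")
}

#' @rdname si_forcing
#' @param forcing a forcing object (or `NULL`).
#' @param t time(s) in days.
#' @export
si_forcing_multiplier <- function(forcing, t) {
  if (is.null(forcing) || forcing$mode == "none") return(rep(1, length(t)))
  if (forcing$mode == "step")
    ifelse(t >= forcing$t_on & t <= forcing$t_off, 1 - forcing$drop, 1)
  else
    1 - forcing$drop * (1 - exp(-t / forcing$tau))
}

.default_init <- function(spec, params) {
  init <- c(G = 80, I = 15, beta = 300)
  if (spec$state_dimension == 4) {
    Ca <- calcium(80, params)
    init <- c(init, sigma = sigma_steady_state(80, Ca, 0, params))
  }
  init
}

#' Integrate a progression model over time
#'
#' Solves the model ODEs with the adaptive implicit/explicit `lsoda` solver
#' (the glucose-insulin subsystem relaxes in hours while beta-cell mass
#' evolves over years, so the system is moderately stiff).  Percent body fat
#' is passed as a linearly interpolated forcing held constant beyond the last
#' knot.
#'
#' @param spec model spec from [build_model()].
#' @param params parameter list.
#' @param cov covariate track from [covariate_track()].
#' @param times output time grid (days), increasing from its first element.
#' @param init initial state (defaults to the calibrated operating point).
#' @param forcing optional insulin-sensitivity forcing.
#' @param rtol,atol solver tolerances.
#' @param compiled use the compiled derivative (set `FALSE` for the plain-R
#'   reference path).
#' @return a `dmprog_trajectory`: data frame with columns `t_days`, the state
#'   variables (`G`, `I`, `beta`, and `sigma` when present), and the derived
#'   observables `SI` (forced insulin sensitivity), `sigma_beta`
#'   (beta-cell function) and `disposition` (`SI * I`).
#' @export
integrate_model <- function(spec, params = default_params(),
                            cov = covariate_track(25), times = seq(0, 3000, by = 5),
                            init = NULL, forcing = NULL,
                            rtol = 1e-8, atol = 1e-8, compiled = TRUE) {
  validate_params(params)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  if (is.null(init)) init <- .default_init(spec, params)
  if (length(init) != spec$state_dimension)
    stop("init has length ", length(init), " but the model needs ",
         spec$state_dimension)
  if (any(!is.finite(init)) || any(init < 0)) stop("init must be finite and non-negative")

  if (compiled) {
    pv <- pack_parms(spec, params, age0 = cov$age0, forcing = forcing)
    ft <- cov$pfat_times
    fp <- cov$pfat
    if (length(ft) == 1) { ft <- c(ft, ft + 1); fp <- rep(fp, 2) }
    # forcing table must span the integration window (constant beyond knots)
    ft <- c(min(ft[1], times[1] - 1), ft, max(ft[length(ft)], times[length(times)]) + 1)
    fp <- c(fp[1], fp, fp[length(fp)])
    sol <- deSolve::ode(y = unname(init), times = times, func = "dmprog_derivs",
                        parms = pv, dllname = "dmprog",
                        initfunc = "dmprog_initmod", initforc = "dmprog_initforc",
                        forcings = cbind(ft, fp),
                        fcontrol = list(method = "linear", rule = 2),
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    fn <- function(t, y, parms) list(model_rhs(y, t, spec, params, cov, forcing))
    sol <- deSolve::ode(y = unname(init), times = times, func = fn, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed near t = ", max(sol[, 1]),
         "; last state: ", paste(signif(sol[nrow(sol), -1], 6), collapse = ", "))
  out <- as.data.frame(sol)
  names(out) <- c("t_days", c("G", "I", "beta", "sigma")[seq_len(spec$state_dimension)])
  if (spec$state_dimension == 3) out$sigma <- params$sigma_const

  X <- excess_ffa_index(pfat_at(cov, out$t_days))
  variant <- if ("S_X_AGE_I" %in% spec$ingredients) "S_X_AGE_I"
             else if ("S_X_AGE" %in% spec$ingredients) "S_X_AGE"
             else if ("S_X" %in% spec$ingredients) "S_X" else "none"
  out$SI <- insulin_sensitivity(X, cov$age0, out$t_days,
                                I = out$I, params = params, variant = variant) *
    si_forcing_multiplier(forcing, out$t_days)
  out$sigma_beta <- out$sigma * out$beta
  out$disposition <- out$SI * out$I
  class(out) <- c("dmprog_trajectory", "data.frame")
  out
}

#' Steady state of a model with frozen covariates
#'
#' Finds a root of the right-hand side by damped Newton iteration with a
#' numerical Jacobian, seeded (optionally) by a long pre-integration, and
#' classifies local stability from the Jacobian eigenvalues.
#'
#' @param spec model spec.
#' @param params parameter list.
#' @param pfat frozen percent body fat.
#' @param age0 frozen baseline age (time is held at `t = 0`).
#' @param init starting guess (defaults to the calibrated operating point).
#' @param pre_integrate days of relaxation used to seed Newton (0 to skip).
#' @param tol maximum absolute derivative accepted at the root.
#' @return list with `state` (named vector), `derivatives`, `stable`
#'   (logical: all Jacobian eigenvalues have negative real part), and
#'   `eigenvalues`.
#' @export
steady_state <- function(spec, params = default_params(), pfat = 7, age0 = 25,
                         init = NULL, pre_integrate = 20000, tol = 1e-10) {
  validate_params(params)
  cov <- covariate_track(age0, 0, pfat)
  if (is.null(init)) init <- .default_init(spec, params)
  x <- unname(init)
  if (pre_integrate > 0) {
    traj <- integrate_model(spec, params, cov, times = c(0, pre_integrate / 2, pre_integrate),
                            init = x, rtol = 1e-10, atol = 1e-10)
    x <- unname(as.numeric(traj[nrow(traj), 2:(1 + spec$state_dimension)]))
  }
  f <- function(s) unname(model_rhs(s, 0, spec, params, cov))
  n <- length(x)
  num_jac <- function(s) {
    J <- matrix(0, n, n)
    f0 <- f(s)
    for (j in seq_len(n)) {
      h <- max(1e-6 * abs(s[j]), 1e-8)
      sp <- s; sp[j] <- sp[j] + h
      J[, j] <- (f(sp) - f0) / h
    }
    J
  }
  for (it in 1:100) {
    fx <- f(x)
    if (max(abs(fx)) < tol) break
    J <- num_jac(x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 1e-12)
      if (max(abs(f(xn))) < max(abs(fx)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  fx <- f(x)
  if (max(abs(fx)) >= tol)
    stop("no steady state found to tolerance ", tol,
         " from search box around c(", paste(signif(init, 4), collapse = ", "),
         "); residual ", signif(max(abs(fx)), 3))
  ev <- eigen(num_jac(x), only.values = TRUE)$values
  nm <- c("G", "I", "beta", "sigma")[seq_len(n)]
  list(state = stats::setNames(x, nm), derivatives = stats::setNames(fx, nm),
       stable = all(Re(ev) < 0), eigenvalues = ev)
}

.experiment_base <- function(spec, params, forcing, times) {
  ss <- steady_state(spec, params, pfat = 7, age0 = 25)
  integrate_model(spec, params, covariate_track(25, 0, 7), times = times,
                  init = ss$state, forcing = forcing)
}

#' Step-wise insulin-sensitivity drop experiment
#'
#' Starts the model at its steady state, drops insulin sensitivity by
#' `drop` during `[t_on, t_off]` and restores it, tracking the transient rise
#' and recovery of glucose and insulin.  Beta-cell mass barely moves during a
#' window of a few days, so both glucose and insulin spike and then return to
#' baseline.
#'
#' @param spec model spec (base/Model-1 family).
#' @param params parameter list.
#' @param forcing a step forcing from [si_forcing()].
#' @param times output grid (days); must contain the forcing window.
#' @return list with `trajectory` and `summary` (baseline, peak G, peak I,
#'   relative end-of-run gap from baseline).
#' @export
experiment_step_si <- function(spec = model_preset("base"), params = default_params(),
                               forcing = si_forcing("step", drop = 0.3),
                               times = seq(0, 300, by = 0.25)) {
  if (forcing$mode != "step") stop("forcing must be a step protocol")
  if (forcing$t_on < min(times) || forcing$t_off > max(times))
    stop("forcing window lies outside the time grid")
  traj <- .experiment_base(spec, params, forcing, times)
  base <- traj[1, ]
  endg <- abs(c(G = traj$G[nrow(traj)] / base$G, I = traj$I[nrow(traj)] / base$I) - 1)
  list(trajectory = traj,
       summary = list(G0 = base$G, I0 = base$I,
                      peak_G = max(traj$G), peak_I = max(traj$I),
                      recovery_gap = max(endg)))
}

#' Gradual insulin-sensitivity decline experiment
#'
#' Insulin sensitivity declines exponentially towards `1 - drop` of its
#' baseline over years.  Beta-cell compensation keeps glucose nearly flat
#' while basal insulin rises towards the full-compensation bound
#' `1/(1 - drop) - 1`.
#'
#' @param spec model spec.
#' @param params parameter list.
#' @param forcing an exponential forcing from [si_forcing()].
#' @param horizon simulation horizon (days); at least `5 * tau`.
#' @param dt output step (days).
#' @return list with `trajectory` and `summary`: percent changes of basal
#'   insulin and glucose between start and horizon, and the disposition-index
#'   series.
#' @export
experiment_gradual_si <- function(spec = model_preset("base"), params = default_params(),
                                  forcing = si_forcing("exponential", drop = 0.3, tau = 600),
                                  horizon = 3000, dt = 5) {
  if (forcing$mode != "exponential") stop("forcing must be an exponential protocol")
  if (horizon < 5 * forcing$tau)
    stop("horizon must be at least 5 forcing time constants")
  traj <- .experiment_base(spec, params, forcing, seq(0, horizon, by = dt))
  n <- nrow(traj)
  list(trajectory = traj,
       summary = list(
         pct_change_I = 100 * (traj$I[n] - traj$I[1]) / traj$I[1],
         pct_change_G = 100 * (traj$G[n] - traj$G[1]) / traj$G[1],
         disposition = traj$disposition,
         min_disposition = min(traj$disposition)))
}

#' Sweep of insulin-sensitivity decline rates
#'
#' Runs the gradual-decline experiment for several exponential time
#' constants.  A faster decline elicits a stronger endpoint insulin rise but
#' a lower disposition index (insulin times insulin sensitivity), and glucose
#' trajectories for different rates cross, so cross-sectional sampling at an
#' early versus a late day ranks subjects oppositely.
#'
#' @param spec model spec.
#' @param params parameter list.
#' @param taus two or more exponential time constants (days).
#' @param drop shared fractional drop.
#' @param horizon,dt simulation grid.
#' @return list with one entry per time constant: `tau`, `trajectory`,
#'   `pct_change_I`, `min_disposition`.
#' @export
experiment_rate_sweep <- function(spec = model_preset("base"), params = default_params(),
                                  taus = c(200, 600, 1800), drop = 0.3,
                                  horizon = 3000, dt = 5) {
  if (length(taus) < 1) stop("at least one time constant is required")
  lapply(taus, function(tau) {
    # all rates share one horizon so endpoints are comparable
    traj <- .experiment_base(spec, params,
                             si_forcing("exponential", drop = drop, tau = tau),
                             seq(0, horizon, by = dt))
    n <- nrow(traj)
    list(tau = tau, trajectory = traj,
         pct_change_I = 100 * (traj$I[n] - traj$I[1]) / traj$I[1],
         min_disposition = min(traj$disposition))
  })
}
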