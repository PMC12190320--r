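# Shared fixtures: small cohorts and the linear-Gaussian toy model used to
# cross-check the mixed-effects machinery against closed forms.

m1_scales <- c(c_si = 3.4, c_sigma_beta = 2.4e-05)

# small three-state (Model 1) cohort configuration; heterogeneity only where
# requested so tests stay sharp
m1_config <- function(n, omega = c(gX1 = 0.2, c_si = 0.15), ...) {
  cohort_config(n_subjects = n, spec = model_preset("Model1"),
                omega = omega, scales = m1_scales, ...)
}

# toy mixed model: y_ij = log(m_i) + eps_ij, log m_i ~ N(log m_pop, omega^2);
# linear-Gaussian in log space, so the marginal likelihood has a closed form
toy_subjects <- function(n = 12, nv = 5, m_pop = 2, omega = 0.4,
                         s_eps = 0.15, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    phi_i <- log(m_pop) + rnorm(1, 0, omega)
    y <- matrix(phi_i + rnorm(nv, 0, s_eps), nv, 1,
                dimnames = list(NULL, "obs"))
    list(y = y, predict = function(theta) matrix(log(theta[["m"]]), nv, 1),
         id = i)
  })
}

# exact marginal log-likelihood of the toy model (Gaussian integral)
toy_closed_form_loglik <- function(subjects, mu, omega, s_eps) {
  nv <- nrow(subjects[[1]]$y)
  V <- matrix(omega^2, nv, nv) + diag(s_eps^2, nv)
  ld <- as.numeric(determinant(V)$modulus)
  sum(vapply(subjects, function(su) {
    r <- su$y[, 1] - mu
    as.numeric(-0.5 * (nv * log(2 * pi) + ld + t(r) %*% solve(V, r)))
  }, numeric(1)))
}

# Ishigami function and its analytic Sobol indices
ishigami <- function(X, a = 7, b = 0.1)
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])

ishigami_indices <- function(a = 7, b = 0.1) {
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  S1 <- 0.5 * (1 + b * pi^4 / 5)^2 / V
  S2 <- (a^2 / 8) / V
  Vint <- 8 * b^2 * pi^8 / 225
  list(first = c(S1, S2, 0), total = c(S1 + Vint / V, S2, Vint / V))
}
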