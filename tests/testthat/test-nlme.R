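test_that("the information criterion follows its defining arithmetic", {
  expect_equal(bic(-100, 5, 17), 200 + 5 * log(17))
  expect_equal(bic(-50, 0, 99), 100)
  # one extra parameter at equal likelihood costs exactly log(n)
  expect_equal(bic(-80, 6, 40) - bic(-80, 5, 40), log(40))
  expect_error(bic(-10, -1, 5))
  expect_error(bic(-10, 2, 0))
})

test_that("SAEM recovers the parameters of a linear-Gaussian toy model", {
  subjects <- toy_subjects(n = 30, nv = 6, m_pop = 2, omega = 0.4,
                           s_eps = 0.15, seed = 7)
  fit <- saem_fit(subjects, c(m = log(1.2)), c(m = 0.2), c(obs = 0.3),
                  saem_control(n_burn = 120, n_smooth = 80, seed = 2))
  expect_equal(unname(fit$theta_pop), 2, tolerance = 0.15)
  expect_equal(unname(fit$omega), 0.4, tolerance = 0.35)
  expect_equal(unname(fit$error_sd), 0.15, tolerance = 0.25)
  expect_true(fit$converged)
  # seeded determinism
  fit2 <- saem_fit(subjects, c(m = log(1.2)), c(m = 0.2), c(obs = 0.3),
                   saem_control(n_burn = 120, n_smooth = 80, seed = 2))
  expect_identical(fit$theta_pop, fit2$theta_pop)
})

test_that("importance-sampling likelihood matches the Gaussian closed form", {
  subjects <- toy_subjects(n = 12, seed = 7)
  mu <- log(2); om <- 0.4; s_eps <- 0.15
  est <- marginal_loglik(subjects, c(m = mu), c(m = om), c(obs = s_eps), "m",
                         n_mc = 8000, seed = 3)
  cf <- toy_closed_form_loglik(subjects, mu, om, s_eps)
  expect_lt(abs(est$logL - cf), 3 * est$se)
  # quadrupling the draws roughly halves the reported standard error
  se_small <- mean(vapply(1:5, function(k)
    marginal_loglik(subjects, c(m = mu), c(m = om), c(obs = s_eps), "m",
                    n_mc = 500, seed = k)$se, numeric(1)))
  se_big <- mean(vapply(1:5, function(k)
    marginal_loglik(subjects, c(m = mu), c(m = om), c(obs = s_eps), "m",
                    n_mc = 2000, seed = k)$se, numeric(1)))
  expect_gt(se_small / se_big, 1.4)
  expect_lt(se_small / se_big, 2.8)
  # degenerate random effects: the marginal equals the ordinary likelihood
  z <- marginal_loglik(subjects, c(m = mu), c(m = 0), c(obs = s_eps), "m",
                       n_mc = 10, seed = 1)
  ll0 <- sum(vapply(subjects, function(su)
    sum(dnorm(su$y[, 1], mu, s_eps, log = TRUE)), numeric(1)))
  expect_equal(z$logL, ll0)
  expect_equal(z$se, 0)
})

test_that("empirical-Bayes modes recover the generating random effects", {
  cfg <- cohort_config(n_subjects = 4, spec = model_preset("Model1"),
                       omega = c(gX1 = 0.3),
                       error_sd = c(fpg = 1e-3, fpi = 1e-3,
                                    matsuda = 1e-3, igi = 1e-3),
                       scales = m1_scales,
                       g0_sd = 0, age0_sd = 0, pfat0_sd = 0, pfat_slope_sd = 0,
                       pfat_jitter = 0, visit_jitter = 0, followup_sd = 0)
  co <- generate_cohort(cfg, seed = 51)
  fit <- structure(list(
    fixed = list(gX1 = 0.8), omega = c(gX1 = 0.3),
    error_sd = c(fpg = 1e-3, fpi = 1e-3, matsuda = 1e-3),
    est_names = "gX1", spec = model_preset("Model1"),
    stat = stat_model(random = c(gX1 = 0.3),
                      observables = c("fpg", "fpi", "matsuda")),
    params = default_params(), scales = m1_scales), class = "dmprog_fit")
  eb <- estimate_random_effects(fit, co)
  truth <- vapply(co, function(s) s$eta[["gX1"]], numeric(1))
  expect_lt(max(abs(eb[, 1] - truth)), 1e-2)
  # modes do not depend on subject ordering
  eb_perm <- estimate_random_effects(fit, co[c(3, 1, 4, 2)])
  expect_lt(max(abs(eb_perm[, 1] - truth[c(3, 1, 4, 2)])), 1e-2)
})

test_that("a subject with no usable observations gets the prior mode", {
  su <- list(y = matrix(NA_real_, 3, 1, dimnames = list(NULL, "obs")),
             predict = function(theta) matrix(0, 3, 1), id = 1L)
  mode <- dmprog:::.eb_mode_subject(su, c(m = 0), c(m = 0.5), c(obs = 0.1), "m")
  expect_identical(mode, 0)
  l <- marginal_loglik(list(su), c(m = 0), c(m = 0.5), c(obs = 0.1), "m",
                       n_mc = 50, seed = 1)
  expect_identical(l$logL, 0)
})

test_that("suppressing random effects matches a direct pooled optimiser", {
  co <- generate_cohort(m1_config(5, omega = c(gX1 = 1e-9)), seed = 21)
  stat <- stat_model(random = c(gX1 = 0.2, c_si = 0.2),
                     observables = c("fpg", "fpi", "matsuda"))
  fit <- fit_population(co, model_preset("Model1"), stat,
                        params = default_params(gX1 = 0.6),
                        scales = c(c_si = 2.8, c_sigma_beta = 2.4e-05),
                        method = "pooled")
  # independent objective: profiled Gaussian likelihood coded from scratch
  spec <- model_preset("Model1")
  pred_subject <- function(su, gX1, c_si) {
    p <- default_params(gX1 = gX1)
    g0 <- su$visits$fpg[1]
    half <- p$G1 - beta_growth_roots(p)[1]
    p$G1 <- g0 + half; p$Gb1 <- g0; p$Gb2 <- g0 + 2 * half
    X0 <- excess_ffa_index(pfat_at(su$cov, su$visits$t_days[1]))
    init <- dmprog:::.initial_state(spec, p, g0, X0, su$age0)
    tr <- integrate_model(spec, p, su$cov, times = su$visits$t_days,
                          init = init, rtol = 1e-6, atol = 1e-6)
    ob <- model_to_observables(tr, su$visits$t_days,
                               c(c_si = c_si, c_sigma_beta = 1))
    log(as.matrix(ob[c("fpg", "fpi", "matsuda")]))
  }
  objective <- function(par) {
    gX1 <- 1 / (1 + exp(-par[1])); c_si <- exp(par[2])
    rss <- numeric(3); nobs <- numeric(3)
    for (su in co) {
      pr <- pred_subject(su, gX1, c_si)
      yy <- log(as.matrix(su$visits[c("fpg", "fpi", "matsuda")]))
      rss <- rss + colSums((yy - pr)^2)
      nobs <- nobs + nrow(yy)
    }
    sum(nobs / 2 * (log(2 * pi * rss / nobs) + 1))
  }
  o <- optim(c(0, 1), objective, control = list(maxit = 3000, reltol = 1e-12))
  direct <- c(1 / (1 + exp(-o$par[1])), exp(o$par[2]))
  expect_equal(unname(unlist(fit$fixed)[c("gX1", "c_si")]), direct,
               tolerance = 0.01)
  expect_equal(fit$logL, -o$value, tolerance = abs(0.01 * o$value))
})

test_that("population fitting recovers generating values on a small cohort", {
  # generator heterogeneity restricted to the fitted random-effect set so
  # both fixed effects and variances are estimable
  co <- generate_cohort(m1_config(16, omega = c(gX1 = 0.25, c_si = 0.2)),
                        seed = 61)
  stat <- stat_model(random = c(gX1 = 0.25, c_si = 0.2),
                     observables = c("fpg", "fpi", "matsuda"))
  fit <- fit_population(co, model_preset("Model1"), stat,
                        params = default_params(gX1 = 0.55),
                        scales = c(c_si = 2.3, c_sigma_beta = 2.4e-05),
                        control = saem_control(n_burn = 100, n_smooth = 80,
                                               n_rw = 2, n_mc = 200, seed = 3))
  expect_equal(fit$fixed[["gX1"]], 0.8, tolerance = 0.2)
  expect_equal(fit$fixed[["c_si"]], 3.4, tolerance = 0.2)
  expect_lt(abs(fit$omega[["gX1"]] - 0.25), 0.5 * 0.25)
  expect_lt(abs(fit$omega[["c_si"]] - 0.2), 0.5 * 0.2)
  expect_equal(fit$bic, -2 * fit$logL + fit$k * log(fit$n))
})

test_that("population-fit preconditions are enforced", {
  co <- generate_cohort(m1_config(4), seed = 9)
  stat <- stat_model(random = c(gX1 = 0.2), observables = "fpg")
  expect_error(fit_population(co[1], model_preset("Model1"), stat), "2 subjects")
  short <- co
  short[[1]]$visits <- short[[1]]$visits[1:2, ]
  expect_error(fit_population(short, model_preset("Model1"), stat), "3 visits")
  expect_error(stat_model(random = c(0.2)), "named")
  expect_error(stat_model(random = c(gX1 = -0.1)), ">= 0")
})
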