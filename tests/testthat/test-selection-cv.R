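test_that("admissible additions respect the ingredient rules", {
  m1 <- model_preset("Model1")
  adds <- admissible_additions(m1, ingredient_ids())
  # richer insulin-sensitivity forms replace the current one
  expect_setequal(adds$S_X_AGE, c("S_X_AGE"))
  expect_setequal(adds$S_X_AGE_I, c("S_X_AGE_I"))
  # sigma modifiers are inadmissible without the dynamic-sigma state
  expect_false("LIPO_SIGMA" %in% names(adds))
  expect_false("SIGMA_ENHANCED_GLU" %in% names(adds))
  expect_true("SIGMA_DYNAMIC_CA" %in% names(adds))
  with_sigma <- build_model("m", c("S_X", "SIGMA_DYNAMIC_CA"))
  adds2 <- admissible_additions(with_sigma, ingredient_ids())
  expect_true(all(c("LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC", "SIGMA_ENHANCED_GLU")
                  %in% names(adds2)))
  # the two lipid-sigma forms displace each other
  with_lipo <- build_model("m", c("S_X", "SIGMA_DYNAMIC_CA", "LIPO_SIGMA"))
  adds3 <- admissible_additions(with_lipo, "LIPO_SIGMA_BIPHASIC")
  expect_false("LIPO_SIGMA" %in% adds3$LIPO_SIGMA_BIPHASIC)
})

test_that("k-fold splits partition the cohort into near-equal seeded folds", {
  cohort63 <- vector("list", 63)
  f <- kfold_split(cohort63, k = 3, seed = 1)
  expect_equal(as.integer(table(f)), rep(21L, 3))
  expect_equal(sort(unique(f)), 1:3)
  expect_identical(f, kfold_split(cohort63, k = 3, seed = 1))
  expect_false(identical(f, kfold_split(cohort63, k = 3, seed = 2)))
  f2 <- kfold_split(vector("list", 10), k = 4, seed = 5)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_length(f2, 10)
  expect_error(kfold_split(vector("list", 2), k = 3), "exceeds")
})

test_that("testing-mode BIC relates to fitting-mode BIC as expected", {
  co <- generate_cohort(m1_config(6), seed = 41)
  stat <- stat_model(random = c(gX1 = 0.2, c_si = 0.2),
                     observables = c("fpg", "fpi", "matsuda"))
  fit <- fit_population(co, model_preset("Model1"), stat, default_params(),
                        m1_scales,
                        saem_control(n_burn = 60, n_smooth = 40, n_mc = 200,
                                     seed = 4))
  # same subjects, same population parameters: the testing-mode criterion is
  # the fitting-mode one minus the whole parameter penalty, up to MC error
  bt <- bic_by_testing(fit, co, n_mc = 500, seed = 9)
  expect_equal(bt$k, 0)
  expect_lt(abs(bt$bic - (fit$bic - fit$k * log(fit$n))),
            2 * 2 * sqrt(bt$se^2 + fit$logL_se^2) + 1e-8)
  # at the generating population values, held-out data score close to the
  # training-mode likelihood (no over-parameterisation signal)
  truth_fit <- fit
  truth_fit$fixed <- list(gX1 = 0.8, c_si = 3.4)
  truth_fit$omega <- c(gX1 = 0.2, c_si = 0.15)
  test_co <- generate_cohort(m1_config(12), seed = 42)
  bt2 <- bic_by_testing(truth_fit, test_co, n_mc = 400, seed = 10)
  per_subj_train <- bt$logL / length(co)
  per_subj_test <- bt2$logL / length(test_co)
  expect_lt(abs(per_subj_test - per_subj_train) / abs(per_subj_train), 0.35)
  expect_error(bic_by_testing(fit, list()), "empty")
})

test_that("the greedy search adopts the ingredient that lowers the criterion", {
  # truth has an adiposity-dependent insulin sensitivity; the legacy model
  # (constant sensitivity) must lose to the candidate that adds it
  co <- generate_cohort(m1_config(8), seed = 31)
  stat <- stat_model(random = c(c_si = 0.2),
                     observables = c("fpg", "fpi", "matsuda"))
  ctrl <- saem_control(n_burn = 50, n_smooth = 30, n_mc = 150, seed = 4)
  res <- generation_search(model_preset("Topp"), c("S_X", "LIPO_MASS"), co,
                           stat, default_params(), m1_scales, ctrl,
                           stop_rel = 0.025, max_generations = 1)
  expect_equal(res[[1]]$generation, 0L)
  gen1 <- res[[2]]
  expect_true(all(c("S_X", "LIPO_MASS") %in% gen1$candidates$ingredient))
  # the winner carries the generation's minimal criterion value
  expect_equal(gen1$bic, min(gen1$candidates$bic, na.rm = TRUE))
  expect_true("S_X" %in% gen1$winner$ingredients)
  # adopting the winner never increases the criterion sequence
  expect_lte(gen1$bic, res[[1]]$bic)
  # an empty pool returns the base model only
  res0 <- generation_search(model_preset("Model1"), character(), co, stat,
                            default_params(), m1_scales, ctrl)
  expect_length(res0, 1)
})

test_that("eFAST reproduces the variance decomposition of an additive model", {
  a <- c(1, 2, 0.5)
  res <- efast(function(X) X %*% a,
               list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1)),
               n = 1025, M = 4, n_resample = 2, seed = 1)
  S_true <- a^2 / sum(a^2)    # equal input variances cancel
  expect_equal(res$first_order, S_true, tolerance = 0.02)
  expect_equal(res$total_order, S_true, tolerance = 0.02)
  expect_true(all(res$first_order >= 0 & res$total_order <= 1 + 1e-6))
  expect_lte(sum(res$first_order), 1 + 0.02)
})

test_that("eFAST matches the analytic Ishigami indices", {
  truth <- ishigami_indices()
  res <- efast(ishigami, list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi)),
               n = 4097, M = 4, n_resample = 4, seed = 2)
  expect_equal(res$first_order, truth$first, tolerance = 0.02)
  expect_equal(res$total_order, truth$total, tolerance = 0.02)
})

test_that("an uninfluential parameter receives a near-zero total index", {
  res <- efast(function(X) X[, 1] + 0 * X[, 2],
               list(x1 = c(0, 1), dummy = c(0, 1)), n = 1025, seed = 3)
  expect_lt(res$total_order[res$parameter == "dummy"], 0.02)
  expect_lt(res$first_order[res$parameter == "dummy"], 0.02)
})

test_that("eFAST refuses sample sizes below the Nyquist bound", {
  expect_error(efast(function(X) X[, 1], list(a = c(0, 1), b = c(0, 1)),
                     n = 60, M = 4), "need n > 64")
  expect_error(efast(function(X) X[, 1], list(a = c(0, 1))), "2 parameters")
})

test_that("the model screen ranks influential parameters above inert ones", {
  # enh3 only acts when the enhanced-glucose ingredient is present, so for
  # the selected model it is an inert (dummy) input of the screen
  res <- efast_sensitivity(model_preset("Model5"),
                           ranges = list(gX1 = c(0.3, 0.95),
                                         sigma6 = c(0.1, 0.6),
                                         enh3 = c(1, 2)),
                           output = "G_end", horizon = 2000, pfat = 40,
                           n = 257, n_resample = 2, seed = 5)
  expect_lt(res$total_order[res$parameter == "enh3"], 0.02)
  expect_gt(res$total_order[res$parameter == "gX1"], 0.1)
  expect_lte(sum(res$first_order), 1 + 0.05)
})
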