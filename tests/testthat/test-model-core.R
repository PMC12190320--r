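test_that("excess-FFA index maps the adiposity range linearly with clamping", {
  expect_identical(excess_ffa_index(7), 0)
  expect_identical(excess_ffa_index(52), 1)
  expect_equal(excess_ffa_index(29.5), 0.5)
  expect_equal(excess_ffa_index(c(2, 60)), c(0, 1.1))  # clamped
  expect_error(excess_ffa_index(NaN), "finite")
})

test_that("insulin-sensitivity factors collapse to their analytic limits", {
  p <- default_params()
  expect_equal(insulin_sensitivity(0.3, params = default_params(gX1 = 0),
                                   variant = "S_X"), p$SI_base)
  expect_equal(insulin_sensitivity(p$gX3, params = p, variant = "S_X"),
               p$SI_base * (1 - p$gX1 / 2))
  # at basal insulin the insulin factor is exactly 1
  expect_equal(
    insulin_sensitivity(0.5, age0 = 30, t = 100, I = p$I0, params = p,
                        variant = "S_X_AGE_I"),
    insulin_sensitivity(0.5, age0 = 30, t = 100, params = p,
                        variant = "S_X_AGE"))
  # gi1 = 0 removes the insulin factor entirely
  p0 <- default_params(gi1 = 0)
  expect_equal(
    insulin_sensitivity(0.5, 30, 100, I = 200, params = p0, variant = "S_X_AGE_I"),
    insulin_sensitivity(0.5, 30, 100, params = p0, variant = "S_X_AGE"))
  expect_error(insulin_sensitivity(0, params = default_params(gX1 = 1, gX2 = 1e3,
                                                              gX3 = -1),
                                   variant = "S_X"), "non-positive")
})

test_that("insulin sensitivity is monotone non-increasing in adiposity", {
  X <- seq(0, 1.1, length.out = 60)
  si <- insulin_sensitivity(X, variant = "S_X")
  expect_true(all(diff(si) <= 0))
  si2 <- insulin_sensitivity(X, age0 = 40, t = 2000, variant = "S_X_AGE")
  expect_true(all(diff(si2) <= 0))
})

test_that("hepatic glucose production has the stated structure and bounds", {
  p <- default_params()
  expect_equal(hgp_rate(50, 0.5, default_params(hepa_max = 0)), p$hepa_b)
  expect_equal(hgp_rate(0, 0.3, p), p$hepa_b + p$hepa_max / hepa_km(0.3, p))
  # raising X raises production at fixed insulin, pointwise on a grid
  for (I in c(0, 15, 60, 200)) {
    h <- hgp_rate(I, seq(0, 1.1, length.out = 40), p)
    expect_true(all(diff(h) >= 0))
  }
  # suppression by insulin, floored above hepa_b
  h_i <- hgp_rate(seq(0, 500, length.out = 50), 0.2, p)
  expect_true(all(diff(h_i) <= 0))
  expect_true(all(h_i > p$hepa_b))
  expect_error(hgp_rate(-1, 0), "non-negative")
})

test_that("saturating insulin clearance follows the hyperbolic form", {
  p <- default_params()
  expect_equal(insulin_clearance(0, p), p$k1 / p$k2)
  expect_equal(insulin_clearance(p$k2, p), p$k1 / (2 * p$k2))
  # clearance flux increases and saturates at k1
  I <- c(1, 10, 100, 1e3, 1e6)
  flux <- insulin_clearance(I, p) * I
  expect_true(all(diff(flux) > 0))
  expect_equal(insulin_clearance(1e12, p) * 1e12, p$k1, tolerance = 1e-6)
})

test_that("calcium and secretion drive reproduce Hill-function limits", {
  p <- default_params()
  expect_equal(calcium(0, p), p$Ca_b)
  expect_equal(calcium(p$Ca2, p), p$Ca_b + p$Ca1 / 2)
  expect_equal(calcium(1e9, p), p$Ca_b + p$Ca1, tolerance = 1e-6)
  expect_true(all(diff(calcium(seq(0, 400, 2), p)) > 0))
  expect_equal(secretion_drive(p$Ca_b, p), 0)
  expect_equal(secretion_drive(p$Ca_b + p$Ca3, p), 0.5)
  dr <- secretion_drive(p$Ca_b + seq(0, 2, length.out = 50), p)
  expect_true(all(diff(dr) > 0) && all(dr < 1))
  expect_error(secretion_drive(p$Ca_b - 0.01, p), "Ca_b")
})

test_that("secretory-capacity steady state matches substitution limits", {
  p <- default_params()
  # sigma5 = 0 kills the decline factor entirely: f = f_gd * 0 + sigma1
  p5 <- default_params(sigma5 = 0)
  expect_equal(sigma_steady_state(100, calcium(100, p5), 0, p5),
               p5$sigma0 * p5$sigma1)
  # biphasic lipid factor is exactly 1 at X = 0
  expect_equal(sigma_steady_state(90, calcium(90, p), 0, p, "LIPO_SIGMA_BIPHASIC"),
               sigma_steady_state(90, calcium(90, p), 0, p, "none"))
  # calcium-toxicity threshold saturates at sigma7 - sigma8
  ca_hi <- 1e6
  sCa <- p$sigma7 - p$sigma8 * ca_hi^6 / (ca_hi^6 + p$sigma_g^6)
  expect_equal(sCa, p$sigma7 - p$sigma8, tolerance = 1e-9)
  # raising sigma6 lowers the capacity at fixed high glucose (earlier
  # glucotoxicity), checked on a grid
  for (G in c(100, 110, 120)) {
    vals <- vapply(seq(0.1, 0.6, length.out = 12), function(s6) {
      ps <- default_params(sigma6 = s6)
      sigma_steady_state(G, calcium(G, ps), 0, ps)
    }, numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("bump growth function roots match an independent root finder", {
  p <- default_params()
  roots <- beta_growth_roots(p)
  f <- function(G) beta_growth_rate(G, params = p)
  r1 <- uniroot(f, c(p$G1 - 4 * p$b2, p$G1), tol = 1e-12)$root
  r2 <- uniroot(f, c(p$G1, p$G1 + 4 * p$b2), tol = 1e-12)$root
  expect_equal(roots, c(r1, r2), tolerance = 1e-9)
  # peak and tail limits
  expect_equal(f(p$G1), p$b1 - p$b3)
  expect_equal(beta_growth_rate(1e5, params = p), -p$b3, tolerance = 1e-8)
  # legacy parabola has its zeros exactly at Gb1 and Gb2
  expect_equal(beta_growth_rate(p$Gb1, params = p, topp = TRUE), 0)
  expect_equal(beta_growth_rate(p$Gb2, params = p, topp = TRUE), 0)
  # lipotoxic term deepens the floor to -b3 - b4
  expect_equal(beta_growth_rate(1e5, X = 1e3, params = p, lipo_mass = TRUE),
               -p$b3 - p$b4, tolerance = 1e-6)
})

test_that("model builder enforces the ingredient combination rules", {
  expect_equal(build_model("Model1", character())$state_dimension, 3L)
  expect_equal(build_model("m", "SIGMA_DYNAMIC_CA")$state_dimension, 4L)
  expect_error(build_model("m", c("LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC")),
               "LIPO_SIGMA and LIPO_SIGMA_BIPHASIC")
  expect_error(build_model("m", c("S_X", "S_X_AGE")), "S_X and S_X_AGE")
  expect_error(build_model("m", "LIPO_SIGMA"), "SIGMA_DYNAMIC_CA")
  expect_error(build_model("m", "NOT_AN_INGREDIENT"), "unknown")
  expect_error(build_model("Topp", "S_X"), "no ingredients")
  m5 <- model_preset("Model5")
  expect_setequal(m5$ingredients, c("S_X_AGE_I", "HGP_DYNAMIC", "CLEARANCE_SAT",
                                    "SIGMA_DYNAMIC_CA", "LIPO_SIGMA_BIPHASIC"))
  expect_equal(m5$state_dimension, 4L)
})

test_that("compiled and plain-R right-hand sides agree along trajectories", {
  set.seed(42)
  cov <- covariate_track(30, c(0, 500, 1500), c(25, 33, 44))
  specs <- list(model_preset("Topp"), model_preset("Model1"), model_preset("Model5"),
                build_model("mix", c("S_X_AGE", "HGP_DYNAMIC", "SIGMA_DYNAMIC_CA",
                                     "LIPO_SIGMA", "LIPO_MASS", "SIGMA_ENHANCED_GLU")))
  p <- default_params()
  for (spec in specs) {
    nd <- spec$state_dimension
    init <- c(95, 30, 250, if (nd == 4) 180)
    tt <- seq(0, 150, by = 50)
    trC <- integrate_model(spec, p, cov, times = tt, init = init,
                           rtol = 1e-10, atol = 1e-10)
    trR <- integrate_model(spec, p, cov, times = tt, init = init,
                           rtol = 1e-10, atol = 1e-10, compiled = FALSE)
    expect_lt(max(abs(as.matrix(trC[2:(1 + nd)]) - as.matrix(trR[2:(1 + nd)]))),
              1e-6)
  }
})

test_that("neutralised ingredients reduce the derivative to the parent model", {
  cov <- covariate_track(25, 0, 30)
  state <- c(88, 25, 280)
  # richer insulin-sensitivity forms collapse onto S(X) when their extra
  # factors are switched off
  p0 <- default_params(gA1 = 0, gi1 = 0)
  expect_equal(
    model_rhs(state, 500, build_model("a", "S_X_AGE_I"), p0, cov),
    model_rhs(state, 500, build_model("b", "S_X"), p0, cov))
  # dynamic hepatic production with zero amplitude and a matching meal
  # constant is exactly the constant-influx model
  ph <- default_params(hepa_max = 0)
  ph$meal_const <- ph$Gin - ph$hepa_b
  expect_equal(
    model_rhs(state, 0, build_model("h", c("S_X", "HGP_DYNAMIC")), ph, cov),
    model_rhs(state, 0, build_model("g", "S_X"), ph, cov))
  # with the FFA factor off, the base model's glucose and insulin equations
  # equal the recalibrated legacy model's (the mass equations differ by
  # construction: bump/logistic versus parabola/exponential)
  pt <- default_params(gX1 = 0)
  r_base <- model_rhs(state, 0, model_preset("base"), pt, cov)
  r_topp <- model_rhs(state, 0, model_preset("Topp"), pt, cov)
  expect_equal(r_base[c("G", "I")], r_topp[c("G", "I")], tolerance = 1e-12)
})

test_that("no derivative drives a zero-valued state negative", {
  set.seed(11)
  specs <- list(model_preset("Model1"), model_preset("Model5"))
  for (spec in specs) {
    nd <- spec$state_dimension
    for (rep in 1:20) {
      st <- runif(nd, 0, 300)
      zero_at <- sample(nd, 1)
      st[zero_at] <- 0
      d <- model_rhs(st, runif(1, 0, 2000), spec, default_params(),
                     covariate_track(30, 0, runif(1, 7, 52)))
      expect_gte(d[zero_at], 0)
    }
  }
})

test_that("basal glucose balance closes at the calibrated operating point", {
  p <- default_params()
  expect_equal(p$Gin, p$SG * 80 + p$SI_base * 15 * 80)
  d <- model_rhs(c(80, 15, 300), 0, model_preset("base"), p, covariate_track(25, 0, 7))
  expect_equal(unname(d["G"]), 0)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(validate_params(default_params(b1 = 1, b3 = 2)), "b1")
  expect_error(validate_params(default_params(gX1 = 1.2)), "\\[0, 1\\]")
  expect_error(validate_params(default_params(SG = -1)), "> 0")
  expect_error(validate_params(default_params(iir_min = 0)), "iir_min")
  expect_silent(validate_params(default_params()))
})

test_that("model configurations round-trip through YAML", {
  p <- default_params(gX1 = 0.65, sigma6 = 0.4)
  spec <- model_preset("Model5")
  path <- tempfile(fileext = ".yaml")
  write_model_config(path, spec, p)
  cfg <- read_model_config(path)
  expect_setequal(cfg$spec$ingredients, spec$ingredients)
  expect_equal(cfg$params$gX1, 0.65)
  expect_equal(cfg$params$sigma6, 0.4)
  expect_equal(cfg$params$Gin, p$Gin)
  unlink(path)
})
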