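#' @useDynLib dmprog, .registration = TRUE
NULL

.ingredient_ids <- c("S_X", "S_X_AGE", "S_X_AGE_I", "HGP_DYNAMIC",
                     "CLEARANCE_SAT", "SIGMA_DYNAMIC_CA", "SIGMA_ENHANCED_GLU",
                     "LIPO_MASS", "LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC")

#' Ingredient identifiers of the model family
#'
#' The base model can be augmented with mechanistic ingredients:
#' \describe{
#'   \item{S_X}{insulin sensitivity falls with the excess-FFA index X.}
#'   \item{S_X_AGE}{additionally falls with baseline age and elapsed time.}
#'   \item{S_X_AGE_I}{additionally falls with supra-basal insulin
#'     (insulin-induced insulin resistance).}
#'   \item{HGP_DYNAMIC}{constant glucose influx replaced by a meal constant
#'     plus an insulin- and FFA-dependent hepatic glucose production rate.}
#'   \item{CLEARANCE_SAT}{constant insulin clearance replaced by the
#'     saturating hyperbolic rate `k1/(k2 + I)`.}
#'   \item{SIGMA_DYNAMIC_CA}{beta-cell secretory capacity becomes a fourth
#'     state variable relaxing to a glucose/calcium-dependent steady state
#'     (glucotoxicity).}
#'   \item{SIGMA_ENHANCED_GLU}{raised glucose sensitivity of the secretory
#'     capacity (multipliers on `sigma3`, `sigma4`).}
#'   \item{LIPO_MASS}{lipotoxic loss term in the beta-cell mass growth rate.}
#'   \item{LIPO_SIGMA}{purely lipotoxic scaling of the secretory-capacity
#'     steady state.}
#'   \item{LIPO_SIGMA_BIPHASIC}{biphasic (stimulatory at low, toxic at high
#'     FFA) scaling of the secretory-capacity steady state.}
#' }
#' The three `S_*` forms are mutually exclusive, as are the two lipid-sigma
#' forms; the sigma-modifying ingredients require `SIGMA_DYNAMIC_CA`.
#'
#' @return character vector of the ten ingredient ids.
#' @export
ingredient_ids <- function() .ingredient_ids

#' Build a model specification from an ingredient set
#'
#' Validates the ingredient combination rules and returns a model spec whose
#' state dimension is 4 when the dynamic secretory-capacity ingredient is
#' present and 3 otherwise.  The reserved name `"Topp"` (with no ingredients)
#' selects the legacy reference model: parabolic beta-cell growth with
#' exponential (non-logistic) mass dynamics and constant secretory capacity.
#'
#' @param name label for the model.
#' @param ingredients character vector of ingredient ids (see
#'   [ingredient_ids()]); may be empty.
#' @return an object of class `dmprog_model` with fields `name`,
#'   `ingredients`, `state_dimension`, `topp`.
#' @examples
#' build_model("Model1", "S_X")$state_dimension
#' build_model("Model5", c("S_X_AGE_I", "HGP_DYNAMIC", "CLEARANCE_SAT",
#'                         "SIGMA_DYNAMIC_CA", "LIPO_SIGMA_BIPHASIC"))
#' @export
build_model <- function(name, ingredients = character()) {
  ingredients <- unique(as.character(ingredients))
  bad <- setdiff(ingredients, .ingredient_ids)
  if (length(bad)) stop("unknown ingredient(s): ", paste(bad, collapse = ", "))
  si <- intersect(ingredients, c("S_X", "S_X_AGE", "S_X_AGE_I"))
  if (length(si) > 1)
    stop("ingredients ", paste(si, collapse = " and "),
         " are mutually exclusive (one insulin-sensitivity form at a time)")
  lip <- intersect(ingredients, c("LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC"))
  if (length(lip) > 1)
    stop("ingredients LIPO_SIGMA and LIPO_SIGMA_BIPHASIC are mutually exclusive")
  needs_sigma <- intersect(ingredients,
                           c("SIGMA_ENHANCED_GLU", "LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC"))
  if (length(needs_sigma) && !"SIGMA_DYNAMIC_CA" %in% ingredients)
    stop("ingredient(s) ", paste(needs_sigma, collapse = ", "),
         " require SIGMA_DYNAMIC_CA")
  topp <- identical(name, "Topp")
  if (topp && length(ingredients))
    stop("the Topp reference model takes no ingredients")
  structure(list(name = name, ingredients = ingredients,
                 state_dimension = if ("SIGMA_DYNAMIC_CA" %in% ingredients) 4L else 3L,
                 topp = topp),
            class = "dmprog_model")
}

#' Preset model specifications
#'
#' `"Topp"` is the recalibrated legacy reference model; `"Model1"` the base
#' model (bump growth, logistic mass dynamics, FFA-dependent insulin
#' sensitivity); `"base"` is Model 1 with the FFA dependence neutralised
#' (used for the insulin-sensitivity forcing experiments); `"Model5"` the
#' selected full model.
#'
#' @param name one of `"Topp"`, `"base"`, `"Model1"`, `"Model5"`.
#' @return a `dmprog_model`.
#' @export
model_preset <- function(name = c("Model1", "Topp", "base", "Model5")) {
  name <- match.arg(name)
  switch(name,
    Topp = build_model("Topp"),
    base = build_model("base"),
    Model1 = build_model("Model1", "S_X"),
    Model5 = build_model("Model5", c("S_X_AGE_I", "HGP_DYNAMIC", "CLEARANCE_SAT",
                                     "SIGMA_DYNAMIC_CA", "LIPO_SIGMA_BIPHASIC")))
}

#' @export
print.dmprog_model <- function(x, ...) {
  cat("<dmprog model> ", x$name, " (", x$state_dimension, " states)\n", sep = "")
  if (length(x$ingredients))
    cat("  ingredients:", paste(x$ingredients, collapse = ", "), "\n")
  else cat("  ingredients: none",
           if (x$topp) " (legacy Topp structure)" else "", "\n", sep = "")
  invisible(x)
}

# --- covariates -------------------------------------------------------------

#' Covariate track: baseline age and percent body fat over time
#'
#' Percent body fat (PFAT) is interpolated piecewise-linearly between visit
#' knots and held constant beyond the last knot; values outside \[7, 52\] are
#' clamped when converted to the excess-FFA index.
#'
#' @param age0 baseline age in years.
#' @param pfat_times knot times in days (strictly increasing).
#' @param pfat percent body fat at the knots.
#' @return an object of class `dmprog_covariates`.
#' @export
covariate_track <- function(age0, pfat_times = 0, pfat = 30) {
  stopifnot(is.finite(age0), length(pfat_times) == length(pfat),
            all(is.finite(pfat_times)), all(is.finite(pfat)))
  if (length(pfat_times) > 1 && any(diff(pfat_times) <= 0))
    stop("pfat knot times must be strictly increasing")
  structure(list(age0 = age0, pfat_times = as.numeric(pfat_times),
                 pfat = as.numeric(pfat)),
            class = "dmprog_covariates")
}

#' @rdname covariate_track
#' @param cov a covariate track.
#' @param t time(s) in days.
#' @export
pfat_at <- function(cov, t) {
  if (length(cov$pfat) == 1) return(rep(cov$pfat, length(t)))
  stats::approx(cov$pfat_times, cov$pfat, xout = t, rule = 2)$y
}

# --- auxiliary model functions (the composable ingredients) -----------------

#' Excess free-fatty-acid index from percent body fat
#'
#' Linear normalisation of percent body fat to the index X, zero at the
#' cohort minimum (7%) and one at the cohort maximum (52%), clamped to
#' \[0, 1.1\] so that moderately out-of-range adiposity is tolerated.
#'
#' @param pfat percent body fat.
#' @return X, dimensionless.
#' @examples
#' excess_ffa_index(c(7, 29.5, 52))
#' @export
excess_ffa_index <- function(pfat) {
  if (!all(is.finite(pfat))) stop("pfat must be finite")
  pmin(pmax((pfat - 7) / 45, 0), 1.1)
}

#' Insulin sensitivity function
#'
#' Insulin sensitivity is `SI_base` multiplied by up to three sigmoidal
#' attenuation factors: excess FFA (variant `S_X`), baseline age plus elapsed
#' time (`S_X_AGE`), and supra-basal insulin (`S_X_AGE_I`).  With
#' `variant = "none"` only the legacy exponential decay `exp(-c t)` applies.
#'
#' @param X excess-FFA index.
#' @param age0 baseline age (years).
#' @param t time since baseline (days).
#' @param I insulin (uU/ml), used by the `S_X_AGE_I` variant.
#' @param params parameter list.
#' @param variant one of `"none"`, `"S_X"`, `"S_X_AGE"`, `"S_X_AGE_I"`.
#' @return SI in ml/uU/day (strictly positive; errors if a parameter
#'   combination drives a factor non-positive).
#' @export
insulin_sensitivity <- function(X, age0 = 25, t = 0, I = NULL, params = default_params(),
                                variant = c("S_X", "none", "S_X_AGE", "S_X_AGE_I")) {
  variant <- match.arg(variant)
  mode <- match(variant, c("none", "S_X", "S_X_AGE", "S_X_AGE_I")) - 1L
  si <- params$SI_base * exp(-params$c * t)
  if (mode >= 1)
    si <- si * (1 - params$gX1 / (1 + exp(-params$gX2 * (X - params$gX3))))
  if (mode >= 2)
    si <- si * (1 - params$gA1 /
                  (1 + exp(-(age0 / params$gA0 + t / params$gA2 - params$gA3))))
  if (mode >= 3) {
    if (is.null(I)) stop("variant S_X_AGE_I requires the insulin level I")
    si <- si * (1 - params$gi1 * (I - params$I0)^2 /
                  ((I - params$I0)^2 + params$gi2^2))
  }
  if (any(si <= 0))
    stop("insulin sensitivity is non-positive for the supplied parameters")
  si
}

#' Hepatic glucose production rate
#'
#' `hepa_b + hepa_max / (hepa_km(X) + IIRh(I) * I)`, where `hepa_km`
#' decreases with excess FFA (strength `Hepasx`) and the insulin-induced
#' hepatic resistance factor `IIRh` decreases with insulin towards a positive
#' floor, so that insulin suppression of hepatic output saturates.
#'
#' @param I insulin (uU/ml), non-negative.
#' @param X excess-FFA index, non-negative.
#' @param params parameter list.
#' @return production rate in mg/dl/day.
#' @export
hgp_rate <- function(I, X, params = default_params()) {
  if (any(I < 0) || any(X < 0)) stop("I and X must be non-negative")
  km <- hepa_km(X, params)
  params$hepa_b + params$hepa_max / (km + iirh(I, params) * I)
}

#' @rdname hgp_rate
#' @export
hepa_km <- function(X, params = default_params()) {
  params$hk0 * (1 - params$Hepasx * X^4 / (X^4 + 0.5^4))
}

#' @rdname hgp_rate
#' @export
iirh <- function(I, params = default_params()) {
  params$iir_min + (1 - params$iir_min) / (1 + (I / params$iir_k)^params$iir_h)
}

#' Saturating insulin clearance rate
#'
#' Hyperbolic clearance `K(I) = k1/(k2 + I)`; the clearance flux `K(I) * I`
#' increases with insulin and saturates at `k1`.
#'
#' @param I insulin (uU/ml), non-negative.
#' @param params parameter list.
#' @return clearance rate in 1/day.
#' @export
insulin_clearance <- function(I, params = default_params()) {
  if (any(I < 0)) stop("I must be non-negative")
  params$k1 / (params$k2 + I)
}

#' Glucose-driven cytosolic calcium
#'
#' Saturating Hill function `Ca_b + Ca1 * G^mt / (G^mt + Ca2^mt)`.
#'
#' @param G glucose (mg/dl), non-negative.
#' @param params parameter list.
#' @return calcium level (dimensionless concentration).
#' @export
calcium <- function(G, params = default_params()) {
  stopifnot(all(G >= 0))
  params$Ca_b + params$Ca1 * G^params$mt / (G^params$mt + params$Ca2^params$mt)
}

#' Calcium-triggered secretion drive
#'
#' `f_I(Ca) = (Ca - Ca_b)^mz / ((Ca - Ca_b)^mz + Ca3^mz)`, zero at baseline
#' calcium and saturating below one.
#'
#' @param Ca calcium level, at least `Ca_b`.
#' @param params parameter list.
#' @return drive in \[0, 1).
#' @export
secretion_drive <- function(Ca, params = default_params()) {
  if (any(Ca < params$Ca_b)) stop("Ca must be >= Ca_b")
  d <- (Ca - params$Ca_b)^params$mz
  d / (d + params$Ca3^params$mz)
}

#' Steady-state beta-cell secretory capacity
#'
#' The glucose part multiplies a gain term (increasing in G) by a
#' glucotoxic decline term whose threshold is lowered by calcium (calcium
#' toxicity), plus an offset: `f = f_gd * f_bd + sigma1`.  An active lipid
#' ingredient multiplies this by `f2(X)`: purely lipotoxic
#' (`1 - sigma10 X^6/(X^6 + sigma11^6)`) or biphasic
#' (`1 + X^8/(X^8 + sigma10^8) - sigma11 X^9/(X^9 + sigma12^9)`).
#'
#' @param G glucose (mg/dl).
#' @param Ca calcium level (from [calcium()]).
#' @param X excess-FFA index.
#' @param params parameter list.
#' @param lipid `"none"`, `"LIPO_SIGMA"` or `"LIPO_SIGMA_BIPHASIC"`.
#' @param enhanced logical; apply the raised glucose-sensitivity multipliers.
#' @return sigma-infinity (secretion units per mg per day), non-negative.
#' @export
sigma_steady_state <- function(G, Ca, X = 0, params = default_params(),
                               lipid = c("none", "LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC"),
                               enhanced = FALSE) {
  lipid <- match.arg(lipid)
  s3 <- params$sigma3 * if (enhanced) params$enh3 else 1
  s4 <- params$sigma4 * if (enhanced) params$enh4 else 1
  f_gd <- params$sigma2 / (1 + exp(-s3 * (G - s4)))
  sCa <- params$sigma7 - params$sigma8 * Ca^6 / (Ca^6 + params$sigma_g^6)
  f_bd <- 1 - 1 / (1 + params$sigma5 * exp(-params$sigma6 * (G - sCa)))
  f_glu <- f_gd * f_bd + params$sigma1
  f2 <- switch(lipid,
    none = 1,
    LIPO_SIGMA = 1 - params$sigma10 * X^6 / (X^6 + params$sigma11^6),
    LIPO_SIGMA_BIPHASIC = 1 + X^8 / (X^8 + params$sigma10^8) -
      params$sigma11 * X^9 / (X^9 + params$sigma12^9))
  pmax(params$sigma0 * f_glu * f2, 0)
}

#' Beta-cell mass net growth rate
#'
#' The bump form `b1 / (((G - G1)/b2)^4 + 1) - b3` bounds the glucotoxic
#' mass loss at `-b3` (unlike the legacy parabola, which is unbounded below)
#' and peaks at `b1 - b3` at `G = G1`; its roots sit at
#' `G1 +/- b2 (b1/b3 - 1)^(1/4)`.  With the lipotoxic-mass ingredient a
#' further loss `-b4 X^6/(X^6 + b5^6)` applies.  `topp = TRUE` selects the
#' legacy parabola `b0 (G - Gb1)(Gb2 - G)`.
#'
#' @param G glucose (mg/dl), non-negative.
#' @param X excess-FFA index.
#' @param params parameter list.
#' @param lipo_mass logical; include the lipotoxic mass-loss term.
#' @param topp logical; use the legacy parabolic form.
#' @return net growth rate in 1/day (before the logistic factor and
#'   `1/tau_beta` scaling applied in the mass equation).
#' @export
beta_growth_rate <- function(G, X = 0, params = default_params(),
                             lipo_mass = FALSE, topp = FALSE) {
  stopifnot(all(G >= 0))
  if (topp) return(params$b0 * (G - params$Gb1) * (params$Gb2 - G))
  f <- params$b1 / (((G - params$G1) / params$b2)^4 + 1) - params$b3
  if (lipo_mass) f <- f - params$b4 * X^6 / (X^6 + params$b5^6)
  f
}

#' Roots of the bump growth function
#'
#' Closed-form zeros `G1 +/- b2 (b1/b3 - 1)^(1/4)` of the bump form.
#'
#' @param params parameter list.
#' @return numeric length-2 vector (lower, upper root).
#' @export
beta_growth_roots <- function(params = default_params()) {
  half <- params$b2 * (params$b1 / params$b3 - 1)^(1 / 4)
  c(params$G1 - half, params$G1 + half)
}

# --- the right-hand side ----------------------------------------------------

#' Right-hand side of the progression ODE system
#'
#' Plain-R reference implementation of the model family derivative.  The
#' compiled equivalent (used by [integrate_model()]) is asserted against this
#' function in the test suite.
#'
#' State is `c(G, I, beta)` or `c(G, I, beta, sigma)` when the dynamic-sigma
#' ingredient is active.  Glucose balance uses the constant influx `Gin`
#' unless `HGP_DYNAMIC` is present, in which case influx is the meal constant
#' plus the hepatic production rate.  The mass equation uses the logistic
#' factor `(1 - beta/beta_max)` except for the legacy Topp structure.
#'
#' @param state numeric state vector.
#' @param t time (days).
#' @param spec model spec from [build_model()].
#' @param params parameter list.
#' @param cov covariate track from [covariate_track()].
#' @param forcing optional insulin-sensitivity forcing from [si_forcing()].
#' @return named derivative vector, d(state)/dt.
#' @export
model_rhs <- function(state, t, spec, params = default_params(),
                      cov = covariate_track(25), forcing = NULL) {
  nd <- spec$state_dimension
  if (length(state) != nd)
    stop("state has length ", length(state), " but the model needs ", nd)
  if (any(!is.finite(state))) stop("non-finite state")
  G <- max(state[1], 0); I <- max(state[2], 0); beta <- max(state[3], 0)
  X <- excess_ffa_index(pfat_at(cov, t))
  dyn_sigma <- "SIGMA_DYNAMIC_CA" %in% spec$ingredients

  variant <- if ("S_X_AGE_I" %in% spec$ingredients) "S_X_AGE_I"
             else if ("S_X_AGE" %in% spec$ingredients) "S_X_AGE"
             else if ("S_X" %in% spec$ingredients) "S_X" else "none"
  si <- insulin_sensitivity(X, cov$age0, t, I, params, variant)
  si <- si * si_forcing_multiplier(forcing, t)

  influx <- if ("HGP_DYNAMIC" %in% spec$ingredients)
    params$meal_const + hgp_rate(I, X, params) else params$Gin
  dG <- influx - params$SG * G - si * I * G

  if (dyn_sigma) {
    sigma <- max(state[4], 0)
    Ca <- calcium(G, params)
    drive <- secretion_drive(Ca, params)
  } else {
    sigma <- params$sigma_const
    drive <- G^2 / (G^2 + params$alpha^2)
  }
  clr <- if ("CLEARANCE_SAT" %in% spec$ingredients)
    insulin_clearance(I, params) else params$K
  dI <- sigma * drive * beta - clr * I

  fb <- beta_growth_rate(G, X, params,
                         lipo_mass = "LIPO_MASS" %in% spec$ingredients,
                         topp = spec$topp)
  dbeta <- if (spec$topp) fb * beta / params$tau_beta
           else fb * beta * (1 - beta / params$beta_max) / params$tau_beta

  out <- c(G = dG, I = dI, beta = dbeta)
  if (dyn_sigma) {
    lipid <- if ("LIPO_SIGMA_BIPHASIC" %in% spec$ingredients) "LIPO_SIGMA_BIPHASIC"
             else if ("LIPO_SIGMA" %in% spec$ingredients) "LIPO_SIGMA" else "none"
    s_inf <- sigma_steady_state(G, Ca, X, params, lipid,
                                enhanced = "SIGMA_ENHANCED_GLU" %in% spec$ingredients)
    out <- c(out, sigma = (s_inf - sigma) / params$tau_sigma)
  }
  out
}
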