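#' Default parameter set for the progression model family
#'
#' Returns the curated default [ParameterSet][default_params] used throughout
#' the package.  Values printed in the calibration of the base model are fixed
#' (`SG = 17` per day, `SI_base = 1` ml/uU/day, `Gin = 2560` mg/dl/day,
#' `Gb2 = 90` mg/dl, basal glucose 80 mg/dl); the remaining shape and rate
#' constants are curated so that the calibrated base model (and the
#' four-variable model with neutral covariates) has a stable fixed point at
#' G = 80 mg/dl, I = 15 uU/ml, beta = 300 mg.
#'
#' Parameter groups (units):
#' \describe{
#'   \item{glucose}{`Gin` (mg/dl/day), `SG` (1/day), `SI_base` (ml/uU/day).}
#'   \item{topp_legacy}{`c` (1/day, legacy exponential decay of insulin
#'     sensitivity; 0 disables it), `alpha` (mg/dl, half-max of the
#'     glucose-driven secretion Hill term), `b0`, `Gb1`, `Gb2` (mg/dl, roots
#'     of the legacy parabolic growth function), `K` (1/day, constant insulin
#'     clearance), `tau_beta` (days), `sigma_const` (secretion capacity used
#'     when the dynamic-sigma ingredient is off).}
#'   \item{S_X}{`gX1` (max fractional loss of insulin sensitivity to excess
#'     FFA, in \[0,1\]), `gX2` (steepness), `gX3` (X at half effect).}
#'   \item{S_AGE}{`gA0` (years), `gA1` (max fractional loss, \[0,1\]), `gA2`
#'     (days), `gA3` (shift).}
#'   \item{S_I}{`gi1` (max fractional loss, \[0,1\]), `gi2` (uU/ml), `I0`
#'     (uU/ml, basal insulin).}
#'   \item{HGP}{`hepa_b` (mg/dl/day floor), `hepa_max` (mg/dl/day scale),
#'     `hk0` (baseline of the insulin half-suppression constant), `Hepasx`
#'     (\[0,1), strength of the FFA shift of `hepa_km`), `iir_min` (positive
#'     floor of the insulin-induced hepatic resistance factor), `iir_k`
#'     (uU/ml), `iir_h` (Hill exponent), `meal_const` (mg/dl/day meal part of
#'     glucose influx when dynamic HGP is active).}
#'   \item{clearance}{`k1` (uU/ml/day saturation flux), `k2` (uU/ml).}
#'   \item{calcium}{`Ca_b`, `Ca1` (baseline and span of cytosolic calcium),
#'     `Ca2` (mg/dl half-max glucose), `Ca3` (half-max of the secretion
#'     drive), `mt`, `mz` (Hill exponents).}
#'   \item{sigma_dyn}{`sigma0` (scale of steady-state secretory capacity),
#'     `sigma1` ... `sigma8`, `sigma_g`, `sigma10`, `sigma11`, `sigma12`
#'     (shape constants of the glucose-dependent and lipid-dependent parts),
#'     `tau_sigma` (days), `enh3`, `enh4` (multipliers applied to `sigma3`,
#'     `sigma4` by the enhanced-glucose-sensitivity ingredient).}
#'   \item{beta_growth}{`b1`, `b2` (mg/dl), `b3` (bump-function shape; the
#'     bump has roots at `G1 +/- b2*(b1/b3 - 1)^(1/4)`, placed at 80 and 90
#'     mg/dl by default), `b4`, `b5` (lipotoxic mass-loss term), `G1` (mg/dl),
#'     `beta_max` (mg).}
#' }
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `dmprog_params`.
#' @examples
#' p <- default_params()
#' p$Gin
#' default_params(gX1 = 0)$gX1
#' @export
default_params <- function(...) {
  f_I80 <- 80^2 / (80^2 + 20000)             # Hill drive at basal glucose
  p <- list(
    # glucose
    Gin = 2560, SG = 17, SI_base = 1,
    # topp legacy
    c = 0, alpha = sqrt(20000), b0 = 0.06, Gb1 = 80, Gb2 = 90,
    K = 432, tau_beta = 1800,
    sigma_const = 432 * 15 / (f_I80 * 300),
    # S_X
    gX1 = 0.8, gX2 = 6, gX3 = 0.4,
    # S_AGE
    gA0 = 30, gA1 = 0.3, gA2 = 10950, gA3 = 2,
    # S_I
    gi1 = 0.4, gi2 = 40, I0 = 15,
    # HGP
    hepa_b = 286, hepa_max = 18336, hk0 = 10, Hepasx = 0.5,
    iir_min = 0.3, iir_k = 40, iir_h = 2, meal_const = 1500,
    # clearance
    k1 = 49680, k2 = 100,
    # calcium / secretion
    Ca_b = 0.05, Ca1 = 0.25, Ca2 = 140, Ca3 = 0.06, mt = 4, mz = 2,
    # dynamic sigma
    sigma0 = NA_real_, sigma1 = 0.1, sigma2 = 1.2, sigma3 = 0.05,
    sigma4 = 100, sigma5 = 20, sigma6 = 0.32, sigma7 = 95, sigma8 = 15,
    sigma_g = 0.15, sigma10 = 0.55, sigma11 = 1.7, sigma12 = 0.85,
    tau_sigma = 30, enh3 = 1.5, enh4 = 1.1,
    # beta growth
    b1 = 3, b2 = 5, b3 = 1.5, b4 = 1, b5 = 0.8, G1 = 85, beta_max = 1000
  )
  # sigma0 closes the four-variable fixed point at (G, I, beta) = (80, 15, 300)
  # with neutral covariates: sigma_inf(80) * f_I(Ca(80)) * 300 = K * 15.
  Ca80 <- p$Ca_b + p$Ca1 * 80^p$mt / (80^p$mt + p$Ca2^p$mt)
  fI80 <- (Ca80 - p$Ca_b)^p$mz / ((Ca80 - p$Ca_b)^p$mz + p$Ca3^p$mz)
  sig_req <- p$K * 15 / (fI80 * 300)
  sCa <- p$sigma7 - p$sigma8 * Ca80^6 / (Ca80^6 + p$sigma_g^6)
  f_gd <- p$sigma2 / (1 + exp(-p$sigma3 * (80 - p$sigma4)))
  f_bd <- 1 - 1 / (1 + p$sigma5 * exp(-p$sigma6 * (80 - sCa)))
  p$sigma0 <- sig_req / (f_gd * f_bd + p$sigma1)

  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  structure(p, class = "dmprog_params")
}

#' Validate a parameter set
#'
#' Checks positivity of rates and half-max constants, the \[0,1\] range of the
#' fractional-effect parameters, and `b1 > b3` (so the bump growth function
#' has two real roots).
#'
#' @param params a list as returned by [default_params()].
#' @return `params`, invisibly; errors on violation.
#' @export
validate_params <- function(params) {
  stopifnot(is.list(params))
  need <- names(default_params())
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  num <- vapply(params[need], function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("non-finite parameter(s): ", paste(need[!num], collapse = ", "))
  pos <- c("Gin", "SG", "SI_base", "alpha", "K", "tau_beta", "sigma_const",
           "gX2", "gA0", "gA2", "gi2", "hk0", "iir_k", "iir_h", "k1", "k2",
           "Ca1", "Ca2", "Ca3", "mt", "mz", "sigma0", "tau_sigma",
           "b1", "b2", "beta_max")
  low <- vapply(pos, function(nm) params[[nm]] <= 0, logical(1))
  if (any(low)) stop("parameter(s) must be > 0: ", paste(pos[low], collapse = ", "))
  unit <- c("gX1", "gA1", "gi1", "sigma10", "Hepasx")
  out <- vapply(unit, function(nm) params[[nm]] < 0 || params[[nm]] > 1, logical(1))
  if (any(out)) stop("parameter(s) must lie in [0, 1]: ", paste(unit[out], collapse = ", "))
  if (params$iir_min <= 0) stop("iir_min must be > 0 (suppression floor)")
  if (params$b1 <= params$b3) stop("b1 must exceed b3 (bump needs two real roots)")
  invisible(params)
}

# --- internal: packing for the compiled right-hand side ---------------------

.parm_names <- c(
  "Gin", "SG", "SI_base",
  "c", "alpha", "b0", "Gb1", "Gb2", "K", "tau_beta", "sigma_const",
  "gX1", "gX2", "gX3",
  "gA0", "gA1", "gA2", "gA3",
  "gi1", "gi2", "I0",
  "hepa_b", "hepa_max", "hk0", "Hepasx", "iir_min", "iir_k", "iir_h", "meal_const",
  "k1", "k2",
  "Ca_b", "Ca1", "Ca2", "Ca3", "mt", "mz",
  "sigma0", "sigma1", "sigma2", "sigma3", "sigma4", "sigma5", "sigma6",
  "sigma7", "sigma8", "sigma_g", "sigma10", "sigma11", "sigma12",
  "tau_sigma", "enh3", "enh4",
  "b1", "b2", "b3", "b4", "b5", "G1", "beta_max",
  "AGE0",
  "flag_si_mode", "flag_topp", "flag_hgp", "flag_clear", "flag_sigma_dyn",
  "flag_enh", "flag_lipo_mass", "flag_lipo",
  "force_mode", "force_drop", "force_t0", "force_t1", "force_tau"
)

# Flatten params + spec + covariate/forcing meta into the double vector the
# compiled derivative function expects.
pack_parms <- function(spec, params, age0 = 25, forcing = NULL) {
  v <- stats::setNames(numeric(length(.parm_names)), .parm_names)
  for (nm in setdiff(names(params), "class")) {
    if (nm %in% .parm_names) v[nm] <- params[[nm]]
  }
  ing <- spec$ingredients
  v["AGE0"] <- age0
  v["flag_si_mode"] <- if ("S_X_AGE_I" %in% ing) 3 else if ("S_X_AGE" %in% ing) 2
                       else if ("S_X" %in% ing) 1 else 0
  v["flag_topp"] <- as.numeric(isTRUE(spec$topp))
  v["flag_hgp"] <- as.numeric("HGP_DYNAMIC" %in% ing)
  v["flag_clear"] <- as.numeric("CLEARANCE_SAT" %in% ing)
  v["flag_sigma_dyn"] <- as.numeric("SIGMA_DYNAMIC_CA" %in% ing)
  v["flag_enh"] <- as.numeric("SIGMA_ENHANCED_GLU" %in% ing)
  v["flag_lipo_mass"] <- as.numeric("LIPO_MASS" %in% ing)
  v["flag_lipo"] <- if ("LIPO_SIGMA_BIPHASIC" %in% ing) 2
                    else if ("LIPO_SIGMA" %in% ing) 1 else 0
  if (!is.null(forcing)) {
    v["force_mode"] <- switch(forcing$mode, none = 0, step = 1, exponential = 2)
    v["force_drop"] <- forcing$drop
    v["force_t0"] <- forcing$t_on %||% 0
    v["force_t1"] <- forcing$t_off %||% 0
    v["force_tau"] <- forcing$tau %||% 1
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a model configuration (YAML)
#'
#' A configuration file stores the model name, the ingredient list (by
#' ingredient id) and any parameter overrides, grouped flat by parameter
#' name.
#'
#' @param path file path.
#' @param spec a model spec from [build_model()].
#' @param params a parameter list from [default_params()].
#' @return `read_model_config()` returns `list(spec =, params =)`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- build_model(cfg$name %||% "model", as.character(cfg$ingredients %||% character()))
  params <- do.call(default_params, as.list(cfg$params %||% list()))
  list(spec = spec, params = params)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(path, spec, params = default_params()) {
  defaults <- unclass(default_params())
  over <- params[vapply(names(defaults), function(nm)
    !isTRUE(all.equal(params[[nm]], defaults[[nm]])), logical(1))]
  yaml::write_yaml(list(name = spec$name,
                        ingredients = as.list(spec$ingredients),
                        params = over), path)
  invisible(path)
}
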