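#' Configuration for the synthetic longitudinal cohort generator
#'
#' The generator emulates a biennial-visit progression study: subjects are
#' euglycemic at baseline (observed fasting glucose below the prediabetes
#' surrogate threshold), adiposity drifts over follow-up, and the chosen
#' structural model is integrated per subject with log-normally (or, for
#' unit-interval parameters, logit-normally) distributed individual
#' parameters and proportional observation noise.
#'
#' Baseline marginals target the progression cohort's characteristics:
#' age 24.8 (6.6) years, percent body fat 36 (7.8), observed fasting glucose
#' 88.4 (10.1) mg/dl, follow-up 6 (2.7) years.
#'
#' @param n_subjects cohort size.
#' @param spec structural model (default: the full selected model).
#' @param params population parameters.
#' @param scales named vector, mapping model insulin sensitivity and
#'   beta-cell function to the Matsuda and insulinogenic indices.
#' @param omega named vector of random-effect SDs (transformed scale) for a
#'   subset of parameter/scale names.
#' @param error_sd named vector of proportional (log-scale) observation
#'   noise SDs for `fpg`, `fpi`, `matsuda`, `igi`.
#' @param age0_mean,age0_sd,age0_range baseline-age distribution (years).
#' @param pfat0_mean,pfat0_sd baseline percent body fat.
#' @param pfat_slope_mean,pfat_slope_sd per-subject linear drift (% per year).
#' @param pfat_jitter visit-level Gaussian jitter of percent body fat.
#' @param g0_mean,g0_sd,g0_range baseline true fasting-glucose distribution
#'   (mg/dl); the location is set above the observed target because the
#'   baseline-euglycemia inclusion rule truncates the observed distribution
#'   from above.
#' @param followup_mean,followup_sd,followup_range follow-up duration (years).
#' @param visit_jitter SD of visit-time jitter (days).
#' @param threshold_pred,threshold_t2d fasting-glucose surrogate thresholds
#'   (mg/dl) for prediabetes and diabetes labels.
#' @param max_retries resampling attempts for subjects whose model
#'   integration fails or who cannot satisfy baseline inclusion.
#' @param make_ogtt also emit a per-visit OGTT curve consistent with the
#'   visit's fasting state and indices.
#' @return a list of class `dmprog_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17,
                          spec = model_preset("Model5"),
                          params = default_params(),
                          scales = c(c_si = 3.4, c_sigma_beta = 2.4e-05),
                          omega = c(gX1 = 0.25, gX2 = 0.2, sigma6 = 0.25,
                                    Hepasx = 0.3, gi1 = 0.3, gA1 = 0.3,
                                    gA2 = 0.2, c_si = 0.2, c_sigma_beta = 0.2),
                          error_sd = c(fpg = 0.07, fpi = 0.15,
                                       matsuda = 0.20, igi = 0.20),
                          age0_mean = 24.8, age0_sd = 6.6, age0_range = c(15, 45),
                          pfat0_mean = 36, pfat0_sd = 7.8,
                          pfat_slope_mean = 1.2, pfat_slope_sd = 0.8,
                          pfat_jitter = 1.2,
                          g0_mean = 92, g0_sd = 8, g0_range = c(60, 100),
                          followup_mean = 6, followup_sd = 2.7,
                          followup_range = c(2, 12),
                          visit_jitter = 90,
                          threshold_pred = 100, threshold_t2d = 115,
                          max_retries = 5, make_ogtt = FALSE) {
  stopifnot(n_subjects >= 1, all(omega >= 0), all(error_sd >= 0))
  validate_params(params)
  structure(as.list(environment()), class = "dmprog_cohort_config")
}

.logit_params <- c("gX1", "gA1", "gi1", "Hepasx", "sigma10")

.logit <- function(x) log(x / (1 - x))
.expit <- function(x) 1 / (1 + exp(-x))

# transform a positive/unit-interval parameter value to the Gaussian scale
param_to_phi <- function(value, name) {
  if (name %in% .logit_params) .logit(value) else log(value)
}

phi_to_param <- function(phi, name) {
  if (name %in% .logit_params) .expit(phi) else exp(phi)
}

#' Sample individual parameters around the population values
#'
#' Individual parameters are `theta_i = theta_pop * exp(eta_i)` with
#' `eta_i ~ N(0, omega^2)` independently per parameter (log-normal);
#' parameters constrained to the unit interval use the equivalent
#' logit-normal form so that individual values respect their bounds.
#'
#' @param params population parameter list.
#' @param scales population scale factors.
#' @param omega named vector of random-effect SDs.
#' @param n number of individuals.
#' @return list of per-individual lists with elements `params`, `scales`,
#'   `eta` (the named random-effect draws).
#' @export
sample_individual_parameters <- function(params, scales, omega, n = 1) {
  nm <- names(omega)
  lapply(seq_len(n), function(i) {
    eta <- stats::rnorm(length(nm), 0, omega)
    names(eta) <- nm
    pi <- params; si <- scales
    for (k in nm) {
      if (k %in% names(scales))
        si[[k]] <- phi_to_param(param_to_phi(scales[[k]], k) + eta[[k]], k)
      else
        pi[[k]] <- phi_to_param(param_to_phi(params[[k]], k) + eta[[k]], k)
    }
    list(params = pi, scales = si, eta = eta)
  })
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# consistent initial state for one subject: basal insulin closes the glucose
# balance at G0, secretory capacity sits at its steady state, mass closes the
# insulin balance.
.initial_state <- function(spec, params, G0, X0, age0) {
  variant <- if ("S_X_AGE_I" %in% spec$ingredients) "S_X_AGE_I"
             else if ("S_X_AGE" %in% spec$ingredients) "S_X_AGE"
             else if ("S_X" %in% spec$ingredients) "S_X" else "none"
  balance <- function(I) {
    si <- insulin_sensitivity(X0, age0, 0, I, params, variant)
    influx <- if ("HGP_DYNAMIC" %in% spec$ingredients)
      params$meal_const + hgp_rate(I, X0, params) else params$Gin
    influx - params$SG * G0 - si * I * G0
  }
  I0 <- stats::uniroot(balance, c(0.01, 2000), tol = 1e-10)$root
  if (spec$state_dimension == 4) {
    Ca <- calcium(G0, params)
    lipid <- if ("LIPO_SIGMA_BIPHASIC" %in% spec$ingredients) "LIPO_SIGMA_BIPHASIC"
             else if ("LIPO_SIGMA" %in% spec$ingredients) "LIPO_SIGMA" else "none"
    sig <- sigma_steady_state(G0, Ca, X0, params, lipid,
                              enhanced = "SIGMA_ENHANCED_GLU" %in% spec$ingredients)
    drive <- secretion_drive(Ca, params)
  } else {
    sig <- params$sigma_const
    drive <- G0^2 / (G0^2 + params$alpha^2)
  }
  clr <- if ("CLEARANCE_SAT" %in% spec$ingredients)
    insulin_clearance(I0, params) else params$K
  beta0 <- clr * I0 / (sig * drive)
  beta0 <- min(max(beta0, 1), 0.95 * params$beta_max)
  init <- c(G = G0, I = I0, beta = beta0)
  if (spec$state_dimension == 4) init <- c(init, sigma = sig)
  init
}

.simulate_subject <- function(cfg, id) {
  age0 <- .rtruncnorm1(cfg$age0_mean, cfg$age0_sd, cfg$age0_range[1], cfg$age0_range[2])
  pfat0 <- .rtruncnorm1(cfg$pfat0_mean, cfg$pfat0_sd, 7, 52)
  slope <- stats::rnorm(1, cfg$pfat_slope_mean, cfg$pfat_slope_sd)
  followup <- .rtruncnorm1(cfg$followup_mean, cfg$followup_sd,
                           cfg$followup_range[1], cfg$followup_range[2])
  n_vis <- min(max(3L, 1L + as.integer(round(followup / 2))), 8L)
  vt <- seq(0, followup * 365.25, length.out = n_vis)
  if (n_vis > 2 && cfg$visit_jitter > 0) {
    mingap <- min(diff(vt)) / 3
    jit <- stats::rnorm(n_vis - 2, 0, cfg$visit_jitter)
    vt[2:(n_vis - 1)] <- vt[2:(n_vis - 1)] + jit
    vt <- cummax(pmax(vt, c(0, seq_len(n_vis - 1) * mingap)))
    vt <- vt + c(0, cumsum(rep(1e-6, n_vis - 1)))   # strictly increasing
  }
  pfat <- pfat0 + slope * vt / 365.25 +
    c(0, stats::rnorm(n_vis - 1, 0, cfg$pfat_jitter))
  pfat <- pmin(pmax(pfat, 7), 52)

  indiv <- sample_individual_parameters(cfg$params, cfg$scales, cfg$omega, 1)[[1]]
  G0 <- .rtruncnorm1(cfg$g0_mean, cfg$g0_sd, cfg$g0_range[1], cfg$g0_range[2])
  # anchor the individual glycemic set point: the beta-cell growth function's
  # lower root sits at the subject's baseline glucose, so baseline is an
  # equilibrium and progression is driven by covariate drift and the
  # secretory-capacity dynamics rather than by the initial condition
  half <- indiv$params$G1 - beta_growth_roots(indiv$params)[1]
  indiv$params$G1 <- G0 + half
  indiv$params$Gb1 <- G0
  indiv$params$Gb2 <- G0 + 2 * half
  cov <- covariate_track(age0, vt, pfat)
  init <- .initial_state(cfg$spec, indiv$params, G0, excess_ffa_index(pfat[1]), age0)

  grid <- sort(unique(c(seq(0, max(vt), length.out = 60), vt)))
  traj <- integrate_model(cfg$spec, indiv$params, cov, times = grid, init = init,
                          rtol = 1e-8, atol = 1e-8)
  obs <- model_to_observables(traj, vt, indiv$scales)

  sd <- cfg$error_sd
  for (col in names(sd))
    obs[[col]] <- obs[[col]] * exp(stats::rnorm(n_vis, 0, sd[[col]]))
  # inclusion rule: observed baseline fasting glucose must be euglycemic
  tries <- 0
  while (obs$fpg[1] >= cfg$threshold_pred && tries < 20) {
    obs$fpg[1] <- traj$G[1] * exp(stats::rnorm(1, 0, sd[["fpg"]]))
    tries <- tries + 1
  }
  if (obs$fpg[1] >= cfg$threshold_pred) return(NULL)

  ogtt <- NULL
  if (cfg$make_ogtt)
    ogtt <- lapply(seq_len(n_vis), function(j)
      tryCatch(ogtt_from_indices(obs$fpg[j], obs$fpi[j], obs$matsuda[j], obs$igi[j]),
               error = function(e) NULL))

  visits <- cbind(obs, age_years = age0 + vt / 365.25, pfat = pfat)
  subj <- structure(list(subject_id = id, age0 = age0, cov = cov,
                         visits = visits, init = init,
                         true_params = indiv$params, true_scales = indiv$scales,
                         eta = indiv$eta, ogtt = ogtt),
                    class = "dmprog_subject")
  subj$label <- classify_progression(subj, cfg$threshold_pred, cfg$threshold_t2d)
  subj
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-subject baselines and visit schedules, samples individual
#' parameters, integrates the structural model along the subject's adiposity
#' track, emits noisy observations of the four fitted variables at visit
#' times, and labels glucose-tolerance progression.  Subjects whose model
#' integration fails or who cannot satisfy baseline inclusion are resampled
#' (up to `max_retries` extra draws each).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is fully reproducible from
#'   (config, seed).
#' @return a list of `dmprog_subject` records, class `dmprog_cohort`, with
#'   the config attached as an attribute.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  cohort <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subj <- NULL
    for (try in 0:config$max_retries) {
      subj <- tryCatch(.simulate_subject(config, i), error = function(e) NULL)
      if (!is.null(subj)) break
    }
    if (is.null(subj))
      stop("subject ", i, " could not be generated after ",
           config$max_retries + 1, " attempts")
    cohort[[i]] <- subj
  }
  structure(cohort, class = "dmprog_cohort", config = config)
}

#' Classify glucose-tolerance progression of a subject
#'
#' The label is the most severe state reached over all visits, using
#' fasting-glucose surrogate thresholds.  The surrogates sit below the
#' conventional fasting diagnostic cuts because, in progression cohorts
#' selected on 2-hour glucose, fasting glucose at the 2-hour diagnostic
#' crossing is systematically lower than the fasting threshold.
#'
#' @param subject a `dmprog_subject` (needs a `visits$fpg` column).
#' @param threshold_pred,threshold_t2d surrogate thresholds (mg/dl).
#' @return `"NGT"`, `"preD"` or `"T2D"`.
#' @export
classify_progression <- function(subject, threshold_pred = 100, threshold_t2d = 115) {
  fpg <- subject$visits$fpg
  if (!length(fpg)) stop("subject has no visits")
  if (any(fpg >= threshold_t2d, na.rm = TRUE)) "T2D"
  else if (any(fpg >= threshold_pred, na.rm = TRUE)) "preD"
  else "NGT"
}

#' Baseline characteristics of a cohort
#'
#' @param cohort a `dmprog_cohort`.
#' @return data frame with mean and SD of baseline age, percent body fat,
#'   fasting glucose and insulin, Matsuda and insulinogenic indices, and
#'   follow-up (years), plus a `label` attribute with the progression counts.
#' @export
summarize_baseline <- function(cohort) {
  if (!length(cohort)) stop("empty cohort")
  base <- t(vapply(cohort, function(s) {
    v <- s$visits
    c(age = v$age_years[1], pfat = v$pfat[1], fpg = v$fpg[1], fpi = v$fpi[1],
      matsuda = v$matsuda[1], igi = v$igi[1],
      followup_years = (max(v$t_days) - min(v$t_days)) / 365.25)
  }, numeric(7)))
  out <- data.frame(characteristic = colnames(base),
                    mean = colMeans(base),
                    sd = apply(base, 2, function(x) if (nrow(base) > 1) stats::sd(x) else 0),
                    row.names = NULL)
  attr(out, "labels") <- table(vapply(cohort, `[[`, character(1), "label"))
  out
}

#' Read or write a cohort as a flat CSV
#'
#' One row per visit with columns `subject_id`, `t_days`, `age_years`,
#' `pfat`, `fpg`, `fpi`, `matsuda`, `igi` (empty cell = missing).
#' `write_cohort_truth()` stores the per-subject true simulation parameters
#' for recovery tests.
#'
#' @param cohort a `dmprog_cohort`.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort, function(s)
    cbind(subject_id = s$subject_id,
          s$visits[c("t_days", "age_years", "pfat", "fpg", "fpi", "matsuda", "igi")])))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "t_days", "age_years", "pfat", "fpg", "fpi", "matsuda", "igi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  cohort <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$t_days), ]
    subj <- structure(list(
      subject_id = d$subject_id[1],
      age0 = d$age_years[1] - d$t_days[1] / 365.25,
      cov = covariate_track(d$age_years[1], d$t_days, d$pfat),
      visits = d[c("t_days", "fpg", "fpi", "matsuda", "igi", "age_years", "pfat")]),
      class = "dmprog_subject")
    subj$label <- classify_progression(subj)
    subj
  })
  structure(unname(cohort), class = "dmprog_cohort")
}

#' @rdname write_cohort
#' @export
write_cohort_truth <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort, function(s) {
    if (is.null(s$true_params)) stop("cohort carries no true parameters")
    vals <- c(unlist(s$true_params[names(s$true_params) != "class"]), s$true_scales)
    data.frame(subject_id = s$subject_id, t(vals))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dmprog_cohort <- function(x, ...) {
  labs <- table(vapply(x, `[[`, character(1), "label"))
  cat("<dmprog cohort> ", length(x), " subjects; labels: ",
      paste(names(labs), as.integer(labs), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
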