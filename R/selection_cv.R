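#' Admissible single-ingredient additions to a model
#'
#' An addition from the pool is admissible when the resulting set satisfies
#' the ingredient rules; adding a richer insulin-sensitivity form supersedes
#' the one currently present, and sigma-modifying ingredients are only
#' admissible once the dynamic-sigma ingredient is in the model.
#'
#' @param spec current model spec.
#' @param pool candidate ingredient ids.
#' @return named list of candidate ingredient sets (name = added
#'   ingredient).
#' @export
admissible_additions <- function(spec, pool) {
  pool <- setdiff(pool, spec$ingredients)
  out <- list()
  for (ing in pool) {
    set <- spec$ingredients
    if (ing %in% c("S_X", "S_X_AGE", "S_X_AGE_I"))
      set <- setdiff(set, c("S_X", "S_X_AGE", "S_X_AGE_I"))
    if (ing %in% c("LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC"))
      set <- setdiff(set, c("LIPO_SIGMA", "LIPO_SIGMA_BIPHASIC"))
    set <- c(set, ing)
    ok <- tryCatch({ build_model("candidate", set); TRUE },
                   error = function(e) FALSE)
    if (ok) out[[ing]] <- set
  }
  out
}

#' Greedy generational model search ranked by BIC
#'
#' Starting from a base model, each generation fits the base plus every
#' admissible single ingredient from the pool, ranks the candidates by BIC,
#' and adopts the winner; the loop stops when the best relative BIC
#' improvement falls below `stop_rel` or the pool is exhausted.
#'
#' @param base starting model spec.
#' @param pool ingredient ids to explore.
#' @param cohort the fitting cohort.
#' @param stat a [stat_model()] applied to every candidate.
#' @param params,scales frozen population parameters/scales.
#' @param control a [saem_control()].
#' @param stop_rel stop threshold on the relative BIC improvement.
#' @param max_generations hard cap on generations.
#' @return list of per-generation results: `generation`, `candidates`
#'   (data frame of ingredient, BIC, converged), `winner` spec, `bic`, and
#'   `rel_improvement`; the final element carries the selected model.
#' @export
generation_search <- function(base, pool, cohort, stat = stat_model(),
                              params = default_params(),
                              scales = c(c_si = 3.4, c_sigma_beta = 2.4e-05),
                              control = saem_control(),
                              stop_rel = 0.025, max_generations = 6) {
  base_fit <- fit_population(cohort, base, stat, params, scales, control)
  current <- base
  current_bic <- base_fit$bic
  history <- list(list(generation = 0L,
                       candidates = data.frame(ingredient = "(base)",
                                               bic = current_bic,
                                               converged = base_fit$converged),
                       winner = current, bic = current_bic,
                       rel_improvement = NA_real_))
  for (gen in seq_len(max_generations)) {
    cands <- admissible_additions(current, pool)
    if (!length(cands)) break
    rows <- lapply(names(cands), function(ing) {
      fit <- tryCatch(
        fit_population(cohort, build_model(paste0(current$name, "+", ing),
                                           cands[[ing]]),
                       stat, params, scales, control),
        error = function(e) NULL)
      if (is.null(fit)) return(data.frame(ingredient = ing, bic = NA_real_,
                                          converged = FALSE))
      data.frame(ingredient = ing, bic = fit$bic, converged = fit$converged)
    })
    tab <- do.call(rbind, rows)
    if (all(is.na(tab$bic)))
      stop("all candidate fits failed in generation ", gen,
           "; candidates: ", paste(tab$ingredient, collapse = ", "))
    best <- which.min(tab$bic)
    rel <- (current_bic - tab$bic[best]) / abs(current_bic)
    winner_set <- cands[[tab$ingredient[best]]]
    winner <- build_model(paste0("Gen", gen), winner_set)
    history[[length(history) + 1]] <-
      list(generation = gen, candidates = tab, winner = winner,
           bic = tab$bic[best], rel_improvement = rel)
    if (!is.na(rel) && rel < stop_rel) break
    current <- winner
    current_bic <- tab$bic[best]
  }
  history
}

#' Seeded k-fold split of a cohort
#'
#' Partitions the subjects into `k` folds whose sizes differ by at most one.
#'
#' @param cohort a `dmprog_cohort` (or any list of subjects).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold assignments (1..k), one per subject.
#' @export
kfold_split <- function(cohort, k = 3, seed = 1) {
  n <- length(cohort)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  set.seed(seed)
  folds <- rep(seq_len(k), length.out = n)
  sample(folds)
}

#' BIC of a test cohort under fixed population parameters
#'
#' Applies the population distribution from a training fit to held-out
#' subjects, estimating only the random effects: the test log-likelihood is
#' the marginal likelihood at the fixed population parameters (importance
#' sampling around the test subjects' empirical-Bayes modes), and the BIC
#' penalty counts zero estimated population parameters, since neither the
#' fixed effects nor the variances are re-estimated and the random effects
#' are integrated out rather than counted.
#'
#' @param train_fit a `dmprog_fit` from the training folds.
#' @param test_cohort held-out subjects.
#' @param n_mc importance draws per subject.
#' @param seed RNG seed.
#' @return list with `bic`, `logL`, `se`, and `k = 0`.
#' @export
bic_by_testing <- function(train_fit, test_cohort, n_mc = 1000, seed = 1) {
  if (!length(test_cohort)) stop("empty test cohort")
  lik <- log_likelihood(train_fit, test_cohort, n_mc = n_mc, seed = seed)
  list(bic = bic(lik$logL, 0, length(test_cohort)),
       logL = lik$logL, se = lik$se, k = 0)
}

#' Three-fold cross-validation of a population model
#'
#' For each fold: fit the complementary training subjects, then compute the
#' BIC on the held-out fold both by re-fitting (`bic_by_fitting`) and by
#' fixing the training population parameters and estimating only random
#' effects (`bic_by_testing`); the two are averaged across folds.
#'
#' @param cohort the cohort.
#' @param spec structural model.
#' @param stat,params,scales,control as in [fit_population()].
#' @param k number of folds.
#' @param seed split seed.
#' @return list with per-fold results and the averaged criteria.
#' @export
crossvalidate_population <- function(cohort, spec, stat = stat_model(),
                                     params = default_params(),
                                     scales = c(c_si = 3.4, c_sigma_beta = 2.4e-05),
                                     control = saem_control(), k = 3, seed = 1) {
  folds <- kfold_split(cohort, k, seed)
  per <- lapply(seq_len(k), function(f) {
    train <- cohort[folds != f]
    test <- cohort[folds == f]
    class(train) <- class(test) <- "dmprog_cohort"
    tf <- fit_population(train, spec, stat, params, scales, control)
    bt <- bic_by_testing(tf, test, n_mc = control$n_mc, seed = seed + f)
    ff <- fit_population(test, spec, stat, params, scales, control)
    list(fold = f, bic_by_testing = bt$bic, bic_by_fitting = ff$bic)
  })
  list(folds = folds, per_fold = per,
       mean_bic_by_testing = mean(vapply(per, `[[`, numeric(1), "bic_by_testing")),
       mean_bic_by_fitting = mean(vapply(per, `[[`, numeric(1), "bic_by_fitting")))
}

# --- extended FAST sensitivity analysis -------------------------------------

#' Extended FAST variance-based sensitivity indices
#'
#' Implements the extended Fourier Amplitude Sensitivity Test: each
#' parameter in turn is assigned the high driving frequency
#' `floor((n - 1) / (2 M))` while the complementary parameters share low
#' frequencies at most `max(1, floor(high / (2 M)))`; parameters move along
#' the search curve `x_j(s) = 0.5 + asin(sin(w_j s + phase_j)) / pi`,
#' rescaled to their ranges.  First-order indices come from the spectral
#' power at the first `M` harmonics of the high frequency, total-order
#' indices from one minus the low-frequency (complementary) power, averaged
#' over `n_resample` random-phase curves.
#'
#' @param fn vectorised model: takes a matrix (rows = evaluations, columns =
#'   parameters) and returns a numeric vector of outputs.
#' @param ranges named list of length-2 ranges, one per parameter.
#' @param n samples per search curve; must exceed the Nyquist bound
#'   `4 M^2 + 1`.
#' @param M interference factor (harmonics kept per frequency).
#' @param n_resample random-phase resampling curves.
#' @param seed RNG seed for the phases.
#' @return data frame with `parameter`, `first_order`, `total_order`.
#' @export
efast <- function(fn, ranges, n = 1025, M = 4, n_resample = 2, seed = 1) {
  kpar <- length(ranges)
  if (kpar < 2) stop("need at least 2 parameters with finite ranges")
  if (n <= 4 * M^2)
    stop("sample size n = ", n, " is below the Nyquist bound; need n > ",
         4 * M^2, " for M = ", M)
  set.seed(seed)
  nm <- names(ranges)
  nh <- floor((n - 1) / 2)
  w_hi <- floor((n - 1) / (2 * M))
  w_lo_max <- max(1, floor(w_hi / (4 * M)))   # complement harmonics stay well below the w_hi/2 cutoff
  # back the driving frequency off the Nyquist edge so modulation sidebands
  # of its M-th harmonic do not fold back onto the counted bins
  w_hi <- floor((nh - M * w_lo_max) / M)
  s <- pi * (2 * seq_len(n) - n - 1) / n
  S1 <- St <- matrix(0, kpar, n_resample)
  for (ii in seq_len(kpar)) {
    w <- numeric(kpar)
    w[ii] <- w_hi
    # spread complementary frequencies over [1, w_lo_max] so the search curve
    # covers the complementary subspace instead of locking onto a short
    # closed path
    if (kpar - 1 <= w_lo_max) {
      wc <- round(seq(1, w_lo_max, length.out = kpar - 1))
    } else {
      wc <- rep(seq_len(w_lo_max), length.out = kpar - 1)
    }
    # odd complement frequencies cannot place a harmonic exactly on a
    # multiple of the (even-rich) driving frequency
    wc <- wc + (wc %% 2 == 0)
    w[-ii] <- wc
    for (rr in seq_len(n_resample)) {
      phase <- stats::runif(kpar, 0, 2 * pi)
      X <- vapply(seq_len(kpar), function(j) {
        g <- 0.5 + asin(sin(w[j] * s + phase[j])) / pi
        ranges[[j]][1] + g * (ranges[[j]][2] - ranges[[j]][1])
      }, numeric(n))
      colnames(X) <- nm
      y <- fn(X)
      if (length(y) != n || any(!is.finite(y)))
        stop("model output must be a finite vector of length n")
      y <- y - mean(y)
      nh <- floor((n - 1) / 2)
      ft <- stats::fft(y)[2:(nh + 1)]
      Z <- (Mod(ft) / n)^2          # one-sided spectral power per harmonic
      V <- 2 * sum(Z)
      Vi <- 2 * sum(Z[seq_len(M) * w_hi])
      Vc <- 2 * sum(Z[seq_len(floor(w_hi / 2))])
      S1[ii, rr] <- Vi / V
      St[ii, rr] <- 1 - Vc / V
    }
  }
  data.frame(parameter = nm,
             first_order = rowMeans(S1),
             total_order = rowMeans(St))
}

#' eFAST screen of a progression model
#'
#' Runs [efast()] on summary functionals of the model trajectory (endpoint
#' glucose, time-averaged insulin, endpoint beta-cell function) over given
#' parameter ranges, as a screen of which parameters influence the
#' observables enough to be estimated.
#'
#' @param spec model spec.
#' @param params baseline parameters; swept parameters are overridden.
#' @param ranges named list of length-2 ranges over swept parameters.
#' @param output one of `"G_end"`, `"I_mean"`, `"sigma_beta_end"`.
#' @param horizon simulation horizon (days).
#' @param pfat frozen percent body fat of the screen.
#' @param n,M,n_resample,seed passed to [efast()].
#' @return data frame of indices per swept parameter.
#' @export
efast_sensitivity <- function(spec, params = default_params(), ranges,
                              output = c("G_end", "I_mean", "sigma_beta_end"),
                              horizon = 3000, pfat = 36,
                              n = 257, M = 4, n_resample = 2, seed = 1) {
  output <- match.arg(output)
  cov <- covariate_track(25, 0, pfat)
  fn <- function(X) {
    apply(X, 1, function(row) {
      p <- params
      for (k in colnames(X)) p[[k]] <- row[[k]]
      tr <- tryCatch(
        integrate_model(spec, p, cov, times = seq(0, horizon, length.out = 61),
                        rtol = 1e-6, atol = 1e-6),
        error = function(e) NULL)
      if (is.null(tr)) return(NA_real_)
      switch(output,
             G_end = tr$G[nrow(tr)],
             I_mean = mean(tr$I),
             sigma_beta_end = tr$sigma_beta[nrow(tr)])
    })
  }
  fn_safe <- function(X) {
    y <- fn(X)
    if (anyNA(y)) y[is.na(y)] <- stats::median(y, na.rm = TRUE)
    y
  }
  efast(fn_safe, ranges, n = n, M = M, n_resample = n_resample, seed = seed)
}
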