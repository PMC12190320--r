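#' Trapezoidal area under a curve
#'
#' @param times sampling times (strictly increasing, at least two).
#' @param values sampled values.
#' @return the exact trapezoid sum, in value times time units.
#' @examples
#' auc_trapezoid(c(0, 120), c(100, 100))  # 12000
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) < 2) stop("need at least two points")
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Matsuda whole-body insulin-sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * Gbar * Ibar)` with fasting glucose `G0` (mg/dl),
#' fasting insulin `I0` (uU/ml) and the OGTT means `Gbar`, `Ibar` computed as
#' AUC over 120 min by the trapezoidal rule.
#'
#' @param G0,I0 fasting glucose and insulin.
#' @param Gbar,Ibar mean OGTT glucose and insulin.
#' @return the dimensionless index.
#' @examples
#' matsuda_index(100, 1, 100, 1)  # 100
#' @export
matsuda_index <- function(G0, I0, Gbar, Ibar) {
  v <- c(G0, I0, Gbar, Ibar)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all inputs must be positive")
  10000 / sqrt(G0 * I0 * Gbar * Ibar)
}

#' Insulinogenic AUC-ratio index from an OGTT curve
#'
#' The ratio of the insulin to the glucose area under the curve over the
#' three-hour OGTT, a beta-cell function proxy.
#'
#' @param curve an OGTT curve from [ogtt_curve()].
#' @return AUC(insulin) / AUC(glucose).
#' @export
insulinogenic_ratio <- function(curve) {
  ag <- auc_trapezoid(curve$times, curve$glucose)
  if (ag == 0) stop("glucose AUC is zero")
  auc_trapezoid(curve$times, curve$insulin) / ag
}

#' OGTT curve container
#'
#' @param times minutes from glucose load, starting at 0, increasing.
#' @param glucose,insulin sampled concentrations (mg/dl, uU/ml).
#' @return an object of class `dmprog_ogtt`.
#' @export
ogtt_curve <- function(times, glucose, insulin) {
  stopifnot(times[1] == 0, all(diff(times) > 0),
            length(glucose) == length(times), length(insulin) == length(times))
  structure(list(times = times, glucose = glucose, insulin = insulin),
            class = "dmprog_ogtt")
}

#' Matsuda index computed from an OGTT curve
#'
#' Fasting values are the curve values at time zero; the OGTT means use the
#' 0-120 min window, per the index definition.
#'
#' @param curve an OGTT curve covering at least 120 min.
#' @return the Matsuda index.
#' @export
matsuda_from_curve <- function(curve) {
  keep <- curve$times <= 120
  if (max(curve$times[keep]) < 120) stop("curve must cover 120 min")
  tg <- curve$times[keep]
  matsuda_index(curve$glucose[1], curve$insulin[1],
                auc_trapezoid(tg, curve$glucose[keep]) / 120,
                auc_trapezoid(tg, curve$insulin[keep]) / 120)
}

#' Construct an OGTT curve matching prescribed index values
#'
#' Builds smooth three-hour excursion curves (a fixed peaked shape scaled
#' above the fasting values) whose Matsuda index and insulinogenic AUC ratio
#' equal the given targets.  The construction solves for the glucose and
#' insulin excursion amplitudes; it is used by the synthetic-cohort generator
#' to emit OGTT curves consistent with each visit's fasting state and
#' indices, and it exercises the index formulas in round-trip tests.
#'
#' @param G0,I0 fasting glucose (mg/dl) and insulin (uU/ml).
#' @param matsuda,igi target index values.
#' @param times sampling grid in minutes (must include 0 and reach 180).
#' @return a `dmprog_ogtt`; errors if no non-negative excursion pair can
#'   reach the targets.
#' @export
ogtt_from_indices <- function(G0, I0, matsuda, igi,
                              times = c(0, 30, 60, 90, 120, 150, 180)) {
  stopifnot(G0 > 0, I0 > 0, matsuda > 0, igi > 0, times[1] == 0, max(times) >= 180)
  # excursion shape: zero at t = 0, peak near 45-60 min, partial return
  shape <- function(t) (t / 45) * exp(1 - t / 45)
  s <- shape(times)
  m120 <- times <= 120
  sbar120 <- auc_trapezoid(times[m120], s[m120]) / 120
  sbar180 <- auc_trapezoid(times, s) / max(times)
  # targets: Gbar*Ibar fixed by Matsuda; AUC ratio fixed by igi
  P <- (10000 / matsuda)^2 / (G0 * I0)       # required Gbar120 * Ibar120
  # unknowns a, b >= 0: G(t) = G0 (1 + a s), I(t) = I0 (1 + b s)
  # igi: I0 (1 + b sbar180) = igi * G0 (1 + a sbar180)
  # matsuda: G0 (1 + a sbar120) * I0 (1 + b sbar120) = P
  f <- function(a) {
    b <- (igi * G0 * (1 + a * sbar180) / I0 - 1) / sbar180
    G0 * I0 * (1 + a * sbar120) * (1 + b * sbar120) - P
  }
  lo <- max(0, (I0 / (igi * G0) - 1) / sbar180)  # keeps b >= 0
  if (f(lo) > 0)
    stop("targets unreachable: fasting state already exceeds the index product")
  hi <- lo + 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) stop("targets unreachable with non-negative excursions")
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  b <- (igi * G0 * (1 + a * sbar180) / I0 - 1) / sbar180
  ogtt_curve(times, G0 * (1 + a * s), I0 * (1 + b * s))
}

#' Map a model trajectory to the four fitted observables
#'
#' Fasting glucose and insulin are the model states; the Matsuda index and
#' the insulinogenic AUC ratio are proportional to model insulin sensitivity
#' and to beta-cell function (`sigma * beta`) through positive scale factors
#' that are estimated when fitting.
#'
#' @param traj a trajectory from [integrate_model()].
#' @param visit_times visit times (days) within the trajectory span.
#' @param scales named list/vector with `c_si` and `c_sigma_beta`.
#' @return data frame with `t_days`, `fpg`, `fpi`, `matsuda`, `igi`.
#' @export
model_to_observables <- function(traj, visit_times,
                                 scales = c(c_si = 1, c_sigma_beta = 1)) {
  if (any(visit_times < min(traj$t_days) | visit_times > max(traj$t_days)))
    stop("visit times outside the trajectory span")
  if (any(scales <= 0)) stop("scale factors must be positive")
  at <- function(col) stats::approx(traj$t_days, traj[[col]], xout = visit_times)$y
  data.frame(t_days = visit_times,
             fpg = at("G"), fpi = at("I"),
             matsuda = scales[["c_si"]] * at("SI"),
             igi = scales[["c_sigma_beta"]] * at("sigma_beta"))
}
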