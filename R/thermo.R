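# Thermodynamics of loop-mediated repression: the repression-level algebra
# of lac reporter assays, the helical-phasing partition-function model of
# RL versus spacing, and nonlinear least-squares fitting.
#
# The model treats looping as delivering an extra local concentration
# J_loop of repressor at the proximal operator, so that
#   RL(sp) = RL_noloop + (RL_noloop - 1) * (K_NSL + K_max exp(-DG_tw(sp)))
# is exactly consistent with the J-factor transform
#   J_loop = (RL - RL_noloop) [lacI] / (RL_noloop - 1),
# i.e. J_loop(sp) = [lacI] (K_NSL + K_max exp(-DG_tw(sp))).  The twist
# penalty DG_tw is the harmonic torsional cost of rotating the operator
# out of register, periodic in the helical repeat.

#' Repression level from Miller units
#'
#' Ratio of reporter activity without the loop-anchoring repressor to the
#' activity of the looping construct with repressor.
#'
#' @param mu_noloop Miller units of the single-operator construct without
#'   repressor.
#' @param mu_loop Miller units of the two-operator construct with
#'   repressor.
#' @return repression level RL (dimensionless, vectorized).
#' @export
repression_level <- function(mu_noloop, mu_loop) {
  if (any(mu_noloop <= 0) || any(mu_loop <= 0))
    stop("Miller units must be positive", call. = FALSE)
  mu_noloop / mu_loop
}

#' Normalized repression level
#'
#' RL with the specific (site-bound) architectural protein divided by RL
#' with the nonspecific control protein; 1 means no specific effect.
#'
#' @param rl_sp,rl_ns repression levels under the specific and nonspecific
#'   TALE condition.
#' @return RLn (vectorized).
#' @export
normalized_rl <- function(rl_sp, rl_ns) {
  if (any(rl_ns <= 0)) stop("RL must be positive", call. = FALSE)
  rl_sp / rl_ns
}

#' Looping J-factor from repression levels
#'
#' `J = (RL_loop - RL_noloop) [lacI] / (RL_noloop - 1)`, the effective
#' molar concentration of operator delivered by the loop.  Negative values
#' indicate anti-cooperative looping.  [rl_from_jloop()] is the exact
#' inverse.
#'
#' @param rl_loop repression level of the looping construct.
#' @param rl_noloop repression level of the single-operator construct;
#'   must exceed 1 for a functional repressor.
#' @param laci_nm cellular repressor concentration in nM (default 100).
#' @return J in nM (vectorized).
#' @export
jloop_from_rl <- function(rl_loop, rl_noloop, laci_nm = 100) {
  if (any(rl_noloop <= 1))
    stop("transform undefined for RL_noloop <= 1", call. = FALSE)
  (rl_loop - rl_noloop) * laci_nm / (rl_noloop - 1)
}

#' @rdname jloop_from_rl
#' @param j looping J-factor in nM.
#' @export
rl_from_jloop <- function(j, rl_noloop, laci_nm = 100) {
  if (any(rl_noloop <= 1))
    stop("transform undefined for RL_noloop <= 1", call. = FALSE)
  rl_noloop + j * (rl_noloop - 1) / laci_nm
}

#' Harmonic torsional penalty of an out-of-register loop
#'
#' The spacing offset is folded to the nearest helical register,
#' `d = sp - sp_optimal - hr * round((sp - sp_optimal)/hr)`, and charged
#' the harmonic twist energy of a rod of the loop's contour length:
#' `DG = C/(2 L) * (2 pi d / hr)^2 / kBT`, zero at every register and
#' periodic in `hr`.
#'
#' @param sp actual spacing (bp, vectorized).
#' @param hr helical repeat (bp/turn).
#' @param sp_optimal spacing of perfect register (bp).
#' @param c_app apparent torsional modulus in units of 1e-19 erg cm.
#' @param contour_bp loop contour length (bp) over which the twist strain
#'   is distributed.
#' @param kBT_erg Boltzmann energy in erg.
#' @return penalty in kBT (vectorized).
#' @export
twist_penalty <- function(sp, hr, sp_optimal, c_app, contour_bp,
                          kBT_erg = 4.1e-14) {
  stopifnot(hr > 0, all(contour_bp > 0))
  d <- sp - sp_optimal - hr * round((sp - sp_optimal) / hr)
  L_cm <- contour_bp * 3.4e-8
  (c_app * 1e-19) / (2 * L_cm) * (2 * pi * d / hr)^2 / kBT_erg
}

#' Predicted repression level versus spacing
#'
#' Series 1 (variable operator-operator spacing, five parameters):
#' `RL(sp) = RLn + (RLn - 1)(K_NSL + K_max exp(-DG_tw(sp)))` with the
#' twist strain distributed over the loop itself (`contour = sp`).
#' Series 2 (variable TALE site inside a fixed loop, three parameters):
#' same form with `K_NSL` absent, `hr` fixed, and the strain distributed
#' over the full fixed loop (`contour = loop_bp`, default 142.5).
#'
#' @param sp spacing in bp (operator-operator for series 1, TALE-operator
#'   for series 2; vectorized).
#' @param params named list or vector: series 1 needs `hr, c_app, k_max,
#'   k_nsl, sp_optimal`; series 2 needs `c_app, k_smax, sp_optimal`.
#' @param rl_noloop measured repression of the no-loop construct.
#' @param series 1 or 2.
#' @param hr helical repeat, required for series 2 (held fixed there).
#' @param loop_bp fixed loop size for series 2.
#' @return predicted RL (vectorized).
#' @export
rl_model <- function(sp, params, rl_noloop = 5, series = 1, hr = NULL,
                     loop_bp = 142.5) {
  p <- as.list(params)
  if (series == 1) {
    dg <- twist_penalty(sp, p$hr, p$sp_optimal, p$c_app, contour_bp = sp)
    rl_noloop + (rl_noloop - 1) * (p$k_nsl + p$k_max * exp(-dg))
  } else {
    stopifnot(!is.null(hr))
    dg <- twist_penalty(sp, hr, p$sp_optimal, p$c_app,
                        contour_bp = loop_bp)
    rl_noloop + (rl_noloop - 1) * p$k_smax * exp(-dg)
  }
}

# fold a fitted optimum into the canonical window (max(sp) - hr, max(sp)]
fold_sp_optimal <- function(sp_opt, hr, sp_max) {
  sp_opt - hr * ceiling((sp_opt - sp_max) / hr)
}

#' Fit the five-parameter spacing model (series 1)
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds) of the
#' series-1 RL model, multi-started over a grid of helical repeats and
#' register offsets; the best-deviance solution is kept.  Equilibrium
#' constants are bounded below by zero, so boundary fits are reported as 0
#' with a one-sided confidence interval.
#'
#' @param data a repression dataset: data frame with columns `spacing` and
#'   `RL` (e.g. from [generate_rl_dataset()] or [read_rl_table()]).
#' @param rl_noloop repression of the no-loop construct (fixed input, not
#'   a fit parameter); defaults to the dataset attribute.
#' @param weights optional per-point weights (e.g. `1/sd^2`); default
#'   unweighted.
#' @param hr_grid,n_offsets multi-start grid: helical repeats crossed with
#'   equally spaced register offsets across one period.
#' @param conf_level confidence level for the parameter intervals.
#' @return Object of class `loop_fit`: coefficients, `conf_level`
#'   intervals from the linearized covariance (t quantiles), the `nls`
#'   object, and fit diagnostics.
#' @export
fit_series1 <- function(data, rl_noloop = NULL, weights = NULL,
                        hr_grid = c(10, 10.5, 11, 11.5), n_offsets = 4,
                        conf_level = 0.95) {
  d <- validate_rl_data(data, min_points = 8)
  if (is.null(rl_noloop)) rl_noloop <- attr(data, "rl_noloop")
  if (is.null(rl_noloop)) stop("rl_noloop must be supplied", call. = FALSE)
  sp_max <- max(d$spacing)
  k0 <- max((max(d$RL) - rl_noloop) / (rl_noloop - 1), 0.5)
  best <- NULL
  for (hr0 in hr_grid) {
    for (off in seq(0, hr0 * (1 - 1 / n_offsets), length.out = n_offsets)) {
      start <- list(hr = hr0, c_app = 0.5, k_max = k0, k_nsl = 0.1 * k0,
                    sp_optimal = sp_max - off)
      fit <- try_nls(RL ~ rl_noloop + (rl_noloop - 1) *
                       (k_nsl + k_max *
                          exp(-twist_penalty(spacing, hr, sp_optimal,
                                             c_app, spacing))),
                     d, start, weights,
                     lower = c(9, 1e-4, 0, 0, sp_max - 2 * max(hr_grid)),
                     upper = c(13, 50, 1e4, 1e4, sp_max + max(hr_grid)),
                     extra = list(rl_noloop = rl_noloop))
      if (!is.null(fit) && (is.null(best) ||
                            stats::deviance(fit) < stats::deviance(best)))
        best <- fit
    }
  }
  if (is.null(best))
    stop("series-1 fit failed to converge from every start", call. = FALSE)
  make_loop_fit(best, d, series = 1, rl_noloop = rl_noloop,
                conf_level = conf_level, sp_max = sp_max)
}

#' Fit the three-parameter fixed-loop model (series 2)
#'
#' As [fit_series1()] but for the series-2 geometry: the loop size is
#' fixed, the helical repeat is inherited from a series-1 fit, and the
#' adjustable parameters are the apparent torsional modulus, the
#' stabilized-loop equilibrium constant and the optimal protein-operator
#' spacing.
#'
#' @inheritParams fit_series1
#' @param hr helical repeat (bp/turn), fixed (from a series-1 fit).
#' @param loop_bp fixed loop contour (bp) carrying the twist strain.
#' @return Object of class `loop_fit`.
#' @export
fit_series2 <- function(data, hr, rl_noloop = NULL, loop_bp = 142.5,
                        weights = NULL, n_offsets = 6, conf_level = 0.95) {
  d <- validate_rl_data(data, min_points = 6)
  if (is.null(rl_noloop)) rl_noloop <- attr(data, "rl_noloop")
  if (is.null(rl_noloop)) stop("rl_noloop must be supplied", call. = FALSE)
  sp_max <- max(d$spacing)
  k0 <- max((max(d$RL) - rl_noloop) / (rl_noloop - 1), 0.5)
  best <- NULL
  for (off in seq(0, hr * (1 - 1 / n_offsets), length.out = n_offsets)) {
    start <- list(c_app = 0.3, k_smax = k0, sp_optimal = sp_max - off)
    fit <- try_nls(RL ~ rl_noloop + (rl_noloop - 1) * k_smax *
                     exp(-twist_penalty(spacing, hr, sp_optimal, c_app,
                                        loop_bp)),
                   d, start, weights,
                   lower = c(1e-4, 0, sp_max - 2 * hr),
                   upper = c(50, 1e4, sp_max + hr),
                   extra = list(rl_noloop = rl_noloop, hr = hr,
                                loop_bp = loop_bp))
    if (!is.null(fit) && (is.null(best) ||
                          stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best))
    stop("series-2 fit failed to converge from every start", call. = FALSE)
  make_loop_fit(best, d, series = 2, rl_noloop = rl_noloop,
                conf_level = conf_level, sp_max = sp_max, hr_fixed = hr)
}

try_nls <- function(formula, data, start, weights, lower, upper, extra) {
  env <- list2env(extra, parent = environment(formula))
  environment(formula) <- env
  args <- list(formula = formula, data = data, start = start,
               lower = lower, upper = upper,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  out <- try(suppressWarnings(do.call(minpack.lm::nlsLM, args)),
             silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

make_loop_fit <- function(fit, data, series, rl_noloop, conf_level,
                          sp_max, hr_fixed = NULL) {
  est <- coef(fit)
  hr_use <- if (series == 1) est[["hr"]] else hr_fixed
  est[["sp_optimal"]] <- fold_sp_optimal(est[["sp_optimal"]], hr_use, sp_max)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, length(est)))
  dfree <- nrow(data) - length(est)
  tq <- qt(1 - (1 - conf_level) / 2, dfree)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  # one-sided at a zero boundary
  at_zero <- est < 1e-8 & names(est) %in% c("k_nsl", "k_max", "k_smax")
  ci[at_zero, "lower"] <- 0
  structure(list(coefficients = est, se = se, ci = ci,
                 conf_level = conf_level, series = series,
                 rl_noloop = rl_noloop, hr_fixed = hr_fixed,
                 fit = fit, data = data,
                 deviance = stats::deviance(fit),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "loop_fit")
}

#' @export
print.loop_fit <- function(x, ...) {
  cat(sprintf("Thermodynamic loop model fit (series %d, %d points)\n",
              x$series, nrow(x$data)))
  tq <- (x$ci[, "upper"] - x$coefficients)
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    ci = sprintf("+/- %.4g", tq))
  print(tab)
  cat(sprintf("residual sum of squares: %.4g\n", x$deviance))
  invisible(x)
}

#' @export
coef.loop_fit <- function(object, ...) object$coefficients

#' Model-implied looping J-factor of a fit
#'
#' @param fit a `loop_fit`.
#' @param sp spacings at which to evaluate (default: the fitted data's).
#' @param laci_nm repressor concentration in nM.
#' @return J in nM; exactly `jloop_from_rl()` of the model prediction.
#' @export
jloop_model <- function(fit, sp = NULL, laci_nm = 100) {
  stopifnot(inherits(fit, "loop_fit"))
  if (is.null(sp)) sp <- fit$data$spacing
  p <- as.list(fit$coefficients)
  rl <- if (fit$series == 1) {
    rl_model(sp, p, fit$rl_noloop, series = 1)
  } else {
    names(p)[names(p) == "k_smax"] <- "k_smax"
    rl_model(sp, p, fit$rl_noloop, series = 2, hr = fit$hr_fixed)
  }
  jloop_from_rl(rl, fit$rl_noloop, laci_nm)
}

validate_rl_data <- function(data, min_points = 3) {
  d <- as.data.frame(data)
  if (!all(c("spacing", "RL") %in% names(d)))
    stop("data needs columns 'spacing' and 'RL'", call. = FALSE)
  if (anyDuplicated(d$spacing))
    stop("duplicate spacings in dataset", call. = FALSE)
  if (any(d$RL <= 0)) stop("RL must be positive", call. = FALSE)
  if (nrow(d) < min_points)
    stop(sprintf("need at least %d spacings", min_points), call. = FALSE)
  d
}

#' Reference thermodynamic parameter sets
#'
#' Representative fitted parameter values for lac repression loops in
#' E. coli carrying the four designed architectural-protein conditions
#' (specific / nonspecific TALE, with or without the Nhp6A bending
#' domain), at 100 uM IPTG.  These are the generator defaults of
#' [generate_rl_dataset()].
#'
#' @param condition one of `"sp_tale"`, `"sp_tale_nhp6a"`, `"ns_tale"`,
#'   `"ns_tale_nhp6a"`.
#' @return named list of series-1 (`series1_params`) or series-2
#'   (`series2_params`) parameters.
#' @export
series1_params <- function(condition = c("ns_tale", "sp_tale",
                                         "sp_tale_nhp6a", "ns_tale_nhp6a")) {
  condition <- match.arg(condition)
  switch(condition,
    sp_tale = list(hr = 10.96, c_app = 2.86, k_max = 9.82, k_nsl = 4.83,
                   sp_optimal = 142.65),
    sp_tale_nhp6a = list(hr = 10.98, c_app = 2.11, k_max = 55.24,
                         k_nsl = 11.48, sp_optimal = 142.82),
    ns_tale = list(hr = 11.07, c_app = 0.44, k_max = 33.56, k_nsl = 0,
                   sp_optimal = 144.03),
    ns_tale_nhp6a = list(hr = 11.13, c_app = 0.31, k_max = 29.88,
                         k_nsl = 0, sp_optimal = 143.14))
}

#' @rdname series1_params
#' @export
series2_params <- function(condition = c("ns_tale", "sp_tale",
                                         "sp_tale_nhp6a", "ns_tale_nhp6a")) {
  condition <- match.arg(condition)
  switch(condition,
    sp_tale = list(c_app = 0.34, k_smax = 15.62, sp_optimal = 97.89),
    sp_tale_nhp6a = list(c_app = 0.36, k_smax = 49.66, sp_optimal = 94.79),
    ns_tale = list(c_app = 0.25, k_smax = 42.03, sp_optimal = 92.95),
    ns_tale_nhp6a = list(c_app = 0.24, k_smax = 38.61, sp_optimal = 93.18))
}
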