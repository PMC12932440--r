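#' Specification of a least-squares calibration problem
#'
#' Defines which parameters are free, their box constraints, the
#' normalized BMD series to fit, and the optimizer budget. Two
#' protocols are supported, mirroring the study design: the
#' natural-menopause refit frees the two estrogen thresholds
#' `{e_PC, e_Sc}`; the surgical fit freezes those and frees the three
#' surgery-effect parameters `{eta_surg, tau, omega_surg}` with bounds
#' `[0, 5] x [0, tau_upper] x [0, 5]` (lower bounds mean "no effect /
#' permanent effect / no effect"). The default `tau_upper = 1` day^-1
#' caps the duration of the surgical transient at a minimum of one day;
#' pass `tau_upper = 1/365` for the stricter year-scale cap.
#'
#' @param free_parameters Character vector: a subset of
#'   `c("e_PC", "e_Sc")` or of `c("eta_surg", "tau", "omega_surg")`.
#' @param data A `bmd_series` (see [normalize_study()] /
#'   [aggregate_bmd()]): normalized BMD vs years since onset.
#' @param lower,upper Named bounds per free parameter; defaults as
#'   above (thresholds get `[1e-6, 1e3]`).
#' @param horizon_years Only observations with
#'   `0 <= t <= horizon_years` enter the objective (default 15; use 30
#'   for long-term fits).
#' @param max_evaluations Cap on residual-function evaluations
#'   (default 10000).
#' @param tolerance Optimizer convergence tolerance (default 1e-8).
#' @param tau_upper Upper bound used for `tau` when no explicit `upper`
#'   is given.
#' @return An object of class `fit_specification`.
#' @export
fit_specification <- function(free_parameters, data,
                              lower = NULL, upper = NULL,
                              horizon_years = 15,
                              max_evaluations = 10000,
                              tolerance = 1e-8,
                              tau_upper = 1) {
  natural_set <- c("e_PC", "e_Sc")
  surgical_set <- c("eta_surg", "tau", "omega_surg")
  if (all(free_parameters %in% natural_set)) {
    protocol <- "natural"
  } else if (all(free_parameters %in% surgical_set)) {
    protocol <- "surgical"
  } else {
    stop("`free_parameters` must be a subset of {e_PC, e_Sc} or of ",
         "{eta_surg, tau, omega_surg}", call. = FALSE)
  }
  if (anyDuplicated(free_parameters))
    stop("duplicated free parameter", call. = FALSE)
  defaults_lower <- c(e_PC = 1e-6, e_Sc = 1e-6,
                      eta_surg = 0, tau = 0, omega_surg = 0)
  defaults_upper <- c(e_PC = 1e3, e_Sc = 1e3,
                      eta_surg = 5, tau = tau_upper, omega_surg = 5)
  lo <- defaults_lower[free_parameters]
  hi <- defaults_upper[free_parameters]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo >= hi)) stop("bounds must satisfy lower < upper",
                          call. = FALSE)
  if (horizon_years <= 0) stop("`horizon_years` must be > 0",
                               call. = FALSE)
  stopifnot(inherits(data, "bmd_series"))
  spec <- list(free_parameters = free_parameters, protocol = protocol,
               lower = lo, upper = hi, data = data,
               horizon_years = horizon_years,
               max_evaluations = max_evaluations, tolerance = tolerance)
  class(spec) <- c("fit_specification", "list")
  spec
}

apply_trial <- function(q, spec, p, s) {
  q <- stats::setNames(as.numeric(q), spec$free_parameters)
  if (spec$protocol == "natural") {
    for (nm in names(q)) p[[nm]] <- q[[nm]]
    validate_natural_parameters(p)
  } else {
    if (is.null(s)) s <- surgical_parameters()
    for (nm in names(q)) s[[nm]] <- q[[nm]]
    validate_surgical_parameters(s)
  }
  list(p = p, s = s)
}

#' Residuals of the model against a normalized BMD series
#'
#' For each observation time within the fitting horizon, returns the
#' model's onset-normalized BMD (with the premenopausal equilibrium
#' recomputed for the trial parameters) minus the observed normalized
#' BMD. Residuals are unweighted. If the integration fails at a trial
#' point, a large constant penalty residual is returned with a warning,
#' which keeps the optimizer away from the infeasible region without
#' aborting the fit.
#'
#' @param q Numeric vector of trial values for
#'   `spec$free_parameters` (within bounds).
#' @param spec A [fit_specification()].
#' @param p,s,e Baseline model objects; free parameters in `q` override
#'   the corresponding entries of `p` (natural protocol) or `s`
#'   (surgical protocol). The estrogen model is rebuilt from the trial
#'   parameters when `e` is `NULL`.
#' @param cfg Simulation settings; the default integrates to the
#'   fitting horizon.
#' @return Numeric vector of residuals, one per in-horizon observation.
#' @export
model_residuals <- function(q, spec, p, s = NULL, e = NULL, cfg = NULL) {
  trial <- apply_trial(q, spec, p, s)
  obs <- spec$data[spec$data$time_years >= 0 &
                     spec$data$time_years <= spec$horizon_years, ]
  if (nrow(obs) == 0L) stop("no observations within the horizon",
                            call. = FALSE)
  if (is.null(cfg))
    cfg <- simulation_config(
      t_end = trial$p$t_m + max(spec$horizon_years, max(obs$time_years)) *
        365 + 31)
  ok <- try({
    traj <- simulate_bone(trial$p, trial$s, e, cfg)
    pred <- relative_bmd_at(traj, obs$time_years)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    warning("integration failed at trial point (",
            paste(signif(q, 4), collapse = ", "),
            "); returning penalty residuals", call. = FALSE)
    return(rep(1e6, nrow(obs)))
  }
  pred - obs$mean_bmd
}

#' Fit the model to a normalized BMD series
#'
#' Bound-constrained Levenberg-Marquardt minimization of the unweighted
#' sum of squared BMD residuals. Deterministic given the starting
#' point. Default starts are the midpoint of the bounds for the
#' surgical protocol and the current parameter values for the natural
#' protocol; optionally a seeded Latin-hypercube multi-start explores
#' the box and returns the best local optimum.
#'
#' @inheritParams model_residuals
#' @param start Named or positional start values within bounds, or
#'   `NULL` for the protocol default.
#' @param multi_start If `TRUE`, run `n_starts` seeded Latin-hypercube
#'   starts and keep the best.
#' @param n_starts Number of multi-start points (default 5).
#' @param seed Integer seed for the multi-start design.
#' @return A `bone_fit` object: list with `estimates` (named vector),
#'   `objective` (sum of squared residuals), `rmse_percent`
#'   (`sqrt(objective / n) * 100`, i.e. RMSE on normalized BMD in
#'   percent), `n_points`, `converged`, `n_evaluations`, `at_bound`
#'   (logical per parameter, within 1e-8 of a bound), `start`, and the
#'   raw optimizer `message`.
#' @export
fit_bone_model <- function(spec, p, s = NULL, e = NULL, start = NULL,
                           multi_start = FALSE, n_starts = 5,
                           seed = NULL, cfg = NULL) {
  stopifnot(inherits(spec, "fit_specification"))
  k <- length(spec$free_parameters)
  if (is.null(start)) {
    start <- if (spec$protocol == "surgical") {
      (spec$lower + spec$upper) / 2
    } else {
      stats::setNames(unlist(p[spec$free_parameters]),
                      spec$free_parameters)
    }
  }
  start <- stats::setNames(as.numeric(start), spec$free_parameters)
  if (any(start < spec$lower | start > spec$upper))
    stop("`start` must lie within the bounds", call. = FALSE)

  starts <- list(start)
  if (multi_start) {
    if (!is.null(seed)) set.seed(seed)
    u <- lhs::randomLHS(n_starts, k)
    extra <- lapply(seq_len(n_starts), function(i) {
      stats::setNames(spec$lower + u[i, ] * (spec$upper - spec$lower),
                      spec$free_parameters)
    })
    starts <- c(starts, extra)
  }

  run_one <- function(st) {
    fit <- minpack.lm::nls.lm(
      par = st, lower = spec$lower, upper = spec$upper,
      fn = function(q) model_residuals(q, spec, p, s, e, cfg),
      control = minpack.lm::nls.lm.control(
        ftol = spec$tolerance, ptol = spec$tolerance,
        gtol = spec$tolerance,
        maxiter = min(1024L, spec$max_evaluations),
        maxfev = spec$max_evaluations))
    fit
  }
  fits <- lapply(starts, run_one)
  objs <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(objs)]]

  est <- stats::setNames(as.numeric(best$par), spec$free_parameters)
  n_obs <- length(best$fvec)
  obj <- stats::deviance(best)
  out <- list(
    estimates = est,
    objective = obj,
    rmse_percent = sqrt(obj / n_obs) * 100,
    n_points = n_obs,
    converged = best$info %in% 1:4,
    n_evaluations = unname(best$niter),
    at_bound = abs(est - spec$lower) <= 1e-8 |
      abs(est - spec$upper) <= 1e-8,
    start = stats::setNames(as.numeric(starts[[1L]]),
                            spec$free_parameters),
    n_starts = length(starts),
    message = best$message,
    spec = spec)
  class(out) <- c("bone_fit", "list")
  out
}

#' Convenience drivers for the two calibration protocols
#'
#' `fit_natural()` frees the estrogen thresholds `{e_PC, e_Sc}` against
#' a natural-menopause series under the hyperbolic estrogen decline;
#' `fit_surgical()` keeps the natural parameters frozen (typically at
#' their previously fitted values) and frees the three surgery-effect
#' parameters against a surgical-menopause series under the abrupt
#' estrogen collapse, over a 15- or 30-year horizon.
#'
#' @param data A `bmd_series` of normalized BMD observations.
#' @param p Natural parameters (frozen in `fit_surgical()`).
#' @param s Surgical parameters carrying the estrogen kinetics; the
#'   three effect parameters are overwritten by the fit.
#' @param horizon_years Fitting horizon (15 short-term, 30 long-term).
#' @param ... Passed to [fit_bone_model()] (`start`, `multi_start`,
#'   `seed`, ...).
#' @return A `bone_fit` object.
#' @export
fit_natural <- function(data, p = natural_parameters(),
                        horizon_years = 15, ...) {
  spec <- fit_specification(c("e_PC", "e_Sc"), data,
                            horizon_years = horizon_years)
  fit_bone_model(spec, p, s = NULL, e = NULL, ...)
}

#' @rdname fit_natural
#' @export
fit_surgical <- function(data, p = natural_parameters(),
                         s = surgical_parameters(),
                         horizon_years = 15, ...) {
  spec <- fit_specification(c("eta_surg", "tau", "omega_surg"), data,
                            horizon_years = horizon_years)
  fit_bone_model(spec, p, s = s, e = NULL, ...)
}

#' @export
print.bone_fit <- function(x, ...) {
  cat(sprintf("<bone_fit> %s protocol, %d points, horizon %g years\n",
              x$spec$protocol, x$n_points, x$spec$horizon_years))
  est <- signif(x$estimates, 5)
  for (i in seq_along(est))
    cat(sprintf("  %-11s %g%s\n", names(est)[i], est[i],
                if (x$at_bound[i]) "  [at bound]" else ""))
  cat(sprintf("  objective %.6g, RMSE %.3f%%, converged: %s\n",
              x$objective, x$rmse_percent, x$converged))
  invisible(x)
}
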