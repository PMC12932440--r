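#' Simulation configuration
#'
#' Controls the integration window, solver tolerances, and output grid
#' for [simulate_bone()]. Defaults follow the study design: integrate
#' from 30 years before menopause onset to 30 years after, with
#' absolute and relative tolerances of 1e-8 and monthly output anchored
#' at onset. `NULL` entries are resolved against `t_m` from the
#' parameter set at simulation time.
#'
#' @param t_start,t_end Integration window in days (defaults
#'   `t_m - 30 * 365` and `t_m + 30 * 365`).
#' @param abs_tol,rel_tol Solver tolerances (> 0, default 1e-8).
#' @param output_grid Strictly increasing output times in days, or
#'   `NULL` for a monthly grid anchored at `t_m`.
#' @param method A deSolve integration method; default `"ode45"`
#'   (adaptive Dormand-Prince Runge-Kutta 4(5)).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(t_start = NULL, t_end = NULL,
                              abs_tol = 1e-8, rel_tol = 1e-8,
                              output_grid = NULL, method = "ode45") {
  if (abs_tol <= 0 || rel_tol <= 0)
    stop("solver tolerances must be > 0", call. = FALSE)
  if (!is.null(output_grid) && any(diff(output_grid) <= 0))
    stop("`output_grid` must be strictly increasing", call. = FALSE)
  cfg <- list(t_start = t_start, t_end = t_end, abs_tol = abs_tol,
              rel_tol = rel_tol, output_grid = output_grid,
              method = method)
  class(cfg) <- c("simulation_config", "list")
  cfg
}

resolve_config <- function(cfg, p) {
  if (is.null(cfg$t_start)) cfg$t_start <- p$t_m - 30 * 365
  if (is.null(cfg$t_end)) cfg$t_end <- p$t_m + 30 * 365
  if (cfg$t_start >= p$t_m || cfg$t_end <= p$t_m)
    stop("`t_start < t_m < t_end` is required", call. = FALSE)
  if (is.null(cfg$output_grid)) {
    month <- 365 / 12
    pre <- rev(seq(p$t_m, cfg$t_start, by = -month))
    post <- seq(p$t_m, cfg$t_end, by = month)
    grid <- c(pre, post[-1L])
    if (grid[1L] > cfg$t_start) grid <- c(cfg$t_start, grid)
    if (grid[length(grid)] < cfg$t_end) grid <- c(grid, cfg$t_end)
    cfg$output_grid <- grid
  } else {
    g <- cfg$output_grid
    if (g[1L] < cfg$t_start || g[length(g)] > cfg$t_end)
      stop("`output_grid` must lie within [t_start, t_end]",
           call. = FALSE)
    if (!(p$t_m %in% g)) g <- sort(c(g, p$t_m))
    if (g[1L] > cfg$t_start) g <- c(cfg$t_start, g)
    if (g[length(g)] < cfg$t_end) g <- c(g, cfg$t_end)
    cfg$output_grid <- g
  }
  cfg
}

#' Simulate the bone remodeling model
#'
#' Integrates the seven-state model with an adaptive explicit
#' Runge-Kutta scheme, starting from the premenopausal equilibrium
#' (recomputed from `p` on every call, so calibration trial parameters
#' always get consistent initial conditions). The integration is split
#' into a pre-onset segment `[t_start, t_m]` and a post-onset segment
#' `[t_m, t_end]` so that the discontinuity in estrogen and in the
#' post-surgical rates falls exactly on a segment boundary; the
#' post-onset segment uses right-limit values at `t_m`.
#'
#' @param p A [natural_parameters()] object.
#' @param s A [surgical_parameters()] object or `NULL` (natural model).
#' @param e An [estrogen_model()]; defaults to the natural decline
#'   built from `p` (or the surgical decline built from `s` when `s`
#'   carries estrogen kinetics and `e` is `"auto"`).
#' @param cfg A [simulation_config()].
#' @return A `bone_trajectory`: a data frame with columns `time` (days),
#'   `years_since_onset`, the seven state columns, `bmd`
#'   (`BMC0 * Bd`), and `relative_bmd` (BMD normalized by its value at
#'   `t_m`, so exactly 1 at onset). The parameter objects and config
#'   are attached as attributes.
#' @examples
#' \donttest{
#' p <- natural_parameters()
#' traj <- simulate_bone(p, e = estrogen_model("natural", p = p))
#' traj[traj$years_since_onset == 0, "relative_bmd"]  # 1
#' }
#' @export
simulate_bone <- function(p, s = NULL, e = NULL,
                          cfg = simulation_config()) {
  validate_natural_parameters(p)
  if (!is.null(s)) validate_surgical_parameters(s)
  if (is.null(e)) {
    e <- if (is.null(s)) estrogen_model("natural", p = p)
         else estrogen_model("surgical", p = p, s = s)
  }
  cfg <- resolve_config(cfg, p)
  grid <- cfg$output_grid
  t_m <- p$t_m

  E0 <- estrogen_level(e, cfg$t_start)
  y0 <- premenopausal_steady_state(p, E = E0, cross_check = FALSE)$state

  pre_grid <- grid[grid <= t_m]
  post_grid <- grid[grid >= t_m]

  pre <- integrate_segment(y0, pre_grid, p, s, e, cfg,
                           post_branch = FALSE)
  y_tm <- unlist(pre[nrow(pre), state_names()])
  post <- integrate_segment(y_tm, post_grid, p, s, e, cfg,
                            post_branch = TRUE)
  out <- rbind(pre, post[-1L, , drop = FALSE])

  out$bmd <- p$BMC0 * out$Bd
  bmd_tm <- out$bmd[match(t_m, out$time)]
  out$relative_bmd <- out$bmd / bmd_tm
  out$years_since_onset <- (out$time - t_m) / 365
  out <- out[, c("time", "years_since_onset", state_names(), "bmd",
                 "relative_bmd")]
  rownames(out) <- NULL
  attr(out, "parameters") <- p
  attr(out, "surgical") <- s
  attr(out, "estrogen") <- e
  attr(out, "config") <- cfg
  class(out) <- c("bone_trajectory", "data.frame")
  out
}

integrate_segment <- function(y0, times, p, s, e, cfg, post_branch) {
  f <- make_derivs(p, s, e, post_branch = post_branch)
  dfun <- function(t, y, parms) list(f(t, y))
  if (length(times) < 2L) {
    out <- matrix(c(times, y0), nrow = 1L)
  } else {
    out <- deSolve::ode(y = stats::setNames(unname(y0), state_names()),
                        times = times, func = dfun, parms = NULL,
                        method = cfg$method,
                        atol = cfg$abs_tol, rtol = cfg$rel_tol)
    diagn <- attr(out, "istate")
    if (!is.null(diagn) && diagn[1L] < 0)
      stop(sprintf("integration failed near t = %g days",
                   out[nrow(out), 1L]), call. = FALSE)
  }
  df <- as.data.frame(unclass(out))
  names(df) <- c("time", state_names())
  df
}

#' Interpolate relative BMD from a trajectory
#'
#' Monotone cubic (Fritsch-Carlson) interpolation of the
#' onset-normalized BMD at arbitrary times within the simulated span;
#' used to compare the model with observations taken at irregular
#' times. Values at stored grid points are reproduced exactly, and
#' interpolated values cannot overshoot the neighboring stored values.
#'
#' @param traj A `bone_trajectory` from [simulate_bone()].
#' @param years_since_onset Time(s) in years relative to menopause
#'   onset; must lie within the simulated span.
#' @return Interpolated relative BMD value(s).
#' @export
relative_bmd_at <- function(traj, years_since_onset) {
  stopifnot(inherits(traj, "bone_trajectory"))
  rng <- range(traj$years_since_onset)
  if (any(years_since_onset < rng[1L] | years_since_onset > rng[2L]))
    stop(sprintf(
      "requested time outside the simulated span [%.2f, %.2f] years",
      rng[1L], rng[2L]), call. = FALSE)
  fun <- stats::splinefun(traj$years_since_onset, traj$relative_bmd,
                          method = "monoH.FC")
  fun(years_since_onset)
}

#' Local sensitivity envelope for the surgery-effect parameters
#'
#' Perturbs the three surgery-effect parameters by a fixed fraction
#' around their nominal values and returns the nominal trajectory
#' together with a "stronger/longer-lasting" upper perturbation
#' (`eta_surg` and `omega_surg` increased by the fraction, `tau`
#' *decreased* by it, since a smaller relaxation rate means
#' longer-lasting effects) and the opposite lower perturbation.
#'
#' @inheritParams simulate_bone
#' @param fraction Relative perturbation (default 0.25).
#' @return A list with `bone_trajectory` elements `nominal`, `upper`,
#'   `lower`, and the `fraction` used.
#' @export
sensitivity_envelope <- function(p, s, e = NULL,
                                 cfg = simulation_config(),
                                 fraction = 0.25) {
  if (is.null(s)) stop("`s` is required for the sensitivity envelope",
                       call. = FALSE)
  if (fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  perturb <- function(f) {
    surgical_parameters(kappa_E = s$kappa_E, k_syn = s$k_syn,
                        eta_surg = s$eta_surg * (1 + f),
                        omega_surg = s$omega_surg * (1 + f),
                        tau = s$tau * (1 - f))
  }
  list(nominal = simulate_bone(p, s, e, cfg),
       upper = simulate_bone(p, perturb(fraction), e, cfg),
       lower = simulate_bone(p, perturb(-fraction), e, cfg),
       fraction = fraction)
}

#' Export a trajectory as CSV
#'
#' @param traj A `bone_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "bone_trajectory"))
  df <- as.data.frame(traj)
  df <- df[, c("years_since_onset", state_names(), "bmd",
               "relative_bmd")]
  names(df)[1L] <- "time_years_since_onset"
  names(df)[ncol(df)] <- "relative_BMD"
  names(df)[ncol(df) - 1L] <- "BMD"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a simulated trajectory
#'
#' Two-panel summary: onset-normalized BMD, and the cell populations as
#' percent of their premenopausal levels.
#'
#' @param x A `bone_trajectory`.
#' @param which Panels to draw: `"bmd"`, `"cells"`, or both.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.bone_trajectory <- function(x, which = c("bmd", "cells"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if ("bmd" %in% which) {
    graphics::plot(x$years_since_onset, x$relative_bmd, type = "l",
                   xlab = "Years since menopause onset",
                   ylab = "Relative BMD", ...)
    graphics::abline(v = 0, lty = 3)
  }
  if ("cells" %in% which) {
    cells <- c("C", "B", "S", "Sc")
    ref <- as.numeric(x[1L, cells])
    pct <- 100 * sweep(as.matrix(x[, cells]), 2, ref, "/")
    graphics::matplot(x$years_since_onset, pct, type = "l", lty = 1,
                      xlab = "Years since menopause onset",
                      ylab = "% of premenopausal level", ...)
    graphics::legend("bottomleft", legend = cells, lty = 1,
                     col = seq_along(cells), bty = "n")
  }
  invisible(x)
}
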