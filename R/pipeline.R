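#' Run a named end-to-end experiment
#'
#' Drives the computational experiments of the analysis with one call:
#' \describe{
#'   \item{`natural_refit`}{Free `{e_PC, e_Sc}` against a
#'     natural-menopause series.}
#'   \item{`surgical_fit_short` / `surgical_fit_long`}{Freeze the
#'     natural parameters, free `{eta_surg, tau, omega_surg}` against a
#'     surgical series over a 15- or 30-year horizon.}
#'   \item{`no_new_effects`}{Simulate the abrupt surgical estrogen
#'     collapse with `eta_surg = omega_surg = 0`, alongside the natural
#'     decline for comparison.}
#'   \item{`alpha_sweep`}{Sweep the sclerostin production multiplier
#'     over `[0.7, 1.2]` at post-surgical estrogen and report the steady
#'     BMD change rate, including the reference points `alpha = 0.8`
#'     and `alpha = 0.94`.}
#'   \item{`sensitivity`}{±25% envelopes of the surgery-effect
#'     parameters around `s`.}
#' }
#' When `output_dir` is given, result tables are written as CSV, fit
#' results as JSON, and a `manifest.json` records parameters, seed,
#' tolerances, and package version so the run can be repeated
#' bit-identically.
#'
#' @param experiment One of the experiment names above.
#' @param p Natural parameters (default packaged values).
#' @param s Surgical parameters; defaults to the preset matching the
#'   experiment (`short_term`, `long_term`, or kinetics-only).
#' @param data A `bmd_series` for the fitting experiments; if `NULL`, a
#'   synthetic cohort generated from `synthetic_spec` is curated and
#'   used.
#' @param synthetic_spec A [synthetic_cohort_spec()] used when `data`
#'   is `NULL` (defaults to one matching the experiment's estrogen
#'   variant and truth `s`).
#' @param output_dir Directory for result files, or `NULL` to skip
#'   writing.
#' @param seed Seed recorded in the manifest and used for any synthetic
#'   generation.
#' @param cfg A [simulation_config()].
#' @param ... Passed to [fit_bone_model()] where applicable.
#' @return A result bundle (list) whose components depend on the
#'   experiment: trajectories, fit results, sweep tables, and the
#'   manifest.
#' @export
run_experiment <- function(experiment = c("natural_refit",
                                          "surgical_fit_short",
                                          "surgical_fit_long",
                                          "no_new_effects",
                                          "alpha_sweep",
                                          "sensitivity"),
                           p = natural_parameters(), s = NULL,
                           data = NULL, synthetic_spec = NULL,
                           output_dir = NULL, seed = 1L,
                           cfg = simulation_config(), ...) {
  experiment <- match.arg(experiment)
  if (is.null(s)) {
    s <- switch(experiment,
                surgical_fit_short = surgical_preset("short_term"),
                surgical_fit_long = surgical_preset("long_term"),
                sensitivity = surgical_preset("short_term"),
                surgical_parameters())
  }

  result <- switch(experiment,
    natural_refit = {
      d <- data %||% curated_synthetic(synthetic_spec, p, NULL,
                                       "natural", seed)
      fit <- fit_natural(d, p, ...)
      trial <- apply_trial(fit$estimates, fit$spec, p, NULL)
      list(fit = fit, data = d,
           trajectory = simulate_bone(trial$p, NULL, NULL, cfg))
    },
    surgical_fit_short = ,
    surgical_fit_long = {
      horizon <- if (experiment == "surgical_fit_short") 15 else 30
      d <- data %||% curated_synthetic(synthetic_spec, p, s, "surgical",
                                       seed)
      fit <- fit_surgical(d, p, s, horizon_years = horizon, ...)
      trial <- apply_trial(fit$estimates, fit$spec, p, s)
      list(fit = fit, data = d,
           trajectory = simulate_bone(trial$p, trial$s, NULL, cfg))
    },
    no_new_effects = {
      s0 <- surgical_parameters(kappa_E = s$kappa_E, k_syn = s$k_syn)
      list(surgical = simulate_bone(p, s0, NULL, cfg),
           natural = simulate_bone(p, NULL,
                                   estrogen_model("natural", p = p),
                                   cfg))
    },
    alpha_sweep = {
      sweep <- sclerostin_production_sweep(
        p, s, alphas = sort(unique(c(seq(0.7, 1.2, by = 0.005),
                                     0.8, 0.94))))
      list(sweep = sweep,
           reference_points = sweep[sweep$alpha %in% c(0.8, 0.94), ],
           premenopause_rate = steady_bmd_rate(p, E = 1),
           postmenopause_rate = steady_bmd_rate(p,
                                                E = s$k_syn / s$kappa_E))
    },
    sensitivity = {
      sensitivity_envelope(p, s, NULL, cfg)
    })

  manifest <- list(experiment = experiment,
                   natural_parameters = unclass(p),
                   surgical_parameters = if (!is.null(s)) unclass(s),
                   seed = seed,
                   tolerances = list(abs_tol = cfg$abs_tol,
                                     rel_tol = cfg$rel_tol),
                   package_version =
                     as.character(utils::packageVersion("osteodyn")))
  result$manifest <- manifest

  if (!is.null(output_dir)) write_bundle(result, experiment, output_dir)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

curated_synthetic <- function(spec, p, s, variant, seed) {
  if (is.null(spec))
    spec <- synthetic_cohort_spec(true_natural = p, true_surgical = s,
                                  estrogen_variant = variant,
                                  seed = seed)
  aggregate_bmd(lapply(generate_cohort(spec), normalize_study))
}

write_bundle <- function(result, experiment, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(result)) {
    x <- result[[nm]]
    if (inherits(x, "bone_trajectory"))
      write_trajectory_csv(x, out(paste0(nm, ".csv")))
    else if (inherits(x, "bmd_series"))
      write_bmd_series_csv(x, out(paste0(nm, ".csv")))
    else if (inherits(x, "bone_fit"))
      jsonlite::write_json(
        list(estimates = as.list(x$estimates), objective = x$objective,
             rmse_percent = x$rmse_percent, n_points = x$n_points,
             converged = x$converged, at_bound = as.list(x$at_bound)),
        out(paste0(nm, ".json")), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    else if (is.data.frame(x))
      utils::write.csv(x, out(paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(output_dir)
}
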