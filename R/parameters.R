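#' Model parameters for the natural-menopause bone remodeling model
#'
#' Constructs the full rate/threshold parameter set governing the basic
#' multicellular unit (BMU) model: differentiation and apoptosis rates of
#' the five cell populations, sclerostin turnover, bone formation and
#' resorption rates, Hill thresholds, and the estrogen decline timescale.
#' All rates are per day; all cell counts and concentrations are
#' dimensionless (scaled by the daily precursor production of the BMU).
#' Defaults are the published natural-menopause parameterization, also
#' shipped as `inst/extdata/parameters/natural.json`.
#'
#' @param omega_PC Differentiation rate of preosteoclasts to osteoclasts
#'   (day^-1).
#' @param omega_PB Differentiation rate of preosteoblasts to osteoblasts
#'   (day^-1).
#' @param omega_B Differentiation rate of osteoblasts to osteocytes
#'   (day^-1).
#' @param eta_B,eta_C,eta_S Apoptosis rates of osteoblasts, osteoclasts,
#'   and osteocytes (day^-1).
#' @param lambda_B,lambda_C First-order bone formation and resorption
#'   rates (day^-1).
#' @param kappa_Sc Sclerostin degradation rate (day^-1).
#' @param tau_E Characteristic time of the hyperbolic estrogen decline in
#'   natural menopause, in **years** (converted to days internally; see
#'   `$tau_E_days`).
#' @param e_PC Estrogen threshold inhibiting preosteoclast-to-osteoclast
#'   differentiation (dimensionless).
#' @param e_Sc Estrogen threshold inhibiting sclerostin production
#'   (dimensionless).
#' @param sc_PC Sclerostin threshold activating osteoclast
#'   differentiation.
#' @param sc_PB Sclerostin threshold inhibiting osteoblast
#'   differentiation.
#' @param sc_Omega Sclerostin threshold inhibiting bone formation.
#' @param r_Omega Threshold for resorption-coupled enhancement of
#'   formation.
#' @param nu_Omega Maximum relative effect of resorption on formation.
#' @param BMC0 Bone mineral content scale; BMD = `BMC0 * Bd`. Must lie in
#'   (0, 1].
#' @param t_m Time of menopause onset on the simulation clock, in days
#'   (default 0; simulations run from 30 years before to 30 years after).
#' @param resorption_coupling Either `"activation"` (default: the
#'   resorption factor R = C *enhances* formation through
#'   `1 + nu_Omega * f+(R, r_Omega)`, the published equation) or
#'   `"inhibition"` (`1 + nu_Omega * f-(R, r_Omega)`), exposed for
#'   exploration only.
#' @return An object of class `natural_parameters` (a named list).
#' @seealso [surgical_parameters()], [read_parameter_config()]
#' @export
natural_parameters <- function(omega_PC = 0.93,
                               omega_PB = 0.32,
                               omega_B = 6.4e-4,
                               eta_B = 8.678e-3,
                               eta_C = 1.096e-4,
                               eta_S = 1.1e-4,
                               lambda_B = 1.29e-6,
                               lambda_C = 3.82e-6,
                               kappa_Sc = 0.05,
                               tau_E = 2.6,
                               e_PC = 0.2556,
                               e_Sc = 10.59,
                               sc_PC = 8.6e6,
                               sc_PB = 1.63e2,
                               sc_Omega = 3.04e3,
                               r_Omega = 1.02e3,
                               nu_Omega = 1.08e3,
                               BMC0 = 0.8,
                               t_m = 0,
                               resorption_coupling = c("activation",
                                                       "inhibition")) {
  resorption_coupling <- match.arg(resorption_coupling)
  p <- list(omega_PC = omega_PC, omega_PB = omega_PB, omega_B = omega_B,
            eta_B = eta_B, eta_C = eta_C, eta_S = eta_S,
            lambda_B = lambda_B, lambda_C = lambda_C, kappa_Sc = kappa_Sc,
            tau_E = tau_E, tau_E_days = tau_E * 365,
            e_PC = e_PC, e_Sc = e_Sc,
            sc_PC = sc_PC, sc_PB = sc_PB, sc_Omega = sc_Omega,
            r_Omega = r_Omega, nu_Omega = nu_Omega,
            BMC0 = BMC0, t_m = t_m,
            resorption_coupling = resorption_coupling)
  class(p) <- c("natural_parameters", "list")
  validate_natural_parameters(p)
  p
}

validate_natural_parameters <- function(p) {
  rates <- c("omega_PC", "omega_PB", "omega_B", "eta_B", "eta_C", "eta_S",
             "lambda_B", "lambda_C", "kappa_Sc")
  thresholds <- c("e_PC", "e_Sc", "sc_PC", "sc_PB", "sc_Omega", "r_Omega")
  for (nm in c(rates, thresholds, "tau_E", "nu_Omega", "BMC0", "t_m")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter `%s` must be a finite numeric scalar", nm),
           call. = FALSE)
  }
  for (nm in rates)
    if (p[[nm]] < 0)
      stop(sprintf("rate `%s` must be >= 0", nm), call. = FALSE)
  for (nm in thresholds)
    if (p[[nm]] <= 0)
      stop(sprintf("threshold `%s` must be > 0", nm), call. = FALSE)
  if (p$tau_E <= 0) stop("`tau_E` must be > 0", call. = FALSE)
  if (p$BMC0 <= 0 || p$BMC0 > 1)
    stop("`BMC0` must lie in (0, 1]", call. = FALSE)
  if (p$nu_Omega < 0) stop("`nu_Omega` must be >= 0", call. = FALSE)
  invisible(p)
}

#' Model parameters specific to surgical menopause
#'
#' The surgical-menopause extension adds estrogen kinetics after abrupt
#' ovarian hormone withdrawal (first-order degradation `kappa_E` balanced
#' by a residual zero-order synthesis `k_syn`, giving a plateau
#' `k_syn / kappa_E`) and three surgery-effect parameters: fold-increases
#' in osteocyte apoptosis (`eta_surg`) and osteoclast differentiation
#' (`omega_surg`) at surgery, both relaxing back at rate `tau`
#' (`tau = 0` makes the effect permanent).
#'
#' Default estrogen kinetics derive from a 161-minute post-menopausal
#' estradiol half-life and a drop from 156 to 15 pg/mL by 30 days
#' post-surgery via [estrogen_kinetics_from_physiology()]. The effect
#' parameters default to zero (no new effects); use [surgical_preset()]
#' for the published short-term and long-term calibrations.
#'
#' @param kappa_E Estrogen degradation rate post-surgery (day^-1).
#' @param k_syn Residual estrogen synthesis rate post-surgery (day^-1);
#'   `k_syn / kappa_E` is the normalized plateau and must lie in `[0, 1]`.
#' @param eta_surg Peak fold-increase in osteocyte apoptosis at surgery
#'   (dimensionless, >= 0; the rate jumps to `(1 + eta_surg) * eta_S`).
#' @param omega_surg Peak fold-increase in osteoclast differentiation
#'   (dimensionless, >= 0).
#' @param tau Relaxation rate of both surgery effects (day^-1, >= 0).
#' @return An object of class `surgical_parameters`.
#' @export
surgical_parameters <- function(kappa_E = NULL, k_syn = NULL,
                                eta_surg = 0, omega_surg = 0, tau = 0) {
  if (is.null(kappa_E) || is.null(k_syn)) {
    kin <- estrogen_kinetics_from_physiology(161, 156, 15)
    if (is.null(kappa_E)) kappa_E <- kin$kappa_E
    if (is.null(k_syn)) k_syn <- kin$k_syn
  }
  s <- list(kappa_E = kappa_E, k_syn = k_syn, eta_surg = eta_surg,
            omega_surg = omega_surg, tau = tau)
  class(s) <- c("surgical_parameters", "list")
  validate_surgical_parameters(s)
  s
}

validate_surgical_parameters <- function(s) {
  for (nm in c("kappa_E", "k_syn", "eta_surg", "omega_surg", "tau")) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter `%s` must be a finite numeric scalar", nm),
           call. = FALSE)
  }
  if (s$kappa_E <= 0) stop("`kappa_E` must be > 0", call. = FALSE)
  plateau <- s$k_syn / s$kappa_E
  if (plateau < 0 || plateau > 1)
    stop("`k_syn / kappa_E` (the estrogen plateau) must lie in [0, 1]",
         call. = FALSE)
  if (s$eta_surg < 0) stop("`eta_surg` must be >= 0", call. = FALSE)
  if (s$omega_surg < 0) stop("`omega_surg` must be >= 0", call. = FALSE)
  if (s$tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  invisible(s)
}

#' Published surgical-menopause calibrations
#'
#' Returns the surgery-effect parameter sets calibrated against
#' cross-sectional lumbar-spine BMD series truncated at 15 years
#' (`"short_term"`: `eta_surg = 5`, `tau = 9.7e-3`, `omega_surg = 1.86`)
#' or extended to 30 years (`"long_term"`: `eta_surg = 0.4174`,
#' `tau = 0`, i.e. permanent effects, `omega_surg = 0.2155`) after
#' surgery. Also shipped as JSON under
#' `inst/extdata/parameters/`.
#'
#' @param which `"short_term"`, `"long_term"`, or `"none"` (estrogen
#'   kinetics only, zero new effects).
#' @return A [surgical_parameters()] object.
#' @export
surgical_preset <- function(which = c("short_term", "long_term", "none")) {
  which <- match.arg(which)
  switch(which,
    short_term = surgical_parameters(eta_surg = 5, tau = 9.7e-3,
                                     omega_surg = 1.86),
    long_term = surgical_parameters(eta_surg = 0.4174, tau = 0,
                                    omega_surg = 0.2155),
    none = surgical_parameters())
}

#' Read and write flat parameter configuration files
#'
#' Parameter sets are serialized as flat key/value JSON whose keys match
#' the argument names of [natural_parameters()] and
#' [surgical_parameters()] (`tau_E` in years, as in the constructor). The
#' packaged defaults live under
#' `system.file("extdata", "parameters", package = "osteodyn")`:
#' `natural.json`, `surgical_short_term.json`, `surgical_long_term.json`.
#'
#' @param path File path to read from or write to.
#' @param p A `natural_parameters` or `surgical_parameters` object.
#' @return `read_parameter_config()` returns the reconstructed parameter
#'   object (the type is inferred from the keys);
#'   `write_parameter_config()` returns `path` invisibly.
#' @export
read_parameter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if ("kappa_E" %in% names(x)) {
    do.call(surgical_parameters,
            x[intersect(names(x),
                        c("kappa_E", "k_syn", "eta_surg", "omega_surg",
                          "tau"))])
  } else if ("omega_PC" %in% names(x)) {
    keep <- setdiff(names(formals(natural_parameters)), "...")
    do.call(natural_parameters, x[intersect(names(x), keep)])
  } else {
    stop("unrecognized parameter config (expected `omega_PC` or `kappa_E` ",
         "among the keys): ", path, call. = FALSE)
  }
}

#' @rdname read_parameter_config
#' @export
write_parameter_config <- function(p, path) {
  x <- unclass(p)
  x$tau_E_days <- NULL  # derived field; tau_E is stored in years
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.natural_parameters <- function(x, ...) {
  cat("<natural_parameters> (rates day^-1, thresholds dimensionless)\n")
  flds <- setdiff(names(x), c("tau_E_days", "resorption_coupling"))
  for (nm in flds) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-10s %s\n", "coupling", x$resorption_coupling))
  invisible(x)
}

#' @export
print.surgical_parameters <- function(x, ...) {
  cat("<surgical_parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  cat(sprintf("  estrogen plateau k_syn/kappa_E = %.4g\n",
              x$k_syn / x$kappa_E))
  invisible(x)
}
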