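#' Algebraic estrogen models
#'
#' Estrogen enters the bone remodeling model as a prescribed algebraic
#' function of time, normalized to its level at menopause onset. Three
#' variants are supported:
#' \describe{
#'   \item{`natural`}{`E(t) = 1` for `t <= t_m`, then the hyperbolic
#'     decay `1 / (1 + (t - t_m) / tau_E)` with characteristic time
#'     `tau_E` (days).}
#'   \item{`surgical`}{`E(t) = 1` for `t <= t_m`, then
#'     `(1 - k_syn/kappa_E) exp(-kappa_E (t - t_m)) + k_syn/kappa_E`:
#'     first-order degradation toward the residual-synthesis plateau
#'     `k_syn / kappa_E`, reached (to within 1e-6) by about 30 days.}
#'   \item{`constant`}{`E(t) = level` for all `t`; used in steady-state
#'     analyses.}
#' }
#'
#' @param variant One of `"natural"`, `"surgical"`, `"constant"`.
#' @param t_m Menopause onset time (days).
#' @param tau_E Characteristic decline time for the natural variant, in
#'   **days**.
#' @param kappa_E,k_syn Surgical degradation and synthesis rates
#'   (day^-1); defaults from [surgical_parameters()].
#' @param level Constant level for the `constant` variant, in `(0, 1]`.
#' @param p,s Optional [natural_parameters()] / [surgical_parameters()]
#'   objects from which `t_m`, `tau_E`, `kappa_E`, `k_syn` are taken.
#' @return An object of class `estrogen_model`.
#' @examples
#' e <- estrogen_model("natural", p = natural_parameters())
#' estrogen_level(e, c(-100, 0, 2.6 * 365))  # 1, 1, 0.5
#' @export
estrogen_model <- function(variant = c("natural", "surgical", "constant"),
                           t_m = 0, tau_E = 2.6 * 365,
                           kappa_E = NULL, k_syn = NULL, level = 1,
                           p = NULL, s = NULL) {
  variant <- match.arg(variant)
  if (!is.null(p)) {
    t_m <- p$t_m
    tau_E <- p$tau_E_days
  }
  if (variant == "surgical") {
    if (is.null(s) && (is.null(kappa_E) || is.null(k_syn)))
      s <- surgical_parameters()
    if (!is.null(s)) {
      kappa_E <- s$kappa_E
      k_syn <- s$k_syn
    }
    plateau <- k_syn / kappa_E
    if (kappa_E <= 0 || plateau < 0 || plateau > 1)
      stop("surgical estrogen model requires kappa_E > 0 and ",
           "k_syn/kappa_E in [0, 1]", call. = FALSE)
  }
  if (variant == "natural" && tau_E <= 0)
    stop("natural estrogen model requires tau_E > 0", call. = FALSE)
  if (variant == "constant" && (level <= 0 || level > 1))
    stop("constant estrogen level must lie in (0, 1]", call. = FALSE)
  m <- list(variant = variant, t_m = t_m, tau_E = tau_E,
            kappa_E = kappa_E, k_syn = k_syn, level = level)
  class(m) <- c("estrogen_model", "list")
  m
}

#' Evaluate an estrogen model
#'
#' @param model An [estrogen_model()].
#' @param t Time(s) in days on the simulation clock. Vectorized.
#' @param post_branch If `TRUE`, use the post-menopause branch on the
#'   *closed* interval `[t_m, Inf)` (right-limit convention used when
#'   integrating the post-onset segment); by default the pre-menopause
#'   value 1 applies at exactly `t = t_m`.
#' @return Normalized estrogen concentration(s) in `(0, 1]`.
#' @export
estrogen_level <- function(model, t, post_branch = FALSE) {
  stopifnot(inherits(model, "estrogen_model"))
  if (model$variant == "constant") return(rep(model$level, length(t)))
  dt <- t - model$t_m
  post <- if (post_branch) dt >= 0 else dt > 0
  out <- rep(1, length(t))
  if (any(post)) {
    dtp <- dt[post]
    out[post] <- switch(model$variant,
      natural = 1 / (1 + dtp / model$tau_E),
      surgical = {
        plateau <- model$k_syn / model$kappa_E
        (1 - plateau) * exp(-model$kappa_E * dtp) + plateau
      })
  }
  out
}

#' Estrogen kinetic rates from physiological measurements
#'
#' Converts a post-menopausal estradiol half-life and the pre-surgery /
#' 30-days-post-surgery serum concentrations into the first-order
#' degradation rate `kappa_E = ln(2) / t_half` (day^-1), the normalized
#' plateau `post_conc / pre_conc`, and the zero-order residual synthesis
#' rate `k_syn = kappa_E * plateau`. With the literature values
#' (161 min, 156 pg/mL, 15 pg/mL) this gives `kappa_E = 6.1996` day^-1,
#' plateau `0.096`, and `k_syn = 0.596` day^-1.
#'
#' @param half_life_min Estradiol half-life in minutes (> 0).
#' @param pre_conc Serum estradiol before surgery (pg/mL).
#' @param post_conc Serum estradiol at the post-surgical plateau (pg/mL);
#'   must be below `pre_conc`.
#' @return A list with `kappa_E`, `k_syn` (day^-1), and `plateau`
#'   (dimensionless).
#' @export
estrogen_kinetics_from_physiology <- function(half_life_min, pre_conc,
                                              post_conc) {
  if (half_life_min <= 0 || pre_conc <= 0 || post_conc <= 0)
    stop("all arguments must be positive", call. = FALSE)
  if (post_conc >= pre_conc)
    stop("`post_conc` must be below `pre_conc` (normalized plateau < 1)",
         call. = FALSE)
  kappa_E <- log(2) / (half_life_min / 1440)  # minutes -> days
  plateau <- post_conc / pre_conc
  list(kappa_E = kappa_E, k_syn = kappa_E * plateau, plateau = plateau)
}

#' @export
print.estrogen_model <- function(x, ...) {
  cat(sprintf("<estrogen_model> variant = %s, t_m = %g days\n",
              x$variant, x$t_m))
  if (x$variant == "natural")
    cat(sprintf("  tau_E = %g days\n", x$tau_E))
  if (x$variant == "surgical")
    cat(sprintf("  kappa_E = %g /day, k_syn = %g /day, plateau = %.4g\n",
                x$kappa_E, x$k_syn, x$k_syn / x$kappa_E))
  if (x$variant == "constant")
    cat(sprintf("  level = %g\n", x$level))
  invisible(x)
}
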