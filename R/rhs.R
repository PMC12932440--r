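#' Right-hand side of the bone remodeling ODE system
#'
#' Evaluates the time derivatives of the seven-component state
#' `(PB, PC, C, B, S, Sc, Bd)`: scaled preosteoblasts, preosteoclasts,
#' osteoclasts, osteoblasts, osteocytes, sclerostin, and bone density.
#' Estrogen is evaluated algebraically from `e` at time `t`; the
#' post-surgical boosts to osteoclast differentiation and osteocyte
#' apoptosis come from `s` (pass `NULL` for the natural model). The
#' model equations are:
#' \preformatted{
#' dPB/dt = 1 - omega_PB f-(Sc, sc_PB) PB
#' dPC/dt = 1 - omega(t) f-(E, e_PC) f+(Sc, sc_PC) PC
#' dC/dt  = omega(t) f-(E, e_PC) f+(Sc, sc_PC) PC - eta_C C
#' dB/dt  = omega_PB f-(Sc, sc_PB) PB - (eta_B + omega_B) B
#' dS/dt  = omega_B B - eta(t) S
#' dSc/dt = f-(E, e_Sc) S - kappa_Sc Sc
#' dBd/dt = lambda_B B f-(Sc, sc_Omega) (1 + nu_Omega f+(R, r_Omega))
#'          - lambda_C C,  with R = C
#' }
#' Basal production of both precursor pools is 1 in scaled units. Bone
#' density feeds back into no other equation. Note that `dBd/dt` is not
#' sign-protected at `Bd = 0`: the resorption term is zeroth-order in
#' `Bd`, so bone density can become negative under unbalanced parameter
#' sets (the six cell/signal components are structurally nonnegative).
#'
#' @param t Time in days.
#' @param state Named or positional numeric vector
#'   `(PB, PC, C, B, S, Sc, Bd)`, all nonnegative.
#' @param p A [natural_parameters()] object.
#' @param s A [surgical_parameters()] object or `NULL`.
#' @param e An [estrogen_model()].
#' @param post_branch Right-limit convention at `t = t_m` (see
#'   [estrogen_level()]).
#' @return Named numeric vector of derivatives, same order as `state`.
#' @export
bone_rhs <- function(t, state, p, s = NULL, e, post_branch = FALSE) {
  if (length(state) != 7L)
    stop("`state` must have 7 components (PB, PC, C, B, S, Sc, Bd)",
         call. = FALSE)
  if (any(!is.finite(state)))
    stop("`state` contains non-finite values", call. = FALSE)
  f <- make_derivs(p, s, e, post_branch)
  d <- f(t, unname(state))
  names(d) <- state_names()
  d
}

state_names <- function() c("PB", "PC", "C", "B", "S", "Sc", "Bd")

# Closure evaluating the derivatives with all parameters resolved up
# front; this is the hot path for the integrator and the calibration
# loop, so it avoids any per-call list handling.
make_derivs <- function(p, s, e, post_branch = FALSE) {
  omega_PB <- p$omega_PB; omega_PC <- p$omega_PC; omega_B <- p$omega_B
  eta_B <- p$eta_B; eta_C <- p$eta_C; eta_S <- p$eta_S
  lambda_B <- p$lambda_B; lambda_C <- p$lambda_C; kappa_Sc <- p$kappa_Sc
  e_PC <- p$e_PC; e_Sc <- p$e_Sc
  sc_PC <- p$sc_PC; sc_PB <- p$sc_PB; sc_Omega <- p$sc_Omega
  r_Omega <- p$r_Omega; nu_Omega <- p$nu_Omega
  t_m <- p$t_m
  inhib_coupling <- identical(p$resorption_coupling, "inhibition")
  omega_surg <- if (is.null(s)) 0 else s$omega_surg
  eta_surg <- if (is.null(s)) 0 else s$eta_surg
  relax <- if (is.null(s)) 0 else s$tau
  variant <- e$variant
  tau_E <- e$tau_E; kappa_E <- e$kappa_E
  plateau <- if (variant == "surgical") e$k_syn / e$kappa_E else NA_real_
  level <- e$level
  eBsum <- eta_B + omega_B

  function(t, y) {
    dt_m <- t - t_m
    post <- if (post_branch) dt_m >= 0 else dt_m > 0
    E <- if (variant == "constant") level
         else if (!post) 1
         else if (variant == "natural") 1 / (1 + dt_m / tau_E)
         else (1 - plateau) * exp(-kappa_E * dt_m) + plateau
    boost <- if (post) exp(-relax * dt_m) else 0
    w <- omega_PC * (1 + omega_surg * boost)
    h <- eta_S * (1 + eta_surg * boost)

    PB <- y[1L]; PC <- y[2L]; C <- y[3L]; B <- y[4L]
    S <- y[5L]; Sc <- y[6L]

    pc_flux <- w * (e_PC / (E + e_PC)) * (Sc / (Sc + sc_PC)) * PC
    pb_flux <- omega_PB * (sc_PB / (Sc + sc_PB)) * PB
    coupling <- if (inhib_coupling) r_Omega / (C + r_Omega)
                else C / (C + r_Omega)
    d <- c(1 - pb_flux,                        # PB
           1 - pc_flux,                        # PC
           pc_flux - eta_C * C,                # C
           pb_flux - eBsum * B,                # B
           omega_B * B - h * S,                # S
           (e_Sc / (E + e_Sc)) * S - kappa_Sc * Sc,  # Sc
           lambda_B * B * (sc_Omega / (Sc + sc_Omega)) *
             (1 + nu_Omega * coupling) - lambda_C * C)  # Bd
    if (any(!is.finite(d))) {
      eqs <- state_names()[!is.finite(d)]
      stop(sprintf(
        "non-finite derivative in equation(s) %s at t = %g",
        paste(eqs, collapse = ", "), t), call. = FALSE)
    }
    d
  }
}
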