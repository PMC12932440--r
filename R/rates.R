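#' Time-dependent post-surgical rates
#'
#' Surgical menopause transiently boosts two rates. Osteoclast
#' differentiation from preosteoclasts follows
#' `omega(t) = omega_PC` for `t <= t_m` and
#' `omega_PC * (1 + omega_surg * exp(-tau (t - t_m)))` afterwards;
#' osteocyte apoptosis follows the same law with `eta_S` and `eta_surg`.
#' Both jump by the fold-increase at onset and relax back at rate `tau`
#' (`tau = 0` makes the boost permanent). With `s = NULL` or a zero
#' fold-increase they reduce exactly to the constant natural-menopause
#' rates.
#'
#' @param t Time(s) in days. Vectorized.
#' @param p A [natural_parameters()] object (supplies the baseline rate
#'   and `t_m`).
#' @param s A [surgical_parameters()] object, or `NULL` for the natural
#'   model.
#' @param post_branch If `TRUE`, apply the post-onset branch at exactly
#'   `t = t_m` (right-limit convention for post-segment integration).
#' @return Rate(s) in day^-1, bounded by
#'   `[baseline, baseline * (1 + fold)]`.
#' @export
osteoclast_differentiation_rate <- function(t, p, s = NULL,
                                            post_branch = FALSE) {
  surge_rate(t, p$omega_PC, p$t_m, if (is.null(s)) 0 else s$omega_surg,
             if (is.null(s)) 0 else s$tau, post_branch)
}

#' @rdname osteoclast_differentiation_rate
#' @export
osteocyte_apoptosis_rate <- function(t, p, s = NULL, post_branch = FALSE) {
  surge_rate(t, p$eta_S, p$t_m, if (is.null(s)) 0 else s$eta_surg,
             if (is.null(s)) 0 else s$tau, post_branch)
}

surge_rate <- function(t, base, t_m, fold, relax, post_branch) {
  dt <- t - t_m
  post <- if (post_branch) dt >= 0 else dt > 0
  out <- rep(base, length(t))
  if (fold > 0 && any(post))
    out[post] <- base * (1 + fold * exp(-relax * dt[post]))
  out
}
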