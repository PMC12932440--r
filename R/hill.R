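#' Saturating Hill-type signaling interactions
#'
#' Activation and repression of one species by another are modeled with
#' first-order saturating (Hill exponent 1) functions. `hill_activation()`
#' returns \eqn{f^+(X, k) = X / (X + k)} and `hill_inhibition()` returns
#' \eqn{f^-(X, k) = k / (X + k)}, where `threshold` \eqn{k} is the
#' concentration of `x` at which half of the interaction strength is
#' reached. The two always sum to one at the same `(x, threshold)`.
#'
#' @param x Nonnegative concentration (or scaled cell count) of the
#'   signaling species. Vectorized.
#' @param threshold Positive half-saturation threshold, on the same scale
#'   as `x`.
#' @return A value in `[0, 1)` for activation, `(0, 1]` for inhibition.
#' @examples
#' hill_activation(1, 1)        # 0.5 at half-saturation
#' hill_inhibition(0, 5)        # 1: no inhibitor present
#' hill_activation(2, 3) + hill_inhibition(2, 3)  # identically 1
#' @export
hill_activation <- function(x, threshold) {
  check_hill_args(x, threshold)
  x / (x + threshold)
}

#' @rdname hill_activation
#' @export
hill_inhibition <- function(x, threshold) {
  check_hill_args(x, threshold)
  threshold / (x + threshold)
}

check_hill_args <- function(x, threshold) {
  if (!is.numeric(x) || !is.numeric(threshold))
    stop("`x` and `threshold` must be numeric", call. = FALSE)
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop("Hill `threshold` must be positive and finite", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("Hill `x` must be nonnegative and finite", call. = FALSE)
  invisible(TRUE)
}
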