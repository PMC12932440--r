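# Shared fixtures and independent oracles.

default_p <- natural_parameters()
surg_none <- surgical_parameters()
surg_short <- surgical_preset("short_term")
surg_long <- surgical_preset("long_term")

# Premenopausal reference levels used in percent-of-baseline checks
# (computed once from the closed-form cascade).
ss_ref <- premenopausal_steady_state(default_p)$state

# Independent fixed-step classical RK4 integrator, used as the oracle
# for the adaptive solver. `keep_t` must be multiples of `h`.
rk4_oracle <- function(f, y0, keep_t, h) {
  stopifnot(all(abs(keep_t / h - round(keep_t / h)) < 1e-9))
  y <- unname(y0)
  out <- matrix(NA_real_, length(keep_t), length(y0))
  ki <- 1L
  nsteps <- round(max(keep_t) / h)
  for (i in 0:nsteps) {
    t <- i * h
    if (ki <= length(keep_t) && abs(t - keep_t[ki]) < 1e-6) {
      out[ki, ] <- y
      ki <- ki + 1L
    }
    if (i == nsteps) break
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

# Noise-free series sampled straight from the model, for
# self-consistency fits.
model_series <- function(p, s, times = c(0, 1, 2, 3, 5, 8, 10, 12, 15)) {
  spec <- synthetic_cohort_spec(true_natural = p, true_surgical = s,
                                estrogen_variant =
                                  if (is.null(s)) "natural"
                                  else "surgical",
                                observation_times = times,
                                noise_sd = 0, n_studies = 1, seed = 1L)
  normalize_study(generate_cohort(spec)[[1L]])
}
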