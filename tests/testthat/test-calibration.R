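test_that("residuals vanish on data sampled from the model", {
  d <- model_series(default_p, surg_short,
                    times = c(0, 1, 3, 5, 8, 12, 15, 20))
  spec <- fit_specification(c("eta_surg", "tau", "omega_surg"), d,
                            horizon_years = 15)
  r <- model_residuals(c(surg_short$eta_surg, surg_short$tau,
                         surg_short$omega_surg),
                       spec, default_p, surg_short)
  # only the 7 in-horizon observations enter
  expect_length(r, 7)
  expect_lt(max(abs(r)), 1e-7)
  # the onset observation is pinned by normalization
  expect_lt(abs(r[1]), 1e-12)
})

test_that("fit specification enforces protocol and bounds", {
  d <- model_series(default_p, NULL, times = c(0, 2, 5))
  expect_error(fit_specification(c("e_PC", "tau"), d), "subset")
  expect_error(fit_specification("e_PC", d, lower = c(e_PC = 2),
                                 upper = c(e_PC = 1)), "bounds")
  spec <- fit_specification(c("eta_surg", "tau", "omega_surg"), d)
  expect_equal(unname(spec$lower), c(0, 0, 0))
  expect_equal(unname(spec$upper), c(5, 1, 5))
  spec365 <- fit_specification(c("tau"), d, tau_upper = 1 / 365)
  expect_equal(unname(spec365$upper), 1 / 365)
})

test_that("a single-parameter fit recovers the generating value", {
  s_true <- surgical_parameters(eta_surg = 0, tau = 9.7e-3,
                                omega_surg = 1.2)
  d <- model_series(default_p, s_true, times = c(0, 0.5, 1, 2, 4, 8))
  spec <- fit_specification("omega_surg", d, horizon_years = 8)
  s_init <- surgical_parameters(eta_surg = 0, tau = 9.7e-3)
  fit <- fit_bone_model(spec, default_p, s = s_init, start = 2.5)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["omega_surg"]] - 1.2) / 1.2, 1e-3)
  # objective cannot exceed its value at the start point
  r0 <- model_residuals(2.5, spec, default_p, s_init)
  expect_lte(fit$objective, sum(r0^2))
})

test_that("absent effects are driven to the lower bound", {
  d <- model_series(default_p, surg_none, times = c(0, 1, 2, 5, 8))
  spec <- fit_specification(c("eta_surg", "omega_surg"), d,
                            horizon_years = 8)
  fit <- fit_bone_model(spec, default_p, s = surg_none,
                        start = c(0.5, 0.5))
  expect_lt(fit$estimates[["eta_surg"]], 1e-3)
  expect_lt(fit$estimates[["omega_surg"]], 1e-3)
  expect_lt(fit$rmse_percent, 0.01)
})

test_that("seeded multi-start reaches one basin on noise-free data", {
  s_true <- surgical_parameters(eta_surg = 0, tau = 9.7e-3,
                                omega_surg = 1.2)
  d <- model_series(default_p, s_true, times = c(0, 0.5, 1, 2, 4, 8))
  spec <- fit_specification("omega_surg", d, horizon_years = 8)
  s_init <- surgical_parameters(eta_surg = 0, tau = 9.7e-3)
  f1 <- fit_bone_model(spec, default_p, s = s_init, multi_start = TRUE,
                       n_starts = 5, seed = 99)
  f2 <- fit_bone_model(spec, default_p, s = s_init, multi_start = TRUE,
                       n_starts = 5, seed = 99)
  expect_equal(f1$estimates, f2$estimates)  # deterministic under seed
  expect_lt(abs(f1$objective - 0), 1e-6)
  expect_equal(f1$n_starts, 6L)
})

test_that("rmse is consistent with the objective", {
  d <- model_series(default_p, surg_none, times = c(0, 1, 2, 5))
  spec <- fit_specification("omega_surg", d, horizon_years = 8)
  fit <- fit_bone_model(spec, default_p, s = surg_none, start = 0)
  expect_equal(fit$rmse_percent,
               sqrt(fit$objective / fit$n_points) * 100)
  expect_true(fit$at_bound[["omega_surg"]])
})
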