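test_that("closed form and root solve agree to 1e-10 relative", {
  ss <- premenopausal_steady_state(default_p, cross_check = TRUE)
  expect_lt(ss$residual_norm, 1e-10)
  cf <- osteodyn:::closed_form_equilibrium(default_p, 1, 1)
  rs <- osteodyn:::root_solve_equilibrium(default_p, 1, 1, start = cf)
  expect_true(all(abs(rs - cf) / cf < 1e-10))
})

test_that("equilibrium components are positive and Bd-independent", {
  ss <- premenopausal_steady_state(default_p)
  expect_true(all(ss$state > 0))
  expect_equal(unname(ss$state[["Bd"]]), 1)
  # structure: B pinned by basal influx, C by its apoptosis rate
  expect_equal(unname(ss$state[["B"]]),
               1 / (default_p$eta_B + default_p$omega_B))
  expect_equal(unname(ss$state[["C"]]), 1 / default_p$eta_C)
})

test_that("doubling osteocyte apoptosis halves S and Sc, not B", {
  p2 <- natural_parameters(eta_S = 2 * 1.1e-4)
  s1 <- premenopausal_steady_state(default_p)$state
  s2 <- premenopausal_steady_state(p2)$state
  expect_equal(unname(s2[["S"]] / s1[["S"]]), 0.5)
  expect_equal(unname(s2[["Sc"]] / s1[["Sc"]]), 0.5)
  expect_equal(unname(s2[["B"]]), unname(s1[["B"]]))
})

test_that("lower estrogen raises equilibrium sclerostin", {
  hi <- premenopausal_steady_state(default_p, E = 1)$state
  lo <- premenopausal_steady_state(default_p, E = 0.096)$state
  expect_gt(lo[["Sc"]], hi[["Sc"]])
})

test_that("steady BMD rate decreases in the production multiplier", {
  E_post <- surg_none$k_syn / surg_none$kappa_E
  sweep <- sclerostin_production_sweep(default_p, surg_none,
                                       alphas = seq(0.7, 1.2, by = 0.05))
  expect_true(all(diff(sweep$bmd_rate_pct_per_year) < 0))
  expect_named(sweep, c("alpha", "relative_production",
                        "bmd_rate_pct_per_year"))
  # x-axis rescaling: relative production is alpha times the estrogen
  # disinhibition ratio
  expect_equal(sweep$relative_production,
               sweep$alpha * hill_inhibition(E_post, default_p$e_Sc) /
                 hill_inhibition(1, default_p$e_Sc))
  # a root of the sweep yields a balanced (zero) rate
  a0 <- stats::uniroot(function(a) steady_bmd_rate(default_p, E_post, a),
                       c(0.7, 1.2), tol = 1e-10)$root
  expect_lt(abs(steady_bmd_rate(default_p, E_post, a0)), 1e-4)
})

test_that("invalid inputs are rejected", {
  expect_error(premenopausal_steady_state(default_p, E = 0), "E")
  expect_error(premenopausal_steady_state(default_p, alpha = -1),
               "alpha")
  expect_error(natural_parameters(eta_C = -1), "rate")
  expect_error(natural_parameters(e_PC = 0), "threshold")
})
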