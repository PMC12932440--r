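test_that("constant estrogen keeps the cell system at its fixed point", {
  e <- estrogen_model("constant", level = 1)
  traj <- simulate_bone(default_p, NULL, e)
  cells <- c("PB", "PC", "C", "B", "S", "Sc")
  for (nm in cells) {
    rel <- abs(traj[[nm]] - ss_ref[[nm]]) / ss_ref[[nm]]
    expect_lt(max(rel), 1e-6)
  }
  expect_equal(traj$relative_bmd[traj$years_since_onset == 0], 1)
})

test_that("adaptive solution matches a fixed-step RK4 oracle", {
  e <- estrogen_model("surgical", p = default_p, s = surg_short)
  keep_t <- seq(0, 5 * 365, by = 36.5)
  cfg <- simulation_config(t_start = -365, t_end = 5 * 365,
                           output_grid = c(-365, keep_t))
  traj <- simulate_bone(default_p, surg_short, e, cfg)
  y0 <- as.numeric(traj[match(0, traj$time),
                        osteodyn:::state_names()])
  f <- osteodyn:::make_derivs(default_p, surg_short, e,
                              post_branch = TRUE)
  oracle <- rk4_oracle(f, y0, keep_t, h = 0.25)
  sol <- as.matrix(traj[match(keep_t, traj$time),
                        osteodyn:::state_names()])
  rel <- abs(sol - oracle) / pmax(abs(oracle), 1e-8)
  expect_lt(max(rel), 1e-5)
})

test_that("halving the tolerances leaves the solution unchanged", {
  e <- estrogen_model("natural", p = default_p)
  t1 <- simulate_bone(default_p, NULL, e, simulation_config())
  t2 <- simulate_bone(default_p, NULL, e,
                      simulation_config(abs_tol = 5e-9, rel_tol = 5e-9))
  i_end <- nrow(t1)
  expect_lt(abs(t1$relative_bmd[i_end] - t2$relative_bmd[i_end]) /
              abs(t1$relative_bmd[i_end]), 1e-6)
})

test_that("trajectory structure and normalization conventions hold", {
  traj <- simulate_bone(default_p, surg_long)
  expect_s3_class(traj, "bone_trajectory")
  expect_true(all(diff(traj$time) > 0))
  expect_equal(traj$relative_bmd[traj$years_since_onset == 0], 1)
  expect_equal(traj$bmd, default_p$BMC0 * traj$Bd)
  cells <- c("PB", "PC", "C", "B", "S", "Sc")
  expect_true(all(as.matrix(traj[, cells]) >= 0))
})

test_that("interpolation is exact on the grid and bounded between", {
  cfg <- simulation_config(t_start = -2 * 365, t_end = 10 * 365)
  traj <- simulate_bone(default_p, surg_short, NULL, cfg)
  expect_equal(relative_bmd_at(traj, 0), 1)
  yrs <- traj$years_since_onset
  expect_equal(relative_bmd_at(traj, yrs[c(3, 10, 40)]),
               traj$relative_bmd[c(3, 10, 40)])
  # monotone interpolation: value between the bracketing grid values
  for (i in c(5, 20, 60)) {
    mid <- (yrs[i] + yrs[i + 1]) / 2
    v <- relative_bmd_at(traj, mid)
    lohi <- range(traj$relative_bmd[i:(i + 1)])
    expect_gte(v, lohi[1] - 1e-12)
    expect_lte(v, lohi[2] + 1e-12)
  }
  expect_error(relative_bmd_at(traj, 11), "span")
  expect_error(relative_bmd_at(traj, -3), "span")
})

test_that("sensitivity envelope brackets the nominal run", {
  cfg <- simulation_config(t_start = -2 * 365, t_end = 8 * 365)
  env0 <- sensitivity_envelope(default_p, surg_short, cfg = cfg,
                               fraction = 0)
  expect_equal(env0$upper$Bd, env0$nominal$Bd)
  expect_equal(env0$lower$Bd, env0$nominal$Bd)

  env <- sensitivity_envelope(default_p, surg_short, cfg = cfg,
                              fraction = 0.25)
  expect_equal(env$upper$relative_bmd[env$upper$years_since_onset == 0],
               1)
  # tau = 0 is preserved by scaling in both directions
  env_l <- sensitivity_envelope(default_p, surg_long, cfg = cfg,
                                fraction = 0.25)
  expect_equal(attr(env_l$upper, "surgical")$tau, 0)
  expect_equal(attr(env_l$lower, "surgical")$tau, 0)
  # early years are less sensitive than late years (BMD spread)
  spread <- abs(env$upper$bmd - env$lower$bmd)
  yrs <- env$nominal$years_since_onset
  expect_lt(mean(spread[yrs > 0 & yrs <= 2]),
            mean(spread[yrs > 6]))
})

test_that("simulation config validates its inputs", {
  expect_error(simulation_config(abs_tol = 0), "tolerances")
  expect_error(simulation_config(output_grid = c(1, 1, 2)),
               "increasing")
  expect_error(simulate_bone(default_p, NULL,
                             estrogen_model("natural", p = default_p),
                             simulation_config(t_start = 10)),
               "t_start")
})
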