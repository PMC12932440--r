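test_that("noise-free generation reproduces the model trajectory", {
  spec <- synthetic_cohort_spec(true_natural = default_p,
                                true_surgical = surg_short,
                                estrogen_variant = "surgical",
                                observation_times = c(0, 1, 3, 7, 12),
                                noise_sd = 0, n_studies = 1, seed = 5)
  study <- generate_cohort(spec)[[1]]
  truth <- attr(study, "truth")
  norm <- normalize_study(study)
  expect_equal(norm$mean_bmd, truth / truth[1])
  # raw values need normalization: baseline scaling is applied
  expect_false(isTRUE(all.equal(study$points$mean_bmd, truth)))
})

test_that("generation is deterministic under the seed", {
  spec <- synthetic_cohort_spec(noise_sd = 0.05, n_studies = 3,
                                observation_times = c(0, 2, 6, 10),
                                seed = 123)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  c3 <- generate_cohort(synthetic_cohort_spec(
    noise_sd = 0.05, n_studies = 3,
    observation_times = c(0, 2, 6, 10), seed = 124))
  expect_false(identical(c1, c3))
})

test_that("study means scatter with standard error noise_sd/sqrt(n)", {
  spec <- synthetic_cohort_spec(true_natural = default_p,
                                estrogen_variant = "natural",
                                observation_times = c(0, 5, 10),
                                noise_sd = 0.06, n_per_point = 25,
                                n_studies = 200, seed = 404)
  cohort <- generate_cohort(spec)
  # de-scale each study by its recorded baseline to expose the draws
  at_10 <- vapply(cohort, function(st)
    st$points$mean_bmd[3] / attr(st, "baseline"), numeric(1))
  emp_sd <- stats::sd(at_10)
  expect_equal(emp_sd, 0.06 / sqrt(25), tolerance = 0.15)
  # recorded per-point SD is the population SD, not the standard error
  expect_equal(cohort[[1]]$points$sd / attr(cohort[[1]], "baseline"),
               rep(0.06, 3))
})

test_that("generate -> curate -> fit closes the loop", {
  spec <- synthetic_cohort_spec(true_natural = default_p,
                                true_surgical = surgical_parameters(
                                  eta_surg = 0, tau = 9.7e-3,
                                  omega_surg = 1.2),
                                estrogen_variant = "surgical",
                                observation_times = c(0, 0.5, 1, 2, 4, 8),
                                noise_sd = 0, n_studies = 2, seed = 7)
  rec <- recovery_experiment(spec, free_parameters = "omega_surg",
                             horizon_years = 8)
  expect_lt(rec$recovery$relative_error, 0.01)
  expect_lt(rec$trajectory_rmse_percent, 0.01)
  expect_s3_class(rec$data, "bmd_series")
})

test_that("cohort spec validates its fields", {
  expect_error(synthetic_cohort_spec(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_cohort_spec(observation_times = c(0, 40)),
               "observation_times")
  expect_error(synthetic_cohort_spec(n_per_point = 0), "n_per_point")
})
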