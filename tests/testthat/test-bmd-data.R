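toy_study <- function(means = c(1.10, 1.05, 0.99, 0.92), scale = 1,
                      times = c(0, 2, 5, 10), n = c(40, 35, 30, 25)) {
  bmd_study("toy", "lumbar_spine", "natural",
            points = data.frame(time_years = times,
                                mean_bmd = scale * means,
                                sd = scale * 0.05 * means,
                                n = n))
}

test_that("normalization divides by the onset observation", {
  s <- normalize_study(toy_study())
  expect_equal(s$mean_bmd[1], 1)
  expect_equal(s$mean_bmd, c(1.10, 1.05, 0.99, 0.92) / 1.10)
  # SD scaled by the same factor: coefficient of variation preserved
  expect_equal(s$sd / s$mean_bmd, rep(0.05, 4))
})

test_that("normalization is scale-invariant and idempotent", {
  a <- normalize_study(toy_study(scale = 1))
  b <- normalize_study(toy_study(scale = 3.7))
  expect_equal(as.data.frame(a), as.data.frame(b))
  renorm <- normalize_study(
    bmd_study("toy", "lumbar_spine", "natural",
              points = data.frame(time_years = a$time_years,
                                  mean_bmd = a$mean_bmd, sd = a$sd,
                                  n = a$n)))
  expect_equal(as.data.frame(renorm), as.data.frame(a))
})

test_that("missing onset observation is a curation error", {
  s <- toy_study(times = c(4, 6, 9, 12))
  expect_error(normalize_study(s), "toy")
  expect_silent(normalize_study(s, onset_window = 5))
})

test_that("aggregation pools by cohort size", {
  mk <- function(id, t, m, n) {
    x <- bmd_series(data.frame(time_years = t, mean_bmd = m,
                               sd = 0.04, n = n), provenance = id)
    x
  }
  # hand-computed weighted mean: (10*0.90 + 30*0.94) / 40 = 0.93
  agg <- aggregate_bmd(list(mk("a", 5.2, 0.90, 10),
                            mk("b", 5.7, 0.94, 30)))
  expect_equal(agg$mean_bmd, 0.93)
  expect_equal(agg$n, 40)
  unw <- aggregate_bmd(list(mk("a", 5.2, 0.90, 10),
                            mk("b", 5.7, 0.94, 30)), weighted = FALSE)
  expect_equal(unw$mean_bmd, 0.92)
})

test_that("aggregation is order-invariant and identity-like", {
  s1 <- normalize_study(toy_study())
  s2 <- normalize_study(toy_study(means = c(1.0, 0.97, 0.93, 0.9)))
  ab <- aggregate_bmd(list(s1, s2))
  ba <- aggregate_bmd(list(s2, s1))
  expect_equal(as.data.frame(ab), as.data.frame(ba))
  # two identical series: between-study variance is zero
  aa <- aggregate_bmd(list(s1, s1))
  expect_equal(aa$mean_bmd, s1$mean_bmd)
  expect_equal(aa$sd, s1$sd)
  # single series passes through up to binning
  one <- aggregate_bmd(list(s1))
  expect_equal(one$mean_bmd, s1$mean_bmd)
})

test_that("linear loss rate is the OLS slope in percent per year", {
  lin <- bmd_series(data.frame(time_years = 0:10,
                               mean_bmd = 1 - 0.02 * (0:10),
                               sd = 0.01, n = 20))
  expect_equal(linear_loss_rate(lin), -2)
  flat <- bmd_series(data.frame(time_years = 0:5, mean_bmd = 0.9,
                                sd = 0.01, n = 20))
  expect_equal(linear_loss_rate(flat), 0)
  # slope invariant to an additive shift
  shifted <- bmd_series(data.frame(time_years = 0:10,
                                   mean_bmd = 1.3 - 0.02 * (0:10),
                                   sd = 0.01, n = 20))
  expect_equal(linear_loss_rate(shifted), -2)
  # window restriction: only the first 15 years enter
  kink <- bmd_series(data.frame(time_years = c(0:15, 20, 25),
                                mean_bmd = c(1 - 0.01 * (0:15), 2, 3),
                                sd = 0.01, n = 20))
  expect_equal(linear_loss_rate(kink, 15), -1)
  deg <- bmd_series(data.frame(time_years = c(2, 2), mean_bmd = c(1, 1),
                               sd = 0, n = 1))
  expect_error(linear_loss_rate(deg), "degenerate|window")
})

test_that("CSV schema is validated with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(study_id = "s1", site = "L2-L4",
                   menopause_type = c("natural", "natural", "weird"),
                   time_years = c(0, 5, 10),
                   mean_bmd = c(1.05, 1.0, -2),
                   sd = c(0.05, 0.05, 0.05), n = c(30, 30, 30))
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_bmd_studies(path), "line 4")

  df$menopause_type <- "surgical"
  df$mean_bmd <- c(1.05, 1.0, 0.95)
  utils::write.csv(df, path, row.names = FALSE)
  studies <- read_bmd_studies(path)
  expect_length(studies, 1)
  expect_equal(studies[[1]]$menopause_type, "surgical")
  expect_equal(nrow(studies[[1]]$points), 3)

  series <- normalize_study(studies[[1]])
  out <- withr::local_tempfile(fileext = ".csv")
  write_bmd_series_csv(series, out)
  back <- utils::read.csv(out)
  expect_equal(back$mean_bmd, series$mean_bmd)
})
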