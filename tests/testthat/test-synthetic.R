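test_that("noise-free generation reproduces the model solution exactly", {
  net <- test_net()
  des <- list(times_days = c(0, 7, 14, 21, 28), V0 = 0.03,
              arms = "control")
  ds <- generate_growth_dataset(net, list(k0 = 1.5e-6, k1 = 4e-7), des,
                                noise_cv = 0, seed = 1)
  expect_equal(ds$control$volume_cm3, ds$provenance$v_true_control)
  # refitting noise-free data drives the SSR to solver precision
  pr <- fit_problem(ds, net, n_starts = 1, seed = 1)
  expect_lt(sum_squared_residuals(c(k0 = 1.5e-6, k1 = 4e-7), pr),
            1e-6 * mean(ds$control$volume_cm3)^2)
})

test_that("measurement noise has the requested coefficient of variation", {
  net <- test_net()
  des <- list(times_days = c(0, 10, 20), V0 = 0.05, arms = "control")
  # one deterministic simulation, many noise draws: replicate datasets
  obs <- vapply(1:200, function(s)
    generate_growth_dataset(net, list(k0 = 1.5e-6, k1 = 4e-7), des,
                            noise_cv = 0.05, seed = s)$control$volume_cm3[3],
    numeric(1))
  cv_emp <- sd(obs) / mean(obs)
  expect_lt(abs(cv_emp / 0.05 - 1), 0.20)
})

test_that("generation is deterministic in the seed, including file bytes", {
  net <- test_net()
  des <- list(times_days = c(0, 7, 14, 21), V0 = 0.02,
              arms = c("control", "treated"), dose = 10,
              treat_start_day = 7)
  d1 <- generate_growth_dataset(net, list(k0 = 2e-6, k1 = 4e-7), des,
                                noise_cv = 0.05, seed = 99)
  d2 <- generate_growth_dataset(net, list(k0 = 2e-6, k1 = 4e-7), des,
                                noise_cv = 0.05, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_growth_dataset(d1, f1)
  write_growth_dataset(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(d1$control, d2$control)
})

test_that("designs with too few points are refused", {
  net <- test_net()
  expect_error(generate_growth_dataset(
    net, list(k0 = 2e-6, k1 = 4e-7),
    list(times_days = c(0, 7), V0 = 0.02, arms = "control")),
    "at least 3")
})

test_that("the preset library spans the study conditions", {
  pre <- preset_designs()
  expect_length(pre, 6)
  for (d in pre) {
    expect_true("control" %in% d$arms)
    expect_true(d$dose %in% c(2, 10))
    expect_gte(length(d$times_days), 5)
  }
  # at least two templates have >= 3 strictly pre-treatment measurements
  n_pre <- vapply(pre, function(d)
    sum(d$times_days < d$treat_start_day), numeric(1))
  expect_gte(sum(n_pre >= 3), 2)
})

test_that("preset ensembles reach final control volumes of 0.8-2.5 cm^3", {
  net <- test_net()
  finals <- vapply(preset_designs(), function(d) {
    ds <- generate_growth_dataset(net, d$true_growth, d, noise_cv = 0,
                                  seed = 1)
    tail(ds$provenance$v_true_control, 1)
  }, numeric(1))
  expect_gt(max(finals), 0.8 * 0.9)
  expect_lt(min(finals), 2.5)
  expect_true(all(finals > 0.5 & finals < 3))
  expect_gt(diff(range(finals)), 0.5)   # genuine diversity
})

test_that("dataset files round-trip and reject schema violations", {
  net <- test_net()
  des <- list(times_days = c(0, 7, 14, 21), V0 = 0.02,
              arms = c("control", "treated"), dose = 2,
              treat_start_day = 7)
  ds <- generate_growth_dataset(net, list(k0 = 2e-6, k1 = 4e-7), des,
                                noise_cv = 0.05, seed = 5, id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_dataset(ds, path)
  back <- read_growth_dataset(path)
  expect_equal(back$control$volume_cm3, ds$control$volume_cm3,
               tolerance = 1e-11)
  expect_equal(back$treated$volume_cm3, ds$treated$volume_cm3,
               tolerance = 1e-11)
  expect_equal(back$dose, 2)
  expect_equal(back$V0, 0.02)
  expect_equal(back$provenance$truth$k0, 2e-6)

  df <- read.csv(path)
  df$volume_cm3[3] <- -1
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_growth_dataset(bad), "row 3")

  df2 <- read.csv(path)
  df2$arm[2] <- "placebo"
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, bad2, row.names = FALSE)
  expect_error(read_growth_dataset(bad2), "placebo")

  df3 <- read.csv(path)[, -2]
  bad3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, bad3, row.names = FALSE)
  expect_error(read_growth_dataset(bad3), "missing columns")

  # unsorted times are normalized with a warning
  df4 <- read.csv(path)
  df4 <- df4[c(2, 1, 3:nrow(df4)), ]
  un <- withr::local_tempfile(fileext = ".csv")
  write.csv(df4, un, row.names = FALSE)
  expect_warning(rt <- read_growth_dataset(un), "unsorted")
  expect_false(is.unsorted(rt$control$time_days))
})
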