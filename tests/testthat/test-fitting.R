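make_dataset <- function(noise_cv = 0, seed = 11,
                         k0 = 1.6e-6, k1 = 4.5e-7) {
  des <- list(times_days = seq(0, 56, by = 7), V0 = 0.03, arms = "control")
  generate_growth_dataset(test_net(), list(k0 = k0, k1 = k1), des,
                          noise_cv = noise_cv, seed = seed)
}

test_that("the SSR objective is exact at the generating parameters", {
  ds <- make_dataset(noise_cv = 0)
  pr <- fit_problem(ds, test_net(), n_starts = 1, seed = 1)
  th <- c(k0 = 1.6e-6, k1 = 4.5e-7)
  ssr0 <- sum_squared_residuals(th, pr)
  expect_lt(ssr0, 1e-6 * mean(ds$control$volume_cm3)^2)
  # perturbing the observations by known residuals gives their sum of
  # squares (0.1^2 + 0.2^2 + 0.3^2 = 0.14 on three points)
  ds2 <- ds
  ds2$control <- ds$control[1:3, ]
  ds2$control$volume_cm3 <- ds2$control$volume_cm3 + c(0.1, -0.2, 0.3)
  pr2 <- fit_problem(ds2, test_net(), n_starts = 1, seed = 1)
  expect_equal(sum_squared_residuals(th, pr2), 0.14, tolerance = 1e-4)
  expect_gte(sum_squared_residuals(c(k0 = 5e-6, k1 = 1e-7), pr2), 0)
})

test_that("default bounds span the study ranges", {
  b <- default_bounds()
  expect_equal(b$k0, c(1e-8, 1e-2))
  expect_equal(b$k1, c(1e-8, 1e-2))
  expect_equal(b$Ang0, c(1e-16, 1e-14))
})

test_that("multistart fitting recovers generating parameters and is
           deterministic under a fixed seed", {
  ds <- make_dataset(noise_cv = 0)
  pr <- fit_problem(ds, test_net(), n_starts = 6, seed = 42)
  en <- fit_dataset(pr)
  expect_equal(nrow(en$runs), 6)
  b <- en$runs[en$best, ]
  expect_lt(abs(b$k0 / 1.6e-6 - 1), 0.05)
  expect_lt(abs(b$k1 / 4.5e-7 - 1), 0.05)
  en2 <- fit_dataset(fit_problem(ds, test_net(), n_starts = 6, seed = 42))
  expect_identical(en$runs, en2$runs)
  # single-start ensembles are legal
  en1 <- fit_dataset(fit_problem(ds, test_net(), n_starts = 1, seed = 3))
  expect_equal(nrow(en1$runs), 1)
})

test_that("fitting problems validate their inputs", {
  ds <- make_dataset()
  ds$control <- ds$control[1:2, ]
  expect_error(fit_problem(ds, test_net()), "at least 3")
  ds2 <- make_dataset()
  expect_error(fit_problem(ds2, test_net(),
                           bounds = list(k0 = c(1e-2, 1e-8),
                                         k1 = c(1e-8, 1e-2))),
               "lower < upper")
})

test_that("best-fit selection keeps runs within the SSR tolerance", {
  ds <- make_dataset(noise_cv = 0.05)
  pr <- fit_problem(ds, test_net(), n_starts = 4, seed = 5)
  en <- fit_dataset(pr)
  en$runs$ssr <- c(1.0, 1.05, 1.2, 1.0)   # synthetic SSR pattern
  sel <- select_best_fits(en, tol = 0.10)
  expect_equal(sort(sel$runs$run), c(1, 2, 4))
  expect_equal(sel$selection$tol, 0.10)
  en$runs$ssr <- rep(2.5, 4)
  expect_equal(nrow(select_best_fits(en)$runs), 4)
})

test_that("member bands: identical members collapse, best fit is contained", {
  ds <- make_dataset(noise_cv = 0.05, seed = 21)
  pr <- fit_problem(ds, test_net(), n_starts = 4, seed = 9)
  en <- select_best_fits(fit_dataset(pr))
  times <- ds$control$time_days * 86400
  bm <- confidence_band(en, times = times, method = "members")
  # the min/max member envelope contains the best-fit trajectory
  sims <- angiofit:::apply_ensemble(en, times)
  expect_true(all(apply(sims, 1, min) <= bm$best))
  expect_true(all(bm$best <= apply(sims, 1, max)))
  one <- en
  one$runs <- en$runs[rep(en$best, 3), ]
  one$best <- 1L
  b1 <- confidence_band(one, times = times, method = "members")
  expect_equal(b1$lower, b1$upper)
  # covariance band is wider than the multistart spread and brackets data
  bc <- confidence_band(en, times = times)
  expect_true(all(bc$upper - bc$lower >= bm$upper - bm$lower - 1e-12))
})

test_that("early-data fits carry wider uncertainty than full fits", {
  ds <- make_dataset(noise_cv = 0.05, seed = 31)
  full <- select_best_fits(fit_dataset(
    fit_problem(ds, test_net(), n_starts = 8, seed = 2)))
  early <- ds
  early$control <- ds$control[ds$control$time_days <= 21, ]
  early_fit <- select_best_fits(fit_dataset(
    fit_problem(early, test_net(), n_starts = 8, seed = 2)))
  times <- ds$control$time_days * 86400
  area <- function(cb) sum(cb$upper - cb$lower)
  expect_gt(area(confidence_band(early_fit, times = times)),
            area(confidence_band(full, times = times)))
})

test_that("rank-based comparisons match a hand-ranked computation", {
  g <- list(a = c(1, 2, 3), b = c(10, 20, 30), c = c(100, 200, 300))
  res <- compare_parameter_sets(g)
  # hand-computed Kruskal-Wallis H: ranks 1..9, group rank sums 6, 15, 24
  H <- 12 / (9 * 10) * (6^2 / 3 + 15^2 / 3 + 24^2 / 3) - 3 * 10
  expect_equal(res$omnibus_H, H)
  expect_equal(dim(res$adjusted_matrix), c(3, 3))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p - 1e-12))
  # identical groups are not significant
  same <- compare_parameter_sets(list(a = c(1, 2, 3, 4),
                                      b = c(1, 2, 3, 4)))
  expect_gt(same$pairwise$p_adj[1], 0.05)
  # constant data across all groups takes the p = 1 path
  const <- compare_parameter_sets(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(const$omnibus_p, 1)
  # Benjamini-Hochberg leaves a single p-value unchanged
  expect_equal(p.adjust(0.037, method = "BH"), 0.037)
  expect_error(compare_parameter_sets(list(a = 1:3)), "two groups")
})
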