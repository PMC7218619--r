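test_that("random-walk extension reproduces its deterministic limits", {
  # RW2 at infinite precision continues the last slope exactly
  ext2 <- extend_random_walk(c(-0.1, 0, 0.1, 0.2), Inf, order = 2, horizon = 3)
  expect_equal(ext2[1, 5:7], c(0.3, 0.4, 0.5))
  # RW1 at infinite precision continues the last value
  ext1 <- extend_random_walk(c(0.3, 0.7), Inf, order = 1, horizon = 4)
  expect_equal(ext1[1, 3:6], rep(0.7, 4))
  # zero horizon is the identity
  u <- matrix(rnorm(10), 2, 5)
  expect_identical(extend_random_walk(u, c(1, 2), order = 1, horizon = 0), u)
})

test_that("h-step RW1 increments have variance h / tau", {
  set.seed(6)
  tau <- 4
  S <- 1e5
  u <- matrix(0, S, 2)
  for (h in c(1, 3)) {
    ext <- extend_random_walk(u, rep(tau, S), order = 1, horizon = h)
    inc <- ext[, 2 + h] - ext[, 2]
    v <- stats::var(inc)
    mc_se <- (h / tau) * sqrt(2 / (S - 1))
    expect_lt(abs(v - h / tau), 3 * mc_se)
  }
})

test_that("frozen flat posterior projects a constant rate everywhere", {
  fz <- frozen_fit()
  proj <- project_rates(fz, horizon = 3, levels = c(10, 50, 95))
  expect_true(all(abs(proj$mean - 0.4) < 1e-12))
  expect_true(all(abs(proj$median - 0.4) < 1e-12))
  expect_true(all(abs(proj$lower - 0.4) < 1e-12))
  expect_true(all(abs(proj$upper - 0.4) < 1e-12))
  # future period labels continue the observed five-year grid
  expect_setequal(unique(proj$period_start), c(2016, 2021, 2026))
  # at-risk counts carried forward from the last observed period
  last_n <- fz$table$n[fz$table$period_index == 3]
  expect_setequal(unique(proj$n_at_risk), unique(last_n))
})

test_that("credible bands are nested across levels in every cell", {
  fit <- debug_fit()
  proj <- project_rates(fit, horizon = 2, levels = c(10, 25, 50, 75, 95))
  nested <- proj |>
    dplyr::group_by(.data$age_start, .data$period_start) |>
    dplyr::arrange(.data$level, .by_group = TRUE) |>
    dplyr::summarise(
      ok = all(diff(lower) <= 1e-12) && all(diff(upper) >= -1e-12) &&
        all(lower <= median & median <= upper),
      .groups = "drop"
    )
  expect_true(all(nested$ok))
  expect_true(all(proj$lower >= 0))
})

test_that("projection bands need enough posterior draws to resolve", {
  fz <- frozen_fit()
  small <- fz
  small$n_draws <- 10L
  small$draws <- lapply(fz$draws, function(x) if (is.matrix(x)) x[1:10, , drop = FALSE] else x[1:10])
  expect_error(project_rates(small, horizon = 1, levels = c(95)), "at least 40 draws")
})

test_that("projections are stable under thinning of the draws", {
  fit <- male_fit()
  proj <- project_rates(fit, horizon = 2, include_overdispersion = FALSE)
  half <- fit
  keep <- seq(1, fit$n_draws, by = 2)
  half$draws <- lapply(fit$draws, function(x) if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep])
  half$n_draws <- length(keep)
  proj_half <- project_rates(half, horizon = 2, include_overdispersion = FALSE)
  j <- dplyr::inner_join(
    dplyr::distinct(tibble::as_tibble(proj), age_start, period_start, median),
    dplyr::distinct(tibble::as_tibble(proj_half), age_start, period_start, median),
    by = c("age_start", "period_start"), suffix = c("", "_half")
  )
  expect_true(all(abs(j$median_half / j$median - 1) < 0.01))
})

test_that("projection deltas measure the change from the baseline period", {
  fz <- frozen_fit()
  proj <- project_rates(fz, horizon = 2, levels = c(50, 95))
  delta <- projection_delta(proj, fz$table)
  base <- fz$table |> dplyr::filter(period_index == 3)
  expect_equal(delta$baseline_rate, base$y / base$n)
  expect_equal(delta$delta, 0.4 - delta$baseline_rate)
  expect_equal(delta$delta_pct_points, 100 * delta$delta)
  expect_error(projection_delta(proj, fz$table, baseline_period = 1900), "not present")

  # hand example: baseline 0.40, projected 0.55 -> +15 percentage points
  toy_tab <- apc_table(tibble::tibble(
    age_start = 31, age_end = 35, period_start = 2011, period_end = 2015,
    n_at_risk = 100, cases = 40
  ))
  toy_proj <- tibble::tibble(
    age_start = 31, age_end = 35, period_start = 2016, period_end = 2020,
    median = 0.55, mean = 0.55, level = 95, lower = 0.5, upper = 0.6
  )
  d <- projection_delta(toy_proj, toy_tab)
  expect_equal(d$delta, 0.15)
  expect_equal(d$delta_pct_points, 15)
})

test_that("a rising period effect projects higher rates for every age group", {
  # default-shaped truth, large counts and no cell noise so the direction
  # of the comparison against the observed baseline is unambiguous
  tr0 <- default_truth("female")
  tr <- apc_truth(
    mu = tr0$mu, alpha = tr0$alpha, beta = tr0$beta, gamma = tr0$gamma,
    n_pattern = matrix(50000L, 14, 5), stratum = "female",
    overdispersion_sd = 0
  )
  tab <- generate_apc_table(tr, seed = 17)
  fit <- fit_apc(
    tab, apc_model_spec(overdispersion = FALSE),
    mcmc_config(n_iter = 12000, burnin = 4000, thin = 10, chains = 1, seed = 23)
  )
  proj <- project_rates(fit, horizon = 2)
  delta <- projection_delta(proj, tab)
  expect_true(all(delta$delta > 0))
})
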