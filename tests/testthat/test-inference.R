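test_that("precision Gibbs step draws from the conjugate Gamma conditional", {
  set.seed(1)
  u <- rnorm(8)
  draws <- replicate(200, gibbs_update_precision(u, order = 1))
  expect_true(all(draws > 0))
  expect_error(gibbs_update_precision(c(1, 2), order = 2), "length >= 3")

  # linear vector under RW2: roughness 0, so the conditional is the
  # Gamma(shape + r/2, rate) and its mean is known in closed form
  u_lin <- 0.3 * (1:10)
  hyper <- c(shape = 1, rate = 0.00005)
  r <- 10 - 2
  set.seed(2)
  d <- replicate(1e5, gibbs_update_precision(u_lin, order = 2, hyper = hyper))
  m_true <- (1 + r / 2) / 0.00005
  mc_se <- sqrt(1 + r / 2) / 0.00005 / sqrt(1e5)
  expect_lt(abs(mean(d) - m_true), 3 * mc_se)

  # full-distribution agreement against the reference CDF
  set.seed(3)
  u2 <- rnorm(6, 0, 0.5)
  q <- rw_quadratic_form(u2, 1)
  d2 <- replicate(1e4, gibbs_update_precision(u2, order = 1, hyper = c(2, 1)))
  ks <- suppressWarnings(stats::ks.test(d2, stats::pgamma, shape = 2 + 5 / 2, rate = 1 + q / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seed and config give bitwise-identical fits", {
  tab <- debug_table()
  cfg <- mcmc_config(n_iter = 1500, burnin = 500, thin = 5, chains = 2, seed = 99)
  f1 <- fit_apc(tab, apc_model_spec(), cfg)
  f2 <- fit_apc(tab, apc_model_spec(), cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summarize_effects(f1), summarize_effects(f2))
})

test_that("retained draws respect sum-to-zero and sane acceptance rates", {
  fit <- debug_fit()
  expect_true(all(abs(rowMeans(fit$draws$alpha)) < 1e-10))
  expect_true(all(abs(rowMeans(fit$draws$beta)) < 1e-10))
  expect_true(all(abs(rowMeans(fit$draws$gamma)) < 1e-10))
  expect_true(all(fit$draws$tau > 0))
  expect_identical(length(fit$draws$mu), (6000L - 2000L) %/% 5L)
  expect_true(all(fit$acceptance$acceptance_rate > 0.05))
  expect_true(all(fit$acceptance$acceptance_rate < 0.8))
})

test_that("intercept-only data recover the pooled log rate", {
  tr <- apc_truth(
    mu = log(0.445), alpha = rep(0, 4), beta = rep(0, 3), gamma = rep(0, 6),
    n_pattern = rep(20000L, 4), stratum = "flat",
    age_starts = seq(51, by = 5, length.out = 4),
    period_starts = seq(2001, by = 5, length.out = 3)
  )
  tab <- generate_apc_table(tr, seed = 8)
  fit <- fit_apc(
    tab, apc_model_spec(overdispersion = FALSE),
    mcmc_config(n_iter = 6000, burnin = 2000, thin = 5, chains = 1, seed = 21)
  )
  target <- log(sum(tab$y) / sum(tab$n))
  mu_d <- fit$draws$mu
  expect_lt(abs(mean(mu_d) - target), 3 * stats::sd(mu_d))
})

test_that("chains agree: split R-hat below 1.05 on mu and precisions", {
  fit <- male_fit()
  expect_lt(split_rhat(fit$draws$mu, fit$draws$chain), 1.05)
  for (tt in c("tau_alpha", "tau_beta", "tau_gamma", "tau_z")) {
    expect_lt(split_rhat(log(fit$draws$tau[, tt]), fit$draws$chain), 1.05)
  }
})

test_that("posterior means agree with dense-grid quadrature under tight priors", {
  # 2 x 2 table, AP model without overdispersion; precisions pinned by a
  # near-degenerate hyperprior so the posterior reduces to 3 free
  # parameters (mu, age contrast, period contrast) amenable to quadrature
  cells <- expand.grid(i = 1:2, j = 1:2)
  df <- tibble::tibble(
    age_start = 31 + 5 * (cells$i - 1), age_end = 35 + 5 * (cells$i - 1),
    period_start = 1991 + 5 * (cells$j - 1), period_end = 1995 + 5 * (cells$j - 1),
    n_at_risk = 5000, cases = c(1500, 2000, 1800, 2400)
  )
  tab <- apc_table(df)
  tau0 <- 100
  hyper <- c(shape = 2e6, rate = 2e6 / tau0) # tau concentrated at 100
  spec <- apc_model_spec(c("age", "period"), rw_order = 1, overdispersion = FALSE,
    effect_hyperprior = hyper
  )
  fit <- fit_apc(tab, spec, mcmc_config(
    n_iter = 2e5, burnin = 2e4, thin = 20, chains = 1, seed = 13
  ))

  # quadrature oracle over (mu, a, b), alpha = (-a, a), beta = (-b, b)
  lp <- function(mu, a, b) {
    eta11 <- mu - a - b; eta21 <- mu + a - b
    eta12 <- mu - a + b; eta22 <- mu + a + b
    y <- matrix(c(1500, 2000, 1800, 2400), 2, 2)
    ll <- y[1, 1] * eta11 + y[2, 1] * eta21 + y[1, 2] * eta12 + y[2, 2] * eta22 -
      5000 * (exp(eta11) + exp(eta21) + exp(eta12) + exp(eta22))
    ll - tau0 * (2 * a)^2 / 2 - tau0 * (2 * b)^2 / 2
  }
  # centre the grid at the crude contrast estimates, span +/- 0.06
  a0 <- log(2000 / 1500) / 2
  b0 <- log(1800 / 1500) / 2
  mu0 <- log(1500 / 5000) + a0 + b0
  gr_a <- seq(a0 - 0.06, a0 + 0.06, length.out = 101)
  gr_b <- seq(b0 - 0.06, b0 + 0.06, length.out = 101)
  mu_gr <- seq(mu0 - 0.06, mu0 + 0.06, length.out = 101)
  grid <- expand.grid(mu = mu_gr, a = gr_a, b = gr_b)
  w <- lp(grid$mu, grid$a, grid$b)
  w <- exp(w - max(w))
  w <- w / sum(w)
  ref <- c(
    mu = sum(w * grid$mu),
    a = sum(w * grid$a),
    b = sum(w * grid$b)
  )
  est <- c(
    mu = mean(fit$draws$mu),
    a = mean(fit$draws$alpha[, 2]),
    b = mean(fit$draws$beta[, 2])
  )
  expect_equal(est[["mu"]], ref[["mu"]], tolerance = 0.02)
  expect_lt(abs(est[["a"]] - ref[["a"]]), 0.02 * max(abs(ref[["a"]]), 0.01))
  expect_lt(abs(est[["b"]] - ref[["b"]]), 0.02 * max(abs(ref[["b"]]), 0.01))
})

test_that("effect summaries respect sum-to-zero geometry and quantile equivariance", {
  fit <- debug_fit()
  # per draw the RRs of one effect multiply to 1
  prods <- exp(rowSums(fit$draws$gamma))
  expect_true(all(abs(prods - 1) < 1e-8))

  s <- summarize_effects(fit, level = 0.9)
  expect_true(all(s$lower_log <= s$median_log & s$median_log <= s$upper_log))
  expect_true(all(s$lower_RR <= s$median_RR & s$median_RR <= s$upper_RR))
  # the median commutes with exp (odd draw counts make it an order statistic)
  expect_equal(s$median_RR, exp(s$median_log), tolerance = 1e-6)

  # all-zero draws give RR = 1 everywhere
  fz <- frozen_fit()
  sz <- summarize_effects(fz)
  expect_true(all(sz$mean_RR == 1 & sz$median_RR == 1))

  set.seed(4)
  x <- rnorm(10001, 0.3, 0.2)
  expect_equal(median(exp(x)), exp(median(x)))
})

test_that("DIC collapses to the plug-in deviance for degenerate draws", {
  fit <- debug_fit()
  S <- fit$n_draws
  one <- posterior_params(fit, 1)
  ll1 <- poisson_loglik(fit$table, one)
  deg <- fit
  deg$draws$mu <- rep(fit$draws$mu[1], S)
  deg$draws$alpha <- fit$draws$alpha[rep(1, S), , drop = FALSE]
  deg$draws$beta <- fit$draws$beta[rep(1, S), , drop = FALSE]
  deg$draws$gamma <- fit$draws$gamma[rep(1, S), , drop = FALSE]
  deg$draws$z <- fit$draws$z[rep(1, S), , drop = FALSE]
  deg$draws$tau <- fit$draws$tau[rep(1, S), , drop = FALSE]
  deg$draws$loglik <- rep(ll1, S)
  dic <- compute_dic(deg)
  expect_equal(dic$pD, 0, tolerance = 1e-8)
  expect_equal(dic$DIC, -2 * ll1, tolerance = 1e-8)

  # thinning a deterministic repeated draw list changes nothing
  half <- deg
  keep <- seq(1, S, by = 2)
  for (nm in c("alpha", "beta", "gamma", "z", "tau")) {
    half$draws[[nm]] <- deg$draws[[nm]][keep, , drop = FALSE]
  }
  half$draws$mu <- deg$draws$mu[keep]
  half$draws$loglik <- deg$draws$loglik[keep]
  half$draws$chain <- deg$draws$chain[keep]
  half$n_draws <- length(keep)
  expect_equal(compute_dic(half)$DIC, dic$DIC)
})

test_that("stored log-likelihoods match independent recomputation", {
  fit <- debug_fit()
  idx <- c(1, 7, fit$n_draws)
  for (s in idx) {
    expect_equal(
      fit$draws$loglik[s],
      oracle_loglik(fit$table, posterior_params(fit, s)),
      tolerance = 1e-8
    )
  }
})

test_that("model selection prefers low DIC with the RW2 full-model tie-break", {
  tab <- debug_table()
  cfg <- mcmc_config(n_iter = 1200, burnin = 400, thin = 4, chains = 1, seed = 31)
  cands <- list(
    apc_model_spec(c("age", "period"), rw_order = 1, overdispersion = FALSE),
    apc_model_spec(rw_order = 2, overdispersion = FALSE)
  )
  sel <- select_model(tab, cands, cfg, near_tie_threshold = 2)
  expect_identical(nrow(sel$dic_table), 2L)
  expect_identical(sum(sel$dic_table$selected), 1L)
  dic_min <- min(sel$dic_table$DIC)
  full_dic <- sel$dic_table$DIC[sel$dic_table$spec_id == cands[[2]]$label]
  if (full_dic - dic_min < 2) {
    expect_identical(sel$spec$label, cands[[2]]$label)
  } else {
    expect_identical(sel$spec$label, sel$dic_table$spec_id[which.min(sel$dic_table$DIC)])
  }

  # single candidate: returned as-is
  solo <- select_model(tab, cands[1], cfg)
  expect_identical(solo$spec$label, cands[[1]]$label)

  # a candidate that cannot fit is flagged and skipped with a warning
  # 20-year age groups over 13-year periods: no integer width ratio, so
  # cohort-indexed candidates cannot fit while AP candidates can
  g <- expand.grid(a = c(31, 51), p = c(1991, 2004))
  no_cohort <- apc_table(tibble::tibble(
    age_start = g$a, age_end = g$a + 19,
    period_start = g$p, period_end = g$p + 12,
    n_at_risk = 500, cases = c(150, 200, 160, 210)
  ))
  cands2 <- list(
    apc_model_spec(c("age", "period", "cohort"), label = "needs-cohorts"),
    apc_model_spec(c("age", "period"), rw_order = 1, overdispersion = FALSE, label = "ap-ok")
  )
  expect_warning(
    sel2 <- select_model(no_cohort, cands2, mcmc_config(
      n_iter = 400, burnin = 100, thin = 2, chains = 1, seed = 5
    )),
    "needs-cohorts"
  )
  expect_identical(sel2$spec$label, "ap-ok")
  expect_false(sel2$dic_table$ok[1])
})
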