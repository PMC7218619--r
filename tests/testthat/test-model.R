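test_that("rw_quadratic_form matches difference penalties and their null spaces", {
  expect_equal(rw_quadratic_form(rep(2.5, 6), order = 1), 0)
  expect_equal(rw_quadratic_form(c(0, 1, 2, 3), order = 2), 0)
  expect_equal(rw_quadratic_form(c(0, 1, 3), order = 1), 5)
  expect_error(rw_quadratic_form(c(1, 2), order = 2), "length >= 3")

  set.seed(1)
  for (rep in 1:20) {
    u <- rnorm(sample(3:12, 1))
    shift <- rnorm(1)
    trend <- rnorm(1) * seq_along(u)
    expect_equal(rw_quadratic_form(u + shift, 1), rw_quadratic_form(u, 1), tolerance = 1e-10)
    expect_equal(rw_quadratic_form(u + shift, 2), rw_quadratic_form(u, 2), tolerance = 1e-10)
    expect_equal(rw_quadratic_form(u + trend, 2), rw_quadratic_form(u, 2), tolerance = 1e-10)
  }
})

test_that("linear_predictor adds the right effect levels per cell", {
  inst <- rand_instance(101, I = 3, J = 3)
  tab <- inst$table
  p0 <- apc_params(mu = log(0.4), alpha = rep(0, 3), beta = rep(0, 3), gamma = rep(0, 5))
  expect_equal(linear_predictor(p0, 2, 3, tab), log(0.4))

  p1 <- apc_params(
    mu = 0, alpha = c(0.1, 0, -0.1), beta = c(0.2, 0, -0.2),
    gamma = c(-0.3, 0.1, 0.1, 0.1, 0)
  )
  # i=1, j=1 -> k = (3-1)+1 = 3
  expect_equal(linear_predictor(p1, 1, 1, tab), 0 + 0.1 + 0.2 + 0.1)

  # brute-force per-cell recomputation on the full grid
  p <- inst$params
  for (i in 1:3) {
    for (j in 1:3) {
      k <- (3 - i) + j
      expected <- p$mu + p$alpha[i] +
        (if (is.null(p$beta)) 0 else p$beta[j]) +
        (if (is.null(p$gamma)) 0 else p$gamma[k]) +
        (if (is.null(p$z)) 0 else p$z[i, j])
      expect_equal(linear_predictor(p, i, j, tab), expected)
    }
  }
  expect_error(linear_predictor(p0, 4, 1, tab), "i <= I")
})

single_cell_table <- function(n, y) {
  apc_table(tibble::tibble(
    age_start = 31, age_end = 35, period_start = 1991, period_end = 1995,
    n_at_risk = n, cases = y
  ))
}

test_that("poisson_loglik matches hand-computed cells and the oracle", {
  p <- apc_params(mu = 0, alpha = 0, beta = 0, gamma = 0)
  # one cell, n = 2, lambda = 1: only the -n*lambda term survives at y = 0
  expect_equal(poisson_loglik(single_cell_table(2, 0), p), -2)
  # one cell, n*lambda = 1, y = 1: 1*log(1) - 1 - log(0!) = -1
  expect_equal(poisson_loglik(single_cell_table(1, 1), p), -1)

  tab <- single_cell_table(2, 1)
  tab$n[1] <- 0L
  expect_error(poisson_loglik(tab, p), "no subjects were at risk")

  for (seed in 1:10) {
    inst <- rand_instance(200 + seed)
    expect_equal(
      poisson_loglik(inst$table, inst$params),
      oracle_loglik(inst$table, inst$params),
      tolerance = 1e-10
    )
  }
})

test_that("log_prior responds linearly to the roughness penalty", {
  spec <- apc_model_spec(c("age", "period"), rw_order = 1, overdispersion = FALSE)
  base <- apc_params(
    mu = 0, alpha = c(-0.1, 0, 0.1), beta = c(-0.2, 0.2),
    tau_alpha = 2, tau_beta = 1
  )
  rough <- apc_params(
    mu = 0, alpha = c(-0.2, 0, 0.2), beta = c(-0.2, 0.2),
    tau_alpha = 2, tau_beta = 1
  )
  dq <- rw_quadratic_form(rough$alpha, 1) - rw_quadratic_form(base$alpha, 1)
  expect_equal(log_prior(rough, spec) - log_prior(base, spec), -2 * dq / 2)

  # constant vector contributes no roughness: kernel reduces to its constant
  flat <- apc_params(mu = 0, alpha = rep(0, 3), beta = c(-0.2, 0.2), tau_alpha = 1, tau_beta = 1)
  curved <- apc_params(mu = 0, alpha = c(-0.1, 0, 0.1), beta = c(-0.2, 0.2), tau_alpha = 1, tau_beta = 1)
  expect_equal(log_prior(flat, spec) - log_prior(curved, spec), rw_quadratic_form(curved$alpha, 1) / 2)
})

test_that("log_posterior equals likelihood plus prior and matches the oracle", {
  for (seed in 1:30) {
    inst <- rand_instance(300 + seed)
    lp <- log_posterior(inst$params, inst$table, inst$spec)
    expect_equal(lp, poisson_loglik(inst$table, inst$params) + log_prior(inst$params, inst$spec))
    expect_equal(lp, oracle_log_posterior(inst$params, inst$table, inst$spec),
      tolerance = 1e-8
    )
  }
})

test_that("with all effects zero the optimal intercept is the pooled log rate", {
  inst <- rand_instance(77, I = 4, J = 3)
  tab <- inst$table
  spec <- apc_model_spec(overdispersion = FALSE)
  obj <- function(mu) {
    log_posterior(
      apc_params(mu = mu, alpha = rep(0, 4), beta = rep(0, 3), gamma = rep(0, 6)),
      tab, spec
    )
  }
  opt <- optimize(obj, interval = c(-5, 2), maximum = TRUE)
  expect_equal(opt$maximum, log(sum(tab$y) / sum(tab$n)), tolerance = 1e-5)
})

test_that("likelihood increases as a count moves toward its expected value", {
  p <- apc_params(mu = log(0.4), alpha = 0, beta = 0, gamma = 0)
  # n = 1000, lambda = 0.4 -> n*lambda = 400
  lls <- vapply(c(300, 350, 380, 399), function(y) {
    poisson_loglik(single_cell_table(1000, y), p)
  }, 0)
  expect_true(all(diff(lls) > 0))
})
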