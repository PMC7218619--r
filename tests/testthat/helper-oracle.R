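# Independent brute-force oracles: plain loops over the printed model
# formulas, written separately from the package code paths.

log_factorial <- function(y) {
  if (y < 2) return(0)
  sum(log(seq(2, y)))
}

# Poisson log-likelihood, term by term, cohort index written out inline
oracle_loglik <- function(table, params) {
  d <- apc_dims(table)
  ll <- 0
  for (r in seq_len(nrow(table))) {
    i <- table$age_index[r]
    j <- table$period_index[r]
    k <- d$M * (d$I - i) + j
    eta <- params$mu + params$alpha[i]
    if (!is.null(params$beta)) eta <- eta + params$beta[j]
    if (!is.null(params$gamma)) eta <- eta + params$gamma[k]
    if (!is.null(params$z)) eta <- eta + params$z[i, j]
    m <- table$n[r] * exp(eta)
    if (table$n[r] > 0) {
      ll <- ll + table$y[r] * log(m) - m - log_factorial(table$y[r])
    }
  }
  ll
}

# prior density from first principles (explicit Gaussian / Gamma formulas)
oracle_log_prior <- function(params, spec) {
  gamma_logpdf <- function(x, shape, rate) {
    shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x
  }
  vecs <- list(age = params$alpha, period = params$beta, cohort = params$gamma)
  taus <- list(age = params$tau_alpha, period = params$tau_beta, cohort = params$tau_gamma)
  orders <- spec$rw_order
  lp <- 0
  for (eff in spec$effects) {
    u <- vecs[[eff]]
    tau <- taus[[eff]]
    ord <- orders[[eff]]
    q <- 0
    if (ord == 1) {
      for (t in 2:length(u)) q <- q + (u[t] - u[t - 1])^2
    } else {
      for (t in 3:length(u)) q <- q + (u[t] - 2 * u[t - 1] + u[t - 2])^2
    }
    r <- length(u) - ord
    lp <- lp + (r / 2) * log(tau / (2 * pi)) - tau * q / 2 +
      gamma_logpdf(tau, spec$effect_hyperprior[["shape"]], spec$effect_hyperprior[["rate"]])
  }
  if (spec$overdispersion) {
    tz <- params$tau_z
    for (v in as.vector(params$z)) {
      lp <- lp + 0.5 * log(tz / (2 * pi)) - tz * v^2 / 2
    }
    lp <- lp + gamma_logpdf(tz, spec$od_hyperprior[["shape"]], spec$od_hyperprior[["rate"]])
  }
  lp
}

oracle_log_posterior <- function(params, table, spec) {
  oracle_loglik(table, params) + oracle_log_prior(params, spec)
}

# random small instance: valid table + params consistent with a spec
rand_instance <- function(seed, I = NULL, J = NULL) {
  set.seed(seed)
  if (is.null(I)) I <- sample(2:5, 1)
  if (is.null(J)) J <- sample(2:5, 1)
  K <- I - 1 + J
  cells <- expand.grid(i = seq_len(I), j = seq_len(J))
  df <- tibble::tibble(
    age_start = 31 + 5 * (cells$i - 1), age_end = 35 + 5 * (cells$i - 1),
    period_start = 1991 + 5 * (cells$j - 1), period_end = 1995 + 5 * (cells$j - 1),
    n_at_risk = sample(50:500, I * J, replace = TRUE)
  )
  df$cases <- rbinom(I * J, df$n_at_risk, runif(1, 0.2, 0.6))
  table <- apc_table(df, stratum = "rand")

  effects <- sample(list(
    c("age", "period"), c("age", "cohort"), c("age", "period", "cohort")
  ), 1)[[1]]
  lens <- c(age = I, period = J, cohort = K)
  spec <- apc_model_spec(
    effects = effects,
    rw_order = setNames(
      vapply(effects, function(e) sample(seq_len(min(2, lens[[e]] - 1)), 1), 0L),
      effects
    ),
    overdispersion = runif(1) < 0.5
  )
  ctr <- function(v) v - mean(v)
  params <- apc_params(
    mu = rnorm(1, -1, 0.3),
    alpha = ctr(rnorm(I, 0, 0.2)),
    beta = if ("period" %in% effects) ctr(rnorm(J, 0, 0.2)) else NULL,
    gamma = if ("cohort" %in% effects) ctr(rnorm(K, 0, 0.2)) else NULL,
    z = if (spec$overdispersion) matrix(rnorm(I * J, 0, 0.1), I, J) else NULL,
    tau_alpha = rgamma(1, 3, 1), tau_beta = rgamma(1, 3, 1),
    tau_gamma = rgamma(1, 3, 1), tau_z = rgamma(1, 3, 1)
  )
  list(table = table, spec = spec, params = params)
}
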