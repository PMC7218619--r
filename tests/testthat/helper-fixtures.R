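# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

male_table <- function() {
  cached("male_table", suppressMessages(generate_apc_table(default_truth("male"), seed = 42)))
}

# moderate-length fit on the male default table, reused across tests
male_fit <- function() {
  cached("male_fit", fit_apc(
    male_table(), apc_model_spec(),
    mcmc_config(n_iter = 30000, burnin = 8000, thin = 20, chains = 2, seed = 7)
  ))
}

debug_table <- function() {
  cached("debug_table", {
    fx <- make_fixture_suite(file.path(tempdir(), "apc_fixture_suite"))
    read_apc_csv(fx$table_csv[fx$name == "debug_4x3_synthetic"])[[1]]
  })
}

debug_fit <- function() {
  cached("debug_fit", fit_apc(
    debug_table(), apc_model_spec(),
    mcmc_config(n_iter = 6000, burnin = 2000, thin = 5, chains = 1, seed = 11)
  ))
}

# degenerate fit whose draws are all identical: zero effects, mu = log(0.4),
# infinite precisions -- the deterministic limit used by projection tests
frozen_fit <- function(S = 64) {
  cached("frozen_fit", {
    tab <- suppressMessages(generate_apc_table(
      apc_truth(
        mu = log(0.4),
        alpha = rep(0, 4), beta = rep(0, 3), gamma = rep(0, 6),
        n_pattern = rep(5000L, 4), stratum = "frozen",
        age_starts = seq(51, by = 5, length.out = 4),
        period_starts = seq(2001, by = 5, length.out = 3)
      ),
      seed = 5
    ))
    spec <- apc_model_spec()
    tau <- matrix(Inf, S, 4, dimnames = list(NULL, c("tau_alpha", "tau_beta", "tau_gamma", "tau_z")))
    draws <- list(
      mu = rep(log(0.4), S),
      alpha = matrix(0, S, 4), beta = matrix(0, S, 3), gamma = matrix(0, S, 6),
      z = matrix(0, S, 12), tau = tau,
      loglik = rep(NA_real_, S), chain = rep(1L, S)
    )
    structure(
      list(
        draws = draws, acceptance = tibble::tibble(), spec = spec,
        config = mcmc_config(seed = 1), table = tab, n_draws = S
      ),
      class = "apc_fit"
    )
  })
}
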