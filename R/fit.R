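#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler: Gaussian random-walk
#' Metropolis single-site updates for the intercept, each effect level and
#' each overdispersion cell, conjugate Gamma updates for the precisions.
#' Proposal scales are adapted toward 20-40% acceptance during burn-in and
#' frozen afterwards.
#'
#' @param n_iter Total iterations per chain.
#' @param burnin Burn-in iterations discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param chains Number of independent chains.
#' @param seed Integer RNG seed.
#' @param proposal_scales Named initial proposal standard deviations for
#'   blocks `mu`, `age`, `period`, `cohort`, `od`.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 50000L, burnin = 10000L, thin = 20L,
                        chains = 2L, seed = 1L,
                        proposal_scales = c(
                          mu = 0.02, age = 0.05, period = 0.05,
                          cohort = 0.05, od = 0.05
                        )) {
  stopifnot(n_iter > 0, burnin >= 0, thin >= 1, chains >= 1)
  if (burnin >= n_iter) abort("`burnin` must be smaller than `n_iter`.")
  if (any(proposal_scales <= 0)) abort("proposal scales must be positive.")
  defaults <- c(mu = 0.02, age = 0.05, period = 0.05, cohort = 0.05, od = 0.05)
  if (!is.null(names(proposal_scales))) {
    defaults[names(proposal_scales)] <- proposal_scales
    proposal_scales <- defaults
  } else {
    proposal_scales <- setNames(rep_len(proposal_scales, 5), names(defaults))
  }
  structure(
    list(
      n_iter = as.integer(n_iter), burnin = as.integer(burnin),
      thin = as.integer(thin), chains = as.integer(chains),
      seed = as.integer(seed), proposal_scales = proposal_scales
    ),
    class = "mcmc_config"
  )
}

#' Conjugate Gibbs draw for a random-walk precision
#'
#' Given an effect vector `u` under an intrinsic RW prior of the stated
#' order with a Gamma(shape, rate) hyperprior on its precision, the full
#' conditional of the precision is
#' `Gamma(shape + r/2, rate + q(u)/2)` with rank r = `length(u) - order` and
#' `q` the [rw_quadratic_form()].
#'
#' @param u Numeric effect vector.
#' @param order Random-walk order, 1 or 2.
#' @param hyper Length-2 `(shape, rate)` of the Gamma hyperprior.
#' @return One positive draw of the precision.
#' @export
gibbs_update_precision <- function(u, order = 1L, hyper = c(shape = 1, rate = 0.00005)) {
  if (length(u) < order + 1) {
    abort(sprintf("effect vector too short: a random walk of order %d needs length >= %d.", order, order + 1))
  }
  if (any(hyper <= 0)) abort("hyperprior shape and rate must be positive.")
  r <- length(u) - order
  rgamma(1, shape = hyper[[1]] + r / 2, rate = hyper[[2]] + rw_quadratic_form(u, order) / 2)
}

# data-driven initial effect values: centred log marginal rates
init_effects <- function(table, spec) {
  d <- apc_dims(table)
  tot <- observed_rates(table, "total")
  mu0 <- log(max(tot$rate, 1e-6))
  centred_log <- function(margin, size) {
    r <- observed_rates(table, margin)
    v <- log(pmax(r$rate[match(seq_len(size), r$level)], 1e-6)) - mu0
    v[!is.finite(v)] <- 0
    v - mean(v)
  }
  alpha <- centred_log("age", d$I)
  beta <- if ("period" %in% spec$effects) centred_log("period", d$J) else numeric(0)
  gamma <- if ("cohort" %in% spec$effects) centred_log("cohort", d$K) else numeric(0)
  if (length(gamma) > 1 && length(beta) > 0) {
    # The APC linear null space (cohort = period - age) makes the linear
    # trend of gamma trade off exactly against linear trends in alpha and
    # beta; marginal-rate inits put an arbitrary age-composition tilt into
    # gamma. Start the chain at the tilt-free representative: project the
    # linear trend out of gamma and fold it into alpha and beta, leaving
    # the initial linear predictor unchanged cell-wise.
    kk <- seq_len(d$K)
    slope <- stats::cov(kk, gamma) / stats::var(kk)
    gamma <- gamma - slope * (kk - mean(kk))
    a_adj <- slope * d$M * (d$I - seq_len(d$I))
    alpha <- alpha + a_adj - mean(a_adj)
    b_adj <- slope * seq_len(d$J)
    beta <- beta + b_adj - mean(b_adj)
  }
  list(mu = mu0, alpha = alpha, beta = beta, gamma = gamma)
}

#' Fit a Bayesian APC model by MCMC
#'
#' Draws posterior samples of the Poisson APC model defined by `spec` on the
#' counts in `table`, using a Metropolis-within-Gibbs sampler. Each retained
#' draw satisfies the sum-to-zero constraints exactly (effect means are
#' absorbed into the intercept after every sweep). Identical seed, config
#' and inputs give identical draws.
#'
#' For the full age-period-cohort model with RW2 priors on every effect the
#' posterior is constant along the Lexis null-space direction (a linear
#' trend in the cohort effect exactly traded against linear trends in age
#' and period), so the sampler additionally selects the representative with
#' zero linear trend in the cohort effect after every sweep, folding the
#' trend into the age and period effects; the linear predictor and all RW2
#' roughness penalties are unchanged by this. Reported cohort effects are
#' therefore curvature-only, the common identification convention that
#' attributes drift to the period effect.
#'
#' @param table An [apc_table()].
#' @param spec An [apc_model_spec()].
#' @param config An [mcmc_config()].
#' @return An `apc_fit` with elements `draws` (list of matrices: `mu`,
#'   `alpha`, `beta`, `gamma`, `z`, `tau`, `loglik`, `chain`), `acceptance`
#'   (tibble per block and chain), `spec`, `config`, `table`.
#' @seealso [summarize_effects()], [compute_dic()], [project_rates()]
#' @export
fit_apc <- function(table, spec = apc_model_spec(), config = mcmc_config()) {
  stopifnot(inherits(table, "apc_table"), inherits(spec, "apc_model_spec"))
  if ("cohort" %in% spec$effects) require_cohorts(table)
  m <- table_matrices(table)
  d <- apc_dims(table)
  has_beta <- "period" %in% spec$effects
  has_gamma <- "cohort" %in% spec$effects
  init <- init_effects(table, spec)

  # sanity: the initial state must have a finite posterior density
  init_params <- apc_params(
    mu = init$mu, alpha = init$alpha,
    beta = if (has_beta) init$beta else NULL,
    gamma = if (has_gamma) init$gamma else NULL,
    z = if (spec$overdispersion) matrix(0, d$I, d$J) else NULL
  )
  lp0 <- log_posterior(init_params, table, spec)
  if (!is.finite(lp0)) {
    abort("non-finite log-posterior at initialization; re-initialize with different starting values or check the table for impossible cells.")
  }

  kid <- m$k
  kid[is.na(kid)] <- 1L
  n_keep <- (config$n_iter - config$burnin) %/% config$thin
  chains <- vector("list", config$chains)
  set.seed(config$seed)
  for (ch in seq_len(config$chains)) {
    chains[[ch]] <- apc_mcmc_cpp(
      y = m$y, n = m$n, kidx = kid,
      has_beta = has_beta, has_gamma = has_gamma, has_z = spec$overdispersion,
      K = if (has_gamma) d$K else 0L,
      ord_a = spec$rw_order[["age"]],
      ord_b = if (has_beta) spec$rw_order[["period"]] else 1L,
      ord_g = if (has_gamma) spec$rw_order[["cohort"]] else 1L,
      eff_shape = spec$effect_hyperprior[["shape"]],
      eff_rate = spec$effect_hyperprior[["rate"]],
      od_shape = spec$od_hyperprior[["shape"]],
      od_rate = spec$od_hyperprior[["rate"]],
      n_iter = config$n_iter, burnin = config$burnin, thin = config$thin,
      constrain_gamma_lin = has_gamma && has_beta && all(spec$rw_order == 2),
      mu0 = init$mu, alpha0 = init$alpha, beta0 = init$beta, gamma0 = init$gamma,
      scales0 = unname(config$proposal_scales)
    )
  }

  bind <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  cat_v <- function(name) do.call(c, lapply(chains, `[[`, name))
  draws <- list(
    mu = cat_v("mu"),
    alpha = bind("alpha"),
    beta = if (has_beta) bind("beta") else NULL,
    gamma = if (has_gamma) bind("gamma") else NULL,
    z = if (spec$overdispersion) bind("z") else NULL,
    tau = bind("tau"),
    loglik = cat_v("loglik"),
    chain = rep(seq_len(config$chains), each = n_keep)
  )
  colnames(draws$tau) <- c("tau_alpha", "tau_beta", "tau_gamma", "tau_z")
  acceptance <- purrr::imap_dfr(chains, function(res, ch) {
    tibble::tibble(
      chain = ch,
      block = c("mu", "age", "period", "cohort", "od"),
      acceptance_rate = as.numeric(res$acceptance),
      attempts = as.numeric(res$attempts)
    )
  }) |>
    dplyr::filter(.data$attempts > 0)

  structure(
    list(
      draws = draws, acceptance = acceptance, spec = spec,
      config = config, table = table, n_draws = n_keep * config$chains
    ),
    class = "apc_fit"
  )
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf(
    "<apc_fit> %s on stratum '%s': %d draws (%d chain(s) x %d kept)\n",
    x$spec$label, x$table$stratum[1], x$n_draws,
    x$config$chains, x$n_draws / x$config$chains
  ))
  print(glance(x))
  invisible(x)
}

#' Extract one posterior draw as an apc_params
#'
#' @param fit An `apc_fit`.
#' @param draw Draw index.
#' @return An [apc_params()].
#' @export
posterior_params <- function(fit, draw) {
  stopifnot(inherits(fit, "apc_fit"), draw >= 1, draw <= fit$n_draws)
  d <- apc_dims(fit$table)
  g <- fit$draws
  apc_params(
    mu = g$mu[draw],
    alpha = g$alpha[draw, ] - mean(g$alpha[draw, ]),
    beta = if (!is.null(g$beta)) g$beta[draw, ] - mean(g$beta[draw, ]) else NULL,
    gamma = if (!is.null(g$gamma)) g$gamma[draw, ] - mean(g$gamma[draw, ]) else NULL,
    z = if (!is.null(g$z)) matrix(g$z[draw, ], d$I, d$J) else NULL,
    tau_alpha = g$tau[draw, "tau_alpha"], tau_beta = g$tau[draw, "tau_beta"],
    tau_gamma = g$tau[draw, "tau_gamma"], tau_z = g$tau[draw, "tau_z"]
  )
}

# posterior mean of all structural parameters (plug-in for DIC)
posterior_mean_params <- function(fit) {
  d <- apc_dims(fit$table)
  g <- fit$draws
  ctr <- function(v) v - mean(v)
  apc_params(
    mu = mean(g$mu),
    alpha = ctr(colMeans(g$alpha)),
    beta = if (!is.null(g$beta)) ctr(colMeans(g$beta)) else NULL,
    gamma = if (!is.null(g$gamma)) ctr(colMeans(g$gamma)) else NULL,
    z = if (!is.null(g$z)) matrix(colMeans(g$z), d$I, d$J) else NULL,
    tau_alpha = mean(g$tau[, "tau_alpha"]), tau_beta = mean(g$tau[, "tau_beta"]),
    tau_gamma = mean(g$tau[, "tau_gamma"]), tau_z = mean(g$tau[, "tau_z"])
  )
}

#' Deviance Information Criterion of a fitted APC model
#'
#' `DIC = mean_deviance + pD` with deviance `D = -2 * poisson_loglik`,
#' `pD = mean_deviance - D(posterior mean of the parameters)`. `pD` is
#' reported as computed, even if negative.
#'
#' @param fit An `apc_fit`.
#' @param table Count table; defaults to the one the model was fitted on.
#' @return Tibble with columns `DIC`, `pD`, `mean_deviance`.
#' @export
compute_dic <- function(fit, table = NULL) {
  stopifnot(inherits(fit, "apc_fit"))
  if (is.null(table)) table <- fit$table
  if (fit$n_draws < 1) abort("no posterior draws available.")
  dev_draws <- -2 * fit$draws$loglik
  mean_dev <- mean(dev_draws)
  d_hat <- -2 * poisson_loglik(table, posterior_mean_params(fit))
  pd <- mean_dev - d_hat
  tibble::tibble(DIC = mean_dev + pd, pD = pd, mean_deviance = mean_dev)
}

#' Posterior effect summaries on log and rate-ratio scales
#'
#' Per level of each included effect: posterior mean, median and a central
#' credible interval, on the log scale and as rate ratios
#' (`RR = exp(effect)`, exponentiated per draw before summarising). By
#' sum-to-zero, the product of RRs across the levels of one effect equals 1
#' in every draw; `RR > 1` marks a level as a risk factor relative to the
#' constrained mean, `RR < 1` as protective.
#'
#' @param fit An `apc_fit`.
#' @param level Credible level of the central interval (default 0.95).
#' @return Tibble: `effect`, `level`, `label`, `mean_log`, `median_log`,
#'   `lower_log`, `upper_log`, `mean_RR`, `median_RR`, `lower_RR`,
#'   `upper_RR`.
#' @export
summarize_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "apc_fit"), level > 0, level < 1)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  tab <- fit$table
  labels <- list(
    age = observed_rates(tab, "age")$label,
    period = observed_rates(tab, "period")$label,
    cohort = if ("cohort" %in% fit$spec$effects) observed_rates(tab, "cohort")$label else NULL
  )
  mats <- list(age = fit$draws$alpha, period = fit$draws$beta, cohort = fit$draws$gamma)
  purrr::map_dfr(fit$spec$effects, function(eff) {
    m <- mats[[eff]]
    purrr::map_dfr(seq_len(ncol(m)), function(l) {
      x <- m[, l]
      qs <- quantile(x, pr, names = FALSE)
      rr <- exp(x)
      qr <- quantile(rr, pr, names = FALSE)
      tibble::tibble(
        effect = eff, level = l, label = labels[[eff]][l],
        mean_log = mean(x), median_log = median(x),
        lower_log = qs[1], upper_log = qs[2],
        mean_RR = mean(rr), median_RR = median(rr),
        lower_RR = qr[1], upper_RR = qr[2]
      )
    })
  })
}

#' @export
tidy.apc_fit <- function(x, level = 0.95, ...) {
  summarize_effects(x, level = level)
}

#' @export
glance.apc_fit <- function(x, ...) {
  dic <- compute_dic(x)
  tibble::tibble(
    model = x$spec$label,
    DIC = dic$DIC, pD = dic$pD, mean_deviance = dic$mean_deviance,
    n_draws = x$n_draws, chains = x$config$chains,
    rhat_mu = split_rhat(x$draws$mu, x$draws$chain),
    min_acceptance = min(x$acceptance$acceptance_rate),
    max_acceptance = max(x$acceptance$acceptance_rate)
  )
}

#' Split-chain potential scale reduction factor
#'
#' Split-R-hat convergence diagnostic: each chain is split in half and the
#' usual between/within variance ratio computed over the resulting
#' half-chains. Values near 1 (conventionally below 1.05) indicate mixing.
#'
#' @param x Numeric draw vector.
#' @param chain Integer chain index per draw.
#' @return Scalar R-hat (NA if fewer than 2 draws per half-chain).
#' @export
split_rhat <- function(x, chain = rep(1L, length(x))) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    if (h < 2) return(list())
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  if (length(halves) < 2) return(NA_real_)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit candidate APC models and select by DIC
#'
#' Fits each candidate specification and returns the one with the lowest
#' DIC (lower is better). When a full age-period-cohort candidate with RW2
#' priors on all effects comes within `near_tie_threshold` of the minimum,
#' it is selected instead: with near-tied DICs the complete model with RW2
#' priors is the standard smoothing target.
#'
#' @param table An [apc_table()].
#' @param candidates List of [apc_model_spec()]s (at least 2, or 1 which is
#'   returned as-is after fitting).
#' @param config An [mcmc_config()].
#' @param near_tie_threshold DIC margin treated as "very similar" (default 2).
#' @return List with `spec` (chosen), `fit` (its apc_fit), `dic_table`
#'   (tibble `spec_id, effects, rw_order, DIC, pD, mean_deviance, selected`),
#'   and `fits` (all successful fits, named by label).
#' @export
select_model <- function(table, candidates, config = mcmc_config(),
                         near_tie_threshold = 2) {
  if (length(candidates) < 1) abort("`candidates` must contain at least one model specification.")
  labels <- vapply(candidates, function(s) s$label, "")
  if (anyDuplicated(labels)) abort("candidate labels must be unique.")
  fits <- setNames(vector("list", length(candidates)), labels)
  rows <- purrr::imap_dfr(candidates, function(spec, idx) {
    res <- tryCatch(fit_apc(table, spec, config), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("candidate '%s' failed to fit (%s); excluded from selection.", spec$label, conditionMessage(res)))
      return(tibble::tibble(
        spec_id = spec$label, effects = paste(spec$effects, collapse = "+"),
        rw_order = paste(spec$rw_order, collapse = ""),
        DIC = NA_real_, pD = NA_real_, mean_deviance = NA_real_, ok = FALSE
      ))
    }
    fits[[spec$label]] <<- res
    dic <- compute_dic(res)
    tibble::tibble(
      spec_id = spec$label, effects = paste(spec$effects, collapse = "+"),
      rw_order = paste(spec$rw_order, collapse = ""),
      DIC = dic$DIC, pD = dic$pD, mean_deviance = dic$mean_deviance, ok = TRUE
    )
  })
  if (!any(rows$ok)) abort("all candidate fits failed; nothing to select.")
  dic_min <- min(rows$DIC[rows$ok])
  is_full_rw2 <- vapply(candidates, function(s) {
    setequal(s$effects, c("age", "period", "cohort")) && all(s$rw_order == 2)
  }, TRUE)
  chosen_id <- rows$spec_id[rows$ok][which.min(rows$DIC[rows$ok])]
  tie <- rows$ok & is_full_rw2 & (rows$DIC - dic_min < near_tie_threshold)
  if (any(tie)) chosen_id <- rows$spec_id[tie][which.min(rows$DIC[tie])]
  rows$selected <- rows$spec_id == chosen_id
  list(
    spec = candidates[[match(chosen_id, labels)]],
    fit = fits[[chosen_id]],
    dic_table = rows,
    fits = fits[!vapply(fits, is.null, TRUE)]
  )
}

#' Rate-ratio effect plot
#'
#' Posterior median RR per level with the credible band, one panel per
#' effect, horizontal reference line at RR = 1.
#'
#' @param object An `apc_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apc_fit <- function(object, level = 0.95, ...) {
  s <- summarize_effects(object, level = level)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$level, y = .data$median_RR)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower_RR, ymax = .data$upper_RR),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey20") +
    ggplot2::facet_wrap(~effect, scales = "free_x") +
    ggplot2::labs(x = "level index", y = "rate ratio") +
    ggplot2::theme_minimal()
}

#' Write posterior effect summaries / DIC tables to CSV
#'
#' @param summaries Output of [summarize_effects()].
#' @param path Output path.
#' @export
write_effects_csv <- function(summaries, path) {
  summaries |>
    dplyr::transmute(
      effect = .data$effect, level_label = .data$label,
      mean_log = .data$mean_log, median_log = .data$median_log,
      lower_log = .data$lower_log, upper_log = .data$upper_log,
      mean_RR = .data$mean_RR, median_RR = .data$median_RR,
      lower_RR = .data$lower_RR, upper_RR = .data$upper_RR
    ) |>
    readr::write_csv(path)
  invisible(path)
}
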