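#' Specify a Bayesian APC model
#'
#' Defines which temporal effects enter the log-linear Poisson rate model
#' `log(lambda_ijk) = mu + alpha_i + beta_j + gamma_k (+ z_ij)`, the order of
#' the random-walk smoothing prior on each effect, and the Gamma hyperpriors
#' on the precisions. The age effect is always included; dropping the cohort
#' effect gives an age-period (AP) model, dropping the period effect an
#' age-cohort (AC) model.
#'
#' Each included effect `u` gets an intrinsic random-walk prior of order 1 or
#' 2 — a Gaussian kernel penalising squared first (RW1) or second (RW2)
#' differences — with precision `tau_u` given a highly non-informative
#' Gamma(shape = 1, rate = 0.00005) hyperprior. Identifiability is imposed by
#' sum-to-zero constraints on every effect vector. The optional
#' overdispersion term `z_ij` is an iid Gaussian cell effect with precision
#' `tau_z ~ Gamma(1, 0.005)`.
#'
#' @param effects Character subset of `c("age", "period", "cohort")`; must
#'   contain `"age"` and at least one other effect.
#' @param rw_order Named integer vector (1 or 2) giving the random-walk order
#'   per included effect; unnamed scalar recycles to all effects.
#' @param overdispersion Include the iid Gaussian cell effect?
#' @param effect_hyperprior,od_hyperprior Length-2 numeric `(shape, rate)` of
#'   the Gamma hyperprior on effect / overdispersion precisions.
#' @param label Optional identifier used in DIC tables.
#' @return An object of class `apc_model_spec`.
#' @examples
#' apc_model_spec()                                  # full APC, RW2, overdispersion
#' apc_model_spec(c("age", "period"), rw_order = 1)  # AP model with RW1 priors
#' @export
apc_model_spec <- function(effects = c("age", "period", "cohort"),
                           rw_order = 2L,
                           overdispersion = TRUE,
                           effect_hyperprior = c(shape = 1, rate = 0.00005),
                           od_hyperprior = c(shape = 1, rate = 0.005),
                           label = NULL) {
  effects <- match.arg(effects, c("age", "period", "cohort"), several.ok = TRUE)
  if (!"age" %in% effects) abort("the age effect must always be included.")
  if (length(effects) < 2) abort("at least two effects must be included (AP, AC or full APC).")
  if (is.null(names(rw_order))) {
    rw_order <- setNames(rep(as.integer(rw_order), length(effects)), effects)
  } else {
    rw_order <- setNames(as.integer(rw_order[effects]), effects)
  }
  if (any(is.na(rw_order)) || !all(rw_order %in% 1:2)) {
    abort("`rw_order` must give 1 or 2 for every included effect.")
  }
  if (any(effect_hyperprior <= 0) || any(od_hyperprior <= 0)) {
    abort("hyperprior shapes and rates must be positive.")
  }
  if (is.null(label)) {
    label <- paste0(
      paste(substr(effects, 1, 1), collapse = ""),
      "-rw", paste(rw_order, collapse = ""),
      if (overdispersion) "-od" else ""
    )
  }
  structure(
    list(
      effects = effects,
      rw_order = rw_order,
      overdispersion = isTRUE(overdispersion),
      effect_hyperprior = c(shape = unname(effect_hyperprior[1]), rate = unname(effect_hyperprior[2])),
      od_hyperprior = c(shape = unname(od_hyperprior[1]), rate = unname(od_hyperprior[2])),
      label = label
    ),
    class = "apc_model_spec"
  )
}

#' @export
print.apc_model_spec <- function(x, ...) {
  cat(sprintf(
    "<apc_model_spec> %s | effects: %s | RW orders: %s | overdispersion: %s\n",
    x$label, paste(x$effects, collapse = "+"),
    paste(paste0(names(x$rw_order), "=", x$rw_order), collapse = ", "),
    x$overdispersion
  ))
  invisible(x)
}

#' Serialise / deserialise a model specification
#'
#' Key-value YAML with fields `effects`, `rw_order`, `overdispersion`,
#' hyperprior shapes and rates, and `label`.
#'
#' @param spec An [apc_model_spec()].
#' @param path File path.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "apc_model_spec"))
  yaml::write_yaml(list(
    effects = spec$effects,
    rw_order = as.list(spec$rw_order),
    overdispersion = spec$overdispersion,
    effect_hyperprior = as.list(spec$effect_hyperprior),
    od_hyperprior = as.list(spec$od_hyperprior),
    label = spec$label
  ), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  apc_model_spec(
    effects = unlist(x$effects),
    rw_order = unlist(x$rw_order),
    overdispersion = x$overdispersion,
    effect_hyperprior = unlist(x$effect_hyperprior),
    od_hyperprior = unlist(x$od_hyperprior),
    label = x$label
  )
}

#' Random-walk roughness penalty
#'
#' Quadratic form of the intrinsic random-walk prior: the sum of squared
#' first differences (order 1) or second differences (order 2) of an ordered
#' effect vector. It is zero for constant vectors (both orders) and for
#' linear sequences (order 2), reflecting the null space of each penalty.
#'
#' @param u Numeric effect vector.
#' @param order 1 (RW1) or 2 (RW2).
#' @return Non-negative scalar.
#' @examples
#' rw_quadratic_form(c(0, 1, 3), order = 1)     # 1^2 + 2^2 = 5
#' rw_quadratic_form(c(0, 1, 2, 3), order = 2)  # 0: linear null space
#' @export
rw_quadratic_form <- function(u, order = 1L) {
  if (!order %in% 1:2) abort("`order` must be 1 or 2.")
  if (length(u) < order + 1) {
    abort(sprintf("effect vector too short: a random walk of order %d needs length >= %d.", order, order + 1))
  }
  sum(diff(u, differences = order)^2)
}

#' One parameter realisation of the APC model
#'
#' Bundles the intercept, effect vectors, optional overdispersion matrix and
#' precisions, enforcing the sum-to-zero identifiability constraints
#' (`mean(alpha) = mean(beta) = mean(gamma) = 0` within 1e-10).
#'
#' @param mu Intercept (general log-rate level).
#' @param alpha Age effects, length I, mean zero.
#' @param beta Period effects, length J, mean zero, or `NULL` (AC model).
#' @param gamma Cohort effects, length K, mean zero, or `NULL` (AP model).
#' @param z Optional I x J overdispersion matrix.
#' @param tau_alpha,tau_beta,tau_gamma,tau_z Positive precisions.
#' @return An object of class `apc_params`.
#' @export
apc_params <- function(mu, alpha, beta = NULL, gamma = NULL, z = NULL,
                       tau_alpha = 1, tau_beta = 1, tau_gamma = 1, tau_z = 1) {
  for (nm in c("alpha", "beta", "gamma")) {
    u <- get(nm)
    if (!is.null(u) && abs(mean(u)) > 1e-10) {
      abort(sprintf("`%s` violates the sum-to-zero constraint (|mean| = %.3g > 1e-10).", nm, abs(mean(u))))
    }
  }
  taus <- c(tau_alpha = tau_alpha, tau_beta = tau_beta, tau_gamma = tau_gamma, tau_z = tau_z)
  if (any(!is.finite(taus) & !is.infinite(taus)) || any(taus <= 0)) {
    abort("precisions must be strictly positive.")
  }
  structure(
    list(
      mu = mu, alpha = alpha, beta = beta, gamma = gamma, z = z,
      tau_alpha = tau_alpha, tau_beta = tau_beta,
      tau_gamma = tau_gamma, tau_z = tau_z
    ),
    class = "apc_params"
  )
}

#' Cell-wise linear predictor
#'
#' `log(lambda_ij) = mu + alpha_i + beta_j + gamma_k (+ z_ij)` with the
#' cohort index `k` derived from `(i, j)` via [cohort_index()]. Effects set
#' to `NULL` in `params` contribute zero.
#'
#' @param params An [apc_params()].
#' @param i,j Age and period indices (vectorised, recycled).
#' @param table The [apc_table()] providing grid dimensions.
#' @return Numeric vector of log-rates.
#' @export
linear_predictor <- function(params, i, j, table) {
  d <- apc_dims(table)
  if (any(i < 1 | i > d$I)) abort(sprintf("age index out of range: 1 <= i <= I = %d.", d$I))
  if (any(j < 1 | j > d$J)) abort(sprintf("period index out of range: 1 <= j <= J = %d.", d$J))
  gamma_term <- if (is.null(params$gamma)) {
    0
  } else {
    require_cohorts(table)
    params$gamma[cohort_index(i, j, I = d$I, M = d$M)]
  }
  eta <- params$mu +
    params$alpha[i] +
    (if (is.null(params$beta)) 0 else params$beta[j]) +
    gamma_term
  if (!is.null(params$z)) eta <- eta + params$z[cbind(i, j)]
  unname(eta)
}

# internal: full I x J matrix of linear predictors
linear_predictor_matrix <- function(params, table) {
  d <- apc_dims(table)
  ij <- expand.grid(i = seq_len(d$I), j = seq_len(d$J))
  matrix(linear_predictor(params, ij$i, ij$j, table), d$I, d$J)
}

#' Poisson log-likelihood of an APC table
#'
#' `sum over cells of y * log(n * lambda) - n * lambda - log(y!)`, with
#' `lambda = exp(linear_predictor)`. Cells with `n = 0, y = 0` contribute
#' zero; `n = 0` with `y > 0` is impossible and raises an error.
#'
#' @param table An [apc_table()].
#' @param params An [apc_params()] dimensioned for `table`.
#' @return Finite scalar log-likelihood.
#' @export
poisson_loglik <- function(table, params) {
  m <- table_matrices(table)
  if (any(m$n == 0 & m$y > 0)) {
    abort("impossible cell: events recorded (y > 0) where no subjects were at risk (n = 0).")
  }
  eta <- linear_predictor_matrix(params, table)
  mu_cell <- m$n * exp(eta)
  keep <- m$n > 0
  sum(m$y[keep] * log(mu_cell[keep]) - mu_cell[keep] - lgamma(m$y[keep] + 1))
}

#' Log-prior density of the APC model
#'
#' Sum, over the effects included in `spec`, of the intrinsic random-walk
#' Gaussian kernel `(r/2) * log(tau / 2*pi) - (tau/2) * q(u)` with rank
#' r = `length(u) - order`, plus the Gamma hyperprior log-density on each
#' precision; plus, when overdispersion is enabled, the iid Gaussian density
#' of `z` under precision `tau_z` and its Gamma hyperprior. The intercept
#' carries a flat prior. Normalising constants are retained throughout so
#' deviance summaries are comparable across specifications.
#'
#' @param params An [apc_params()] satisfying the sum-to-zero invariants.
#' @param spec An [apc_model_spec()].
#' @return Scalar log-prior density.
#' @export
log_prior <- function(params, spec) {
  stopifnot(inherits(params, "apc_params"), inherits(spec, "apc_model_spec"))
  sh <- spec$effect_hyperprior[["shape"]]
  ra <- spec$effect_hyperprior[["rate"]]
  vecs <- list(age = params$alpha, period = params$beta, cohort = params$gamma)
  taus <- list(age = params$tau_alpha, period = params$tau_beta, cohort = params$tau_gamma)
  lp <- 0
  for (eff in spec$effects) {
    u <- vecs[[eff]]
    tau <- taus[[eff]]
    if (is.null(u)) abort(sprintf("spec includes the %s effect but params has none.", eff))
    if (tau <= 0) abort("precisions must be strictly positive.")
    d <- spec$rw_order[[eff]]
    r <- length(u) - d
    lp <- lp + (r / 2) * (log(tau) - log(2 * pi)) -
      (tau / 2) * rw_quadratic_form(u, d) +
      stats::dgamma(tau, shape = sh, rate = ra, log = TRUE)
  }
  if (spec$overdispersion) {
    if (is.null(params$z)) abort("spec enables overdispersion but params has no z.")
    if (params$tau_z <= 0) abort("precisions must be strictly positive.")
    lp <- lp + sum(stats::dnorm(params$z, 0, 1 / sqrt(params$tau_z), log = TRUE)) +
      stats::dgamma(params$tau_z,
        shape = spec$od_hyperprior[["shape"]],
        rate = spec$od_hyperprior[["rate"]], log = TRUE
      )
  }
  lp
}

#' Log-posterior density (unnormalised)
#'
#' [poisson_loglik()] plus [log_prior()], up to a constant not depending on
#' the parameters.
#'
#' @inheritParams poisson_loglik
#' @param spec An [apc_model_spec()].
#' @return Scalar log-posterior density.
#' @export
log_posterior <- function(params, table, spec) {
  poisson_loglik(table, params) + log_prior(params, spec)
}
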