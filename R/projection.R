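#' Extend random-walk effect draws beyond the observed range
#'
#' Per posterior draw, continues an effect vector `H` steps forward from its
#' predictive distribution: for RW1, `u[m+h] ~ N(u[m+h-1], 1/tau)`; for RW2,
#' `u[m+h] ~ N(2 u[m+h-1] - u[m+h-2], 1/tau)`. In the infinite-precision
#' limit RW1 continues the last value constantly and RW2 continues the last
#' slope exactly linearly. The extended portion is NOT re-centred: the
#' sum-to-zero constraint applies to the observed range only.
#'
#' @param u_draws Matrix of effect draws (draws x levels), or a single
#'   vector.
#' @param tau_draws Precision draw per row of `u_draws` (recycled if scalar);
#'   `Inf` gives the deterministic limit.
#' @param order Random-walk order, 1 or 2.
#' @param horizon Number of forward steps `H >= 0`; 0 returns the input.
#' @return Matrix (draws x (levels + H)).
#' @export
extend_random_walk <- function(u_draws, tau_draws, order = 2L, horizon = 1L) {
  if (is.vector(u_draws)) u_draws <- matrix(u_draws, nrow = 1)
  if (!order %in% 1:2) abort("`order` must be 1 or 2.")
  if (horizon < 0) abort("`horizon` must be >= 0.")
  if (horizon == 0) return(u_draws)
  m <- ncol(u_draws)
  if (m < order) {
    abort(sprintf("effect draws too short: a random walk of order %d needs length >= %d.", order, order))
  }
  S <- nrow(u_draws)
  tau_draws <- rep_len(tau_draws, S)
  if (any(tau_draws <= 0)) abort("precisions must be strictly positive.")
  sd <- 1 / sqrt(tau_draws) # Inf precision -> sd 0, deterministic continuation
  out <- cbind(u_draws, matrix(0, S, horizon))
  for (h in seq_len(horizon)) {
    t <- m + h
    mean_h <- if (order == 1) out[, t - 1] else 2 * out[, t - 1] - out[, t - 2]
    out[, t] <- rnorm(S, mean_h, sd)
  }
  out
}

#' Project rates forward with nested credible bands
#'
#' Extrapolates the fitted period effect `H` periods ahead (and the cohort
#' effect along the new diagonals entering the Lexis grid) through the
#' random-walk predictive distribution of each posterior draw, converts the
#' linear predictor of every (age group, future period) cell to a rate, and
#' summarises the predictive draws into a mean, a median, and central
#' credible bands at the requested levels. "10%" denotes the narrow central
#' 10% band around the predictive median, "95%" the widest band. At-risk
#' counts are carried forward from the last observed period by default.
#'
#' @param fit An [fit_apc()] result.
#' @param horizon Number of future periods `H >= 1` (default 2: a 10-year
#'   projection for five-year periods).
#' @param levels Credible-band levels in percent, e.g. `c(10, 25, 50, 75, 95)`.
#' @param at_risk_policy `"carry_forward"` (last observed period's `n` per age
#'   group) or `"supplied"` with `future_n`.
#' @param future_n Optional I x H matrix of future at-risk counts (rows =
#'   age groups), used when `at_risk_policy = "supplied"`.
#' @param include_overdispersion Integrate fresh overdispersion draws
#'   `z ~ N(0, 1/tau_z)` into future cells (default), or project the
#'   structural rate only.
#' @return An `apc_projection` tibble, one row per band level per cell:
#'   `stratum, age_start, age_end, period_start, period_end, n_at_risk,
#'   mean, median, level, lower, upper`.
#' @export
project_rates <- function(fit, horizon = 2L,
                          levels = c(10, 25, 50, 75, 95),
                          at_risk_policy = c("carry_forward", "supplied"),
                          future_n = NULL,
                          include_overdispersion = TRUE) {
  stopifnot(inherits(fit, "apc_fit"), horizon >= 1)
  at_risk_policy <- match.arg(at_risk_policy)
  levels <- sort(unique(levels))
  if (any(levels <= 0 | levels >= 100)) abort("band levels must lie strictly between 0 and 100 percent.")
  S <- fit$n_draws
  min_S <- ceiling(2 / (1 - max(levels) / 100))
  if (S < min_S) {
    abort(sprintf(
      "too few posterior draws (%d) to resolve a %g%% band: at least %d draws are required.",
      S, max(levels), min_S
    ))
  }
  table <- fit$table
  d <- apc_dims(table)
  require_cohorts(table)
  g <- fit$draws

  beta_ext <- if (!is.null(g$beta)) {
    extend_random_walk(g$beta, g$tau[, "tau_beta"],
      order = fit$spec$rw_order[["period"]], horizon = horizon
    )
  } else {
    NULL
  }
  gamma_ext <- if (!is.null(g$gamma)) {
    # new diagonals enter from the youngest age: max k grows by `horizon`
    extend_random_walk(g$gamma, g$tau[, "tau_gamma"],
      order = fit$spec$rw_order[["cohort"]], horizon = horizon
    )
  } else {
    NULL
  }

  last <- table |> dplyr::filter(.data$period_index == d$J)
  n_last <- last$n[order(last$age_index)]
  pw <- d$period_width
  last_start <- max(table$period_start)

  if (at_risk_policy == "supplied") {
    if (is.null(future_n) || !all(dim(future_n) == c(d$I, horizon))) {
      abort(sprintf("`future_n` must be an %d x %d matrix when at_risk_policy = 'supplied'.", d$I, horizon))
    }
  }

  probs_lo <- 0.5 - levels / 200
  probs_hi <- 0.5 + levels / 200
  ages <- table |>
    dplyr::distinct(.data$age_index, .data$age_start, .data$age_end) |>
    dplyr::arrange(.data$age_index)

  cells <- tidyr::expand_grid(i = seq_len(d$I), h = seq_len(horizon))
  rows <- purrr::pmap_dfr(cells, function(i, h) {
    jf <- d$J + h
    k <- d$M * (d$I - i) + jf
    eta <- g$mu + g$alpha[, i]
    if (!is.null(beta_ext)) eta <- eta + beta_ext[, jf]
    if (!is.null(gamma_ext)) eta <- eta + gamma_ext[, k]
    if (include_overdispersion && !is.null(g$z)) {
      eta <- eta + rnorm(S, 0, 1 / sqrt(g$tau[, "tau_z"]))
    }
    rate <- exp(eta)
    lo <- quantile(rate, probs_lo, names = FALSE)
    hi <- quantile(rate, probs_hi, names = FALSE)
    tibble::tibble(
      stratum = table$stratum[1],
      age_start = ages$age_start[i], age_end = ages$age_end[i],
      period_start = last_start + pw * h,
      period_end = last_start + pw * h + pw - 1,
      n_at_risk = if (at_risk_policy == "carry_forward") n_last[i] else future_n[i, h],
      mean = mean(rate), median = median(rate),
      level = levels, lower = lo, upper = hi
    )
  })
  structure(rows,
    band_levels = levels, horizon = horizon,
    class = c("apc_projection", class(rows))
  )
}

#' Rate change over the projection horizon
#'
#' Difference between the projected rate at the final horizon and the
#' observed rate in a baseline period, per age group, in absolute rate
#' points and percentage points.
#'
#' @param projection An [project_rates()] result.
#' @param table The observed [apc_table()] the model was fitted on.
#' @param baseline_period Start year of the baseline period (default: last
#'   observed period).
#' @param measure `"median"` (default) or `"mean"` projected rate.
#' @return Tibble: `age_start, age_end, baseline_rate, projected_rate,
#'   delta, delta_pct_points`.
#' @export
projection_delta <- function(projection, table,
                             baseline_period = NULL, measure = c("median", "mean")) {
  measure <- match.arg(measure)
  stopifnot(inherits(table, "apc_table"))
  if (is.null(baseline_period)) baseline_period <- max(table$period_start)
  if (!baseline_period %in% table$period_start) {
    abort(sprintf("baseline period starting %s not present in the observed table.", baseline_period))
  }
  base <- tibble::as_tibble(as.data.frame(table)) |>
    dplyr::filter(.data$period_start == baseline_period) |>
    dplyr::transmute(.data$age_start, .data$age_end, baseline_rate = .data$y / .data$n)
  proj <- projection |>
    dplyr::filter(.data$period_start == max(.data$period_start)) |>
    dplyr::distinct(.data$age_start, .data$age_end, projected_rate = .data[[measure]])
  dplyr::inner_join(base, proj, by = c("age_start", "age_end")) |>
    dplyr::mutate(
      delta = .data$projected_rate - .data$baseline_rate,
      delta_pct_points = 100 * .data$delta
    )
}

#' Fan chart of observed and projected rates
#'
#' One panel per age group: observed rates as points, predictive mean as a
#' line, nested shaded credible bands, and a dashed vertical line where
#' projection starts.
#'
#' @param object An `apc_projection`.
#' @param table The observed [apc_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apc_projection <- function(object, table, ...) {
  stopifnot(inherits(table, "apc_table"))
  obs <- table |>
    dplyr::transmute(
      age = paste0(.data$age_start, "-", .data$age_end),
      year = (.data$period_start + .data$period_end) / 2,
      rate = ifelse(.data$n > 0, .data$y / .data$n, NA_real_)
    )
  proj <- object |>
    dplyr::mutate(
      age = paste0(.data$age_start, "-", .data$age_end),
      year = (.data$period_start + .data$period_end) / 2
    )
  start_year <- max(table$period_end)
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$lower, ymax = .data$upper,
        group = factor(.data$level), alpha = factor(-.data$level)
      ),
      fill = "firebrick", show.legend = FALSE
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "firebrick") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$rate), size = 1) +
    ggplot2::geom_vline(xintercept = start_year, linetype = "dashed") +
    ggplot2::scale_alpha_discrete(range = c(0.15, 0.5)) +
    ggplot2::facet_wrap(~age) +
    ggplot2::labs(x = "year", y = "rate") +
    ggplot2::theme_minimal()
}

#' Write a projection to CSV
#'
#' Columns `stratum, age_start, age_end, period_start, period_end,
#' n_at_risk, mean, median, level, lower, upper`, one row per band level per
#' cell.
#'
#' @param projection An [project_rates()] result.
#' @param path Output path.
#' @export
write_projection_csv <- function(projection, path) {
  readr::write_csv(tibble::as_tibble(projection), path)
  invisible(path)
}
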