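#' Construct a generative APC truth
#'
#' A truth bundles the generative parameters of the Poisson APC model —
#' intercept, sum-to-zero effect vectors, overdispersion standard deviation
#' and the at-risk pattern — from which [generate_apc_table()] draws count
#' tables. All implied cell rates `lambda = exp(mu + alpha_i + beta_j +
#' gamma_k)` must lie in (0, 1) so counts remain interpretable as rates.
#'
#' @param mu Intercept (log rate level).
#' @param alpha,beta,gamma Effect vectors (length I, J, K = M*(I-1)+J); each
#'   is centred to mean zero.
#' @param n_pattern I x J matrix of at-risk counts, or length-I vector
#'   recycled across periods.
#' @param stratum Stratum label.
#' @param overdispersion_sd Standard deviation of the iid Gaussian cell
#'   effect added to the log rate (0 disables it).
#' @param age_starts,period_starts Interval start years (widths inferred
#'   from spacing; default five-year groups 31-100 and periods 1991-2015).
#' @return Object of class `apc_truth`.
#' @export
apc_truth <- function(mu, alpha, beta, gamma, n_pattern,
                      stratum = "all", overdispersion_sd = 0,
                      age_starts = seq(31, by = 5, length.out = length(alpha)),
                      period_starts = seq(1991, by = 5, length.out = length(beta))) {
  I <- length(alpha)
  J <- length(beta)
  aw <- if (I > 1) age_starts[2] - age_starts[1] else 5
  pw <- if (J > 1) period_starts[2] - period_starts[1] else 5
  M <- aw / pw
  if (!isTRUE(all.equal(M, round(M))) || M < 1) {
    abort("age width must be a positive integer multiple of the period width.")
  }
  M <- as.integer(round(M))
  K <- count_cohorts(I, J, M)
  if (length(gamma) != K) {
    abort(sprintf("`gamma` must have length K = M*(I-1)+J = %d.", K))
  }
  alpha <- alpha - mean(alpha)
  beta <- beta - mean(beta)
  gamma <- gamma - mean(gamma)
  if (is.vector(n_pattern)) n_pattern <- matrix(n_pattern, I, J)
  stopifnot(all(dim(n_pattern) == c(I, J)), all(n_pattern >= 0), overdispersion_sd >= 0)
  kmat <- outer(seq_len(I), seq_len(J), function(i, j) M * (I - i) + j)
  lambda <- exp(mu + outer(alpha, beta, "+") + matrix(gamma[kmat], I, J))
  if (any(lambda <= 0) || any(lambda >= 1)) {
    abort(sprintf(
      "implied cell rates must lie in (0, 1); got range [%.3f, %.3f].",
      min(lambda), max(lambda)
    ))
  }
  structure(
    list(
      mu = mu, alpha = alpha, beta = beta, gamma = gamma,
      n_pattern = n_pattern, stratum = stratum,
      overdispersion_sd = overdispersion_sd,
      age_starts = age_starts, period_starts = period_starts,
      age_width = aw, period_width = pw, I = I, J = J, K = K, M = M,
      lambda = lambda
    ),
    class = "apc_truth"
  )
}

#' Default generative truths emulating a harmonized multi-cohort pain survey
#'
#' Frozen truths for the canonical grid of 14 five-year age groups (31-35 …
#' 96-100) and 5 five-year periods (1991-1995 … 2011-2015), 18 cohort
#' diagonals, one per gender stratum. Their shape follows the descriptive
#' structure such surveys show for self-reported pain: a higher female than
#' male level, a mildly increasing age effect that plateaus at old ages, a
#' monotone increasing period effect on the log scale, and a concave
#' (parabolic) cohort effect peaking for mid-range birth cohorts, with cell
#' rates spanning roughly 0.3-0.55 and at-risk counts of 10^3-10^4 per cell
#' concentrated in the 51-70 age classes.
#'
#' @param stratum `"male"` or `"female"`.
#' @return An [apc_truth()].
#' @examples
#' tr <- default_truth("female")
#' range(tr$lambda)
#' @export
default_truth <- function(stratum = c("male", "female")) {
  stratum <- match.arg(stratum)
  I <- 14L; J <- 5L; K <- 18L
  # age: increasing up to the 81-85 group, flat thereafter
  alpha <- c(seq(-0.08, 0.08, length.out = 11), rep(0.08, 3))
  beta <- seq(-0.08, 0.08, length.out = J)
  # symmetric concave parabola across cohort diagonals, peak-to-trough 0.16
  gamma <- -(0.16 / 8.5^2) * (seq_len(K) - (K + 1) / 2)^2
  n_age <- if (stratum == "male") {
    c(rep(1000, 4), rep(9100, 4), rep(2800, 6))
  } else {
    c(rep(1875, 4), rep(11160, 4), rep(3850, 6))
  }
  apc_truth(
    mu = if (stratum == "male") log(0.375) else log(0.45),
    alpha = alpha, beta = beta, gamma = gamma,
    n_pattern = n_age, stratum = stratum, overdispersion_sd = 0.03
  )
}

#' Draw a synthetic count table from a truth
#'
#' Per cell: `z ~ N(0, overdispersion_sd^2)` (if enabled), `lambda = exp(mu
#' + alpha_i + beta_j + gamma_k + z)`, `y ~ Poisson(n * lambda)`. The
#' Poisson draw can exceed `n` with small probability; such cells are capped
#' at `y = n` to keep the table valid, and a message reports how many cells
#' were capped. Identical `(truth, seed)` give identical tables.
#'
#' @param truth An [apc_truth()].
#' @param seed Integer seed (sets the RNG).
#' @return A valid [apc_table()].
#' @export
generate_apc_table <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "apc_truth"))
  set.seed(seed)
  I <- truth$I; J <- truth$J
  z <- if (truth$overdispersion_sd > 0) {
    matrix(rnorm(I * J, 0, truth$overdispersion_sd), I, J)
  } else {
    matrix(0, I, J)
  }
  lambda <- truth$lambda * exp(z)
  mean_counts <- truth$n_pattern * lambda
  if (any(!is.finite(mean_counts)) || any(mean_counts > .Machine$integer.max / 2)) {
    abort("expected counts n * lambda overflow; use smaller effects or at-risk counts.")
  }
  y <- matrix(rpois(I * J, mean_counts), I, J)
  capped <- y > truth$n_pattern
  if (any(capped)) {
    message(sprintf("capped y at n in %d cell(s) where the Poisson draw exceeded the at-risk count.", sum(capped)))
    y[capped] <- truth$n_pattern[capped]
  }
  cells <- tidyr::expand_grid(i = seq_len(I), j = seq_len(J)) |>
    dplyr::mutate(
      age_start = truth$age_starts[.data$i],
      age_end = truth$age_starts[.data$i] + truth$age_width - 1,
      period_start = truth$period_starts[.data$j],
      period_end = truth$period_starts[.data$j] + truth$period_width - 1,
      n_at_risk = truth$n_pattern[cbind(.data$i, .data$j)],
      cases = y[cbind(.data$i, .data$j)]
    ) |>
    dplyr::select(-"i", -"j")
  apc_table(cells, stratum = truth$stratum)
}

# truth serialised as key-value sidecar, full precision
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(
    list(
      stratum = truth$stratum,
      mu = truth$mu, alpha = truth$alpha, beta = truth$beta, gamma = truth$gamma,
      overdispersion_sd = truth$overdispersion_sd,
      n_pattern = as.vector(truth$n_pattern),
      age_starts = truth$age_starts, period_starts = truth$period_starts
    ),
    path,
    precision = 15
  )
  invisible(path)
}

#' Read a truth manifest written by [make_fixture_suite()]
#'
#' @param path YAML sidecar path.
#' @return An [apc_truth()].
#' @export
read_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  apc_truth(
    mu = x$mu, alpha = unlist(x$alpha), beta = unlist(x$beta),
    gamma = unlist(x$gamma),
    n_pattern = matrix(unlist(x$n_pattern), length(x$alpha), length(x$beta)),
    stratum = x$stratum, overdispersion_sd = x$overdispersion_sd,
    age_starts = unlist(x$age_starts), period_starts = unlist(x$period_starts)
  )
}

# 4 x 3 grid used for fast end-to-end checks (K = 1*(4-1)+3 = 6)
debug_truth <- function() {
  apc_truth(
    mu = log(0.4),
    alpha = seq(-0.05, 0.05, length.out = 4),
    beta = seq(-0.04, 0.04, length.out = 3),
    gamma = -(0.08 / 2.5^2) * (seq_len(6) - 3.5)^2,
    n_pattern = rep(2000L, 4),
    stratum = "debug",
    overdispersion_sd = 0,
    age_starts = seq(51, by = 5, length.out = 4),
    period_starts = seq(2001, by = 5, length.out = 3)
  )
}

intercept_only_truth <- function() {
  apc_truth(
    mu = log(0.445),
    alpha = rep(0, 4), beta = rep(0, 3), gamma = rep(0, 6),
    n_pattern = rep(20000L, 4),
    stratum = "intercept_only",
    overdispersion_sd = 0,
    age_starts = seq(51, by = 5, length.out = 4),
    period_starts = seq(2001, by = 5, length.out = 3)
  )
}

#' Write the deterministic synthetic fixture suite
#'
#' Writes, with fixed internal seeds, CSV fixtures in the interchange
#' schema — the default male and female truths on the canonical 14 x 5
#' grid, a small 4 x 3 debug table, and an intercept-only table — each with
#' a YAML truth manifest sidecar, so recovery experiments never hard-code
#' true values. Running twice produces byte-identical files. All fixtures
#' are synthetic; filenames say so.
#'
#' @param out_dir Writable output directory (created if needed).
#' @return Tibble manifest: `name`, `table_csv`, `truth_yaml`, `seed`.
#' @export
make_fixture_suite <- function(out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory '%s'.", out_dir))
  fixtures <- list(
    male_synthetic = list(truth = default_truth("male"), seed = 101L),
    female_synthetic = list(truth = default_truth("female"), seed = 102L),
    debug_4x3_synthetic = list(truth = debug_truth(), seed = 103L),
    intercept_only_synthetic = list(truth = intercept_only_truth(), seed = 104L)
  )
  purrr::imap_dfr(fixtures, function(fx, name) {
    tab <- suppressMessages(generate_apc_table(fx$truth, seed = fx$seed))
    csv <- file.path(out_dir, paste0(name, ".csv"))
    yml <- file.path(out_dir, paste0(name, "_truth.yml"))
    write_apc_csv(tab, csv)
    write_truth_yaml(fx$truth, yml)
    tibble::tibble(name = name, table_csv = csv, truth_yaml = yml, seed = fx$seed)
  })
}
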