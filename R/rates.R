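#' Observed rates by age, period, cohort or overall
#'
#' Marginal event rates of an [apc_table()]: for every level of the requested
#' margin, the numerator is the sum of event counts and the denominator the
#' sum of at-risk counts over all cells mapping to that level (cohort levels
#' are the Lexis diagonals from [cohort_index()]). Rates are exact ratios,
#' stored at full precision; levels with an empty denominator get `NA`, never
#' zero.
#'
#' @param table An [apc_table()].
#' @param margin One of `"age"`, `"period"`, `"cohort"`, `"total"`.
#' @return Tibble with columns `margin`, `level`, `label`, `numerator`,
#'   `denominator`, `rate` (in `[0, 1]`).
#' @examples
#' tab <- apc_table(tibble::tibble(
#'   age_start = 31, age_end = 50, period_start = 1991, period_end = 2015,
#'   n_at_risk = 18287, cases = 6085
#' ), stratum = "male")
#' observed_rates(tab, "total") # 0.333 (33.3%)
#' @export
observed_rates <- function(table, margin = c("age", "period", "cohort", "total")) {
  stopifnot(inherits(table, "apc_table"))
  margin <- match.arg(margin)
  grouped <- switch(margin,
    total = table |>
      dplyr::summarise(numerator = sum(.data$y), denominator = sum(.data$n)) |>
      dplyr::mutate(level = 1L, label = "total"),
    age = table |>
      dplyr::group_by(
        level = .data$age_index,
        label = paste0(.data$age_start, "-", .data$age_end)
      ) |>
      dplyr::summarise(
        numerator = sum(.data$y), denominator = sum(.data$n), .groups = "drop"
      ),
    period = table |>
      dplyr::group_by(
        level = .data$period_index,
        label = paste0(.data$period_start, "-", .data$period_end)
      ) |>
      dplyr::summarise(
        numerator = sum(.data$y), denominator = sum(.data$n), .groups = "drop"
      ),
    cohort = {
      require_cohorts(table)
      table |>
        dplyr::group_by(
          level = .data$cohort_index,
          label = paste0(
            .data$period_start - .data$age_end, "-",
            .data$period_end - .data$age_start
          )
        ) |>
        dplyr::summarise(
          numerator = sum(.data$y), denominator = sum(.data$n), .groups = "drop"
        ) |>
        dplyr::group_by(.data$level) |>
        dplyr::summarise(
          label = paste0(
            min(as.integer(sub("-.*", "", .data$label))), "-",
            max(as.integer(sub(".*-", "", .data$label)))
          ),
          numerator = sum(.data$numerator),
          denominator = sum(.data$denominator),
          .groups = "drop"
        )
    }
  )
  grouped |>
    dplyr::arrange(.data$level) |>
    dplyr::transmute(
      margin = margin,
      level = as.integer(.data$level),
      label = .data$label,
      numerator = as.integer(.data$numerator),
      denominator = as.integer(.data$denominator),
      rate = ifelse(.data$denominator > 0, .data$numerator / .data$denominator, NA_real_)
    )
}

#' Observed-rate curves by margin
#'
#' Line plot of observed rates by age, period and cohort, one panel per
#' margin, optionally overlaying several strata.
#'
#' @param tables An [apc_table()] or a list of them (e.g. one per gender).
#' @param margins Margins to show.
#' @return A ggplot object.
#' @export
plot_observed_rates <- function(tables, margins = c("age", "period", "cohort")) {
  if (inherits(tables, "apc_table")) tables <- list(tables)
  dat <- purrr::map_dfr(tables, function(tab) {
    purrr::map_dfr(margins, function(m) {
      observed_rates(tab, m) |> dplyr::mutate(stratum = tab$stratum[1])
    })
  })
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$level, y = .data$rate,
    colour = .data$stratum, group = .data$stratum
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey30") +
    ggplot2::facet_wrap(~margin, scales = "free_x") +
    ggplot2::labs(x = "level index", y = "observed rate", colour = NULL) +
    ggplot2::theme_minimal()
}
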