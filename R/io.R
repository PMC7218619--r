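#' Read and write APC count tables as interchange CSV
#'
#' The interchange format has one row per Lexis cell with header
#' `stratum, age_start, age_end, period_start, period_end, n_at_risk, cases`
#' (UTF-8, no thousands separators). `read_apc_csv()` validates each stratum
#' through [apc_table()] (complete grid, equal widths, `cases <= n_at_risk`)
#' and returns one table per stratum; `write_apc_csv()` is its inverse, and
#' the round trip is the identity on valid tables.
#'
#' @param path CSV file path.
#' @return `read_apc_csv()`: a named list of [apc_table()]s, one per stratum.
#' @export
read_apc_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      stratum = readr::col_character(),
      age_start = readr::col_double(),
      age_end = readr::col_double(),
      period_start = readr::col_double(),
      period_end = readr::col_double(),
      n_at_risk = readr::col_double(),
      cases = readr::col_double()
    )
  )
  required <- c("stratum", "age_start", "age_end", "period_start", "period_end", "n_at_risk", "cases")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  key <- paste(raw$stratum, raw$age_start, raw$period_start)
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate (stratum, age, period) key(s) in rows: ",
      paste(which(duplicated(key) | duplicated(key, fromLast = TRUE)), collapse = ", ")
    ))
  }
  split(raw, raw$stratum) |>
    purrr::map(apc_table)
}

#' @rdname read_apc_csv
#' @param tables An [apc_table()] or list of them.
#' @export
write_apc_csv <- function(tables, path) {
  if (inherits(tables, "apc_table")) tables <- list(tables)
  out <- purrr::map_dfr(tables, function(tab) {
    tibble::tibble(
      stratum = tab$stratum,
      age_start = tab$age_start, age_end = tab$age_end,
      period_start = tab$period_start, period_end = tab$period_end,
      n_at_risk = tab$n, cases = tab$y
    )
  })
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a rate series to CSV
#'
#' Columns `margin, level_label, numerator, denominator, rate`.
#'
#' @param rates Output of [observed_rates()] (rows from several margins may be
#'   bound together).
#' @param path Output path.
#' @export
write_rates_csv <- function(rates, path) {
  rates |>
    dplyr::transmute(
      margin = .data$margin, level_label = .data$label,
      numerator = .data$numerator, denominator = .data$denominator,
      rate = .data$rate
    ) |>
    readr::write_csv(path)
  invisible(path)
}
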