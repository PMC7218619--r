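#' Diagonal cohort index of a Lexis cell
#'
#' In an age-by-period (Lexis) count table, birth cohorts run along the
#' diagonals. With age groups indexed `i = 1..I` (1 = youngest), periods
#' indexed `j = 1..J` (1 = earliest), and `M` the ratio between the width in
#' years of the age groups and of the periods, the cohort index of cell
#' `(i, j)` is
#'
#'   k = M * (I - i) + j
#'
#' so that `k = 1` is the oldest (earliest-born) cohort and
#' `k = M * (I - 1) + J` the youngest. For the canonical grid of 14 five-year
#' age groups and 5 five-year periods (`M = 1`) this yields 18 cohorts.
#'
#' @param i Age-group index (vectorised), `1 <= i <= I`; 1 is the youngest
#'   group.
#' @param j Period index (vectorised), `j >= 1`; 1 is the earliest period.
#' @param I Number of age groups.
#' @param M Positive integer ratio age-group width / period width.
#' @return Integer vector of cohort indices `k >= 1`.
#' @examples
#' cohort_index(1, 5, I = 14, M = 1)   # 18: youngest cohort of the 14x5 grid
#' cohort_index(14, 1, I = 14, M = 1)  # 1: oldest cohort
#' @seealso [count_cohorts()], [apc_table()]
#' @export
cohort_index <- function(i, j, I, M = 1L) {
  stopifnot(length(I) == 1L, length(M) == 1L)
  if (!is.numeric(I) || I < 1 || I != round(I)) {
    abort("`I` must be a positive integer (I >= 1).")
  }
  if (!is.numeric(M) || M < 1 || M != round(M)) {
    abort("`M` must be a positive integer (M >= 1).")
  }
  if (any(!is.finite(i)) || any(i < 1)) {
    abort("age index `i` out of range: the lower bound is i >= 1.")
  }
  if (any(i > I)) {
    abort(sprintf("age index `i` out of range: the upper bound is i <= I = %d.", as.integer(I)))
  }
  if (any(!is.finite(j)) || any(j < 1)) {
    abort("period index `j` out of range: the lower bound is j >= 1.")
  }
  as.integer(M * (I - i) + j)
}

#' Number of distinct cohort indices of an I x J Lexis grid
#'
#' @param I Number of age groups.
#' @param J Number of periods.
#' @param M Positive integer ratio age-group width / period width.
#' @return `M * (I - 1) + J`, the number of distinct birth-cohort diagonals.
#' @examples
#' count_cohorts(14, 5, 1)  # 18
#' @export
count_cohorts <- function(I, J, M = 1L) {
  for (nm in c("I", "J", "M")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a positive integer scalar.", nm))
    }
  }
  as.integer(M * (I - 1) + J)
}

#' Build an age-period-cohort count table
#'
#' Validates a data frame of Lexis cells (one row per age-group x period cell
#' of a single stratum) and returns an `apc_table`: a tibble carrying the cell
#' counts together with age, period and cohort indices and grid metadata.
#'
#' The input must have one row per (age group, period) cell with columns
#' `age_start`, `age_end`, `period_start`, `period_end` (calendar years,
#' closed intervals), `n_at_risk` (subjects at risk) and `cases` (event
#' counts), plus optionally `stratum`. All age groups must share one width and
#' all periods another; the grid must be complete (every age x period
#' combination present exactly once); `cases <= n_at_risk` cell-wise.
#'
#' Cohort indices are assigned along the diagonals via [cohort_index()] with
#' `M` = age width / period width. When that ratio is not a positive integer
#' the table is still usable for age/period/total rate arithmetic, but cohort
#' indexing (and hence model fitting) is unavailable and `m_ratio` is `NA`.
#'
#' @param data Data frame of cells as described above.
#' @param stratum Optional stratum label overriding a `stratum` column.
#' @return An `apc_table` tibble with columns `stratum`, `age_index`,
#'   `age_start`, `age_end`, `period_index`, `period_start`, `period_end`,
#'   `cohort_index`, `n`, `y`, and attributes `I`, `J`, `K`, `M`,
#'   `age_width`, `period_width`.
#' @examples
#' cells <- tidyr::expand_grid(age_start = c(31, 36), period_start = c(1991, 1996))
#' cells <- dplyr::mutate(cells,
#'   age_end = age_start + 4, period_end = period_start + 4,
#'   n_at_risk = 1000, cases = 400
#' )
#' apc_table(cells, stratum = "female")
#' @export
apc_table <- function(data, stratum = NULL) {
  data <- tibble::as_tibble(data)
  required <- c("age_start", "age_end", "period_start", "period_end", "n_at_risk", "cases")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(stratum)) {
    stratum <- if ("stratum" %in% names(data)) unique(as.character(data$stratum)) else "all"
  }
  if (length(stratum) != 1L) {
    abort("`data` contains more than one stratum; build one apc_table per stratum (see read_apc_csv()).")
  }

  bad <- which(data$cases > data$n_at_risk)
  if (length(bad) > 0) {
    abort(paste0(
      "cases exceed subjects at risk (y > n) in row(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  if (any(data$n_at_risk < 0) || any(data$cases < 0)) {
    abort("counts must be non-negative.")
  }
  if (any(data$n_at_risk != round(data$n_at_risk)) || any(data$cases != round(data$cases))) {
    abort("`n_at_risk` and `cases` must be integer counts.")
  }
  if (any(data$age_end < data$age_start) || any(data$period_end < data$period_start)) {
    abort("interval ends must not precede starts.")
  }

  age_lv <- dplyr::distinct(data, .data$age_start, .data$age_end) |>
    dplyr::arrange(.data$age_start)
  per_lv <- dplyr::distinct(data, .data$period_start, .data$period_end) |>
    dplyr::arrange(.data$period_start)
  aw <- unique(age_lv$age_end - age_lv$age_start + 1)
  pw <- unique(per_lv$period_end - per_lv$period_start + 1)
  if (length(aw) != 1L) abort("all age groups must have equal width.")
  if (length(pw) != 1L) abort("all periods must have equal width.")
  I <- nrow(age_lv)
  J <- nrow(per_lv)
  if (nrow(data) != I * J) {
    key <- paste(data$age_start, data$period_start)
    dup <- key[duplicated(key)]
    if (length(dup) > 0) {
      abort(paste0("duplicate (age, period) cell(s): ", paste(unique(dup), collapse = "; ")))
    }
    full <- tidyr::expand_grid(age_start = age_lv$age_start, period_start = per_lv$period_start)
    miss <- dplyr::anti_join(full, data, by = c("age_start", "period_start"))
    abort(paste0(
      "incomplete grid: missing (age_start, period_start) cell(s): ",
      paste(paste0("(", miss$age_start, ", ", miss$period_start, ")"), collapse = "; ")
    ))
  }

  M <- aw / pw
  has_m <- isTRUE(all.equal(M, round(M))) && M >= 1
  M <- if (has_m) as.integer(round(M)) else NA_integer_

  age_lv$age_index <- seq_len(I)
  per_lv$period_index <- seq_len(J)
  out <- data |>
    dplyr::left_join(age_lv, by = c("age_start", "age_end")) |>
    dplyr::left_join(per_lv, by = c("period_start", "period_end")) |>
    dplyr::transmute(
      stratum = stratum,
      age_index = .data$age_index,
      age_start = .data$age_start,
      age_end = .data$age_end,
      period_index = .data$period_index,
      period_start = .data$period_start,
      period_end = .data$period_end,
      cohort_index = if (has_m) {
        cohort_index(.data$age_index, .data$period_index, I = I, M = M)
      } else {
        NA_integer_
      },
      n = as.integer(round(.data$n_at_risk)),
      y = as.integer(round(.data$cases))
    ) |>
    dplyr::arrange(.data$period_index, .data$age_index)

  structure(
    out,
    I = I, J = J, M = M,
    K = if (has_m) count_cohorts(I, J, M) else NA_integer_,
    age_width = aw, period_width = pw,
    class = c("apc_table", class(out))
  )
}

#' @export
print.apc_table <- function(x, ...) {
  d <- apc_dims(x)
  cat(sprintf(
    "<apc_table> stratum '%s': %d age groups x %d periods (M = %s, %s cohorts)\n",
    x$stratum[1], d$I, d$J,
    ifelse(is.na(d$M), "NA", d$M), ifelse(is.na(d$K), "NA", d$K)
  ))
  NextMethod()
  invisible(x)
}

#' Grid dimensions of an apc_table
#'
#' @param table An [apc_table()].
#' @return List with `I`, `J`, `K`, `M`, `age_width`, `period_width`.
#' @export
apc_dims <- function(table) {
  stopifnot(inherits(table, "apc_table"))
  list(
    I = attr(table, "I"), J = attr(table, "J"),
    K = attr(table, "K"), M = attr(table, "M"),
    age_width = attr(table, "age_width"),
    period_width = attr(table, "period_width")
  )
}

# internal: I x J matrices of counts / cohort indices, rows = age index
table_matrices <- function(table) {
  d <- apc_dims(table)
  n <- matrix(0L, d$I, d$J)
  y <- matrix(0L, d$I, d$J)
  k <- matrix(NA_integer_, d$I, d$J)
  idx <- cbind(table$age_index, table$period_index)
  n[idx] <- table$n
  y[idx] <- table$y
  k[idx] <- table$cohort_index
  list(n = n, y = y, k = k, I = d$I, J = d$J, K = d$K, M = d$M)
}

require_cohorts <- function(table) {
  if (is.na(apc_dims(table)$M)) {
    abort(paste0(
      "cohort indexing requires the age-group width to be a positive integer ",
      "multiple of the period width; this table has widths ",
      apc_dims(table)$age_width, " and ", apc_dims(table)$period_width, "."
    ))
  }
  invisible(table)
}

#' Birth-cohort diagonals and their non-overlapping decade labels
#'
#' Each cohort diagonal of a Lexis table corresponds to a birth-year window
#' `[period_start - age_end, period_end - age_start]`. Adjacent diagonals
#' overlap; grouping them by the decade in which their window opens (anchored
#' at the earliest diagonal) yields disjoint 10-year birth intervals. For the
#' canonical 14 x 5 grid (ages 31-100, periods 1991-2015) the 18 diagonals
#' collapse into the 9 decades 1891-1900 through 1971-1980.
#'
#' @param table An [apc_table()] with integer `m_ratio`.
#' @return Tibble with one row per cohort index: `cohort_index`,
#'   `birth_start`, `birth_end`, `decade_start`, `decade_end`,
#'   `decade_label`.
#' @export
cohort_decades <- function(table) {
  require_cohorts(table)
  diag_tbl <- table |>
    dplyr::group_by(cohort_index = .data$cohort_index) |>
    dplyr::summarise(
      birth_start = min(.data$period_start - .data$age_end),
      birth_end = max(.data$period_end - .data$age_start),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cohort_index)
  anchor <- min(diag_tbl$birth_start)
  diag_tbl |>
    dplyr::mutate(
      decade_start = anchor + 10 * floor((.data$birth_start - anchor) / 10),
      decade_end = .data$decade_start + 9,
      decade_label = paste0(.data$decade_start, "-", .data$decade_end)
    )
}
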