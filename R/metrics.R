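#' Descriptive and glycemic-variation statistics
#'
#' Computes the primary descriptive outcomes for an analysis interval:
#' median, minimum, maximum, range, plus glycemic variation as the sample
#' standard deviation, variance and coefficient of variation (CV = 100*sd/mean),
#' and a 95% normal reference interval `mean +/- 1.96*sd` describing the span
#' of glucose values (reported as `ri95_*`; it is a reference interval for
#' readings, not a confidence interval of the mean).
#'
#' @param x A numeric vector of glucose values (mmol/L) or a data frame with
#'   a `glucose` column.
#' @return A one-row tibble: `n`, `mean`, `median`, `min`, `max`, `range`,
#'   `sd`, `variance`, `cv_percent`, `ri95_low`, `ri95_high`. Spread
#'   statistics are `NA` when `n = 1`.
#' @examples
#' descriptive(c(4, 5, 6))
#' @export
descriptive <- function(x) {
  v <- glucose_values(x)
  if (length(v) == 0) stop("cannot summarise an empty interval", call. = FALSE)
  n <- length(v)
  m <- mean(v)
  s <- if (n >= 2) stats::sd(v) else NA_real_
  tibble::tibble(
    n = n,
    mean = m,
    median = stats::median(v),
    min = min(v),
    max = max(v),
    range = max(v) - min(v),
    sd = s,
    variance = s^2,
    cv_percent = 100 * s / m,
    ri95_low = pmax(m - 1.96 * s, 0),
    ri95_high = m + 1.96 * s
  )
}

glucose_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"glucose" %in% names(x)) stop("no `glucose` column", call. = FALSE)
    x <- x$glucose
  }
  stopifnot(is.numeric(x))
  x[!is.na(x)]
}

#' 95% reference interval, report-rounded
#'
#' `(mean - 1.96*sd, mean + 1.96*sd)` floored at 0 and rounded to 1 decimal,
#' matching the tabulated reporting convention.
#'
#' @param stats A one-row tibble from [descriptive()] (or anything with
#'   `mean` and `sd`).
#' @param digits Decimal places (default 1); `NULL` for full precision.
#' @return Named numeric vector `c(low, high)`; `NA` when `sd` is undefined.
#' @export
reference_interval_95 <- function(stats, digits = 1) {
  lo <- max(stats$mean - 1.96 * stats$sd, 0)
  hi <- stats$mean + 1.96 * stats$sd
  if (!is.null(digits)) {
    lo <- round(lo, digits)
    hi <- round(hi, digits)
  }
  c(low = lo, high = hi)
}

#' Time in / under / above range
#'
#' Percentages of readings in the ADA 2020 consensus bands: level-2
#' hypoglycemia (`< 3.0`), level-1 hypoglycemia (`>= 3.0` and `< 3.9`), time
#' in range over the tight (`>= 3.9` and `<= 7.8`) and standard (`>= 3.9` and
#' `<= 10.0`) bands, and time above `> 7.8` and `> 10.0` mmol/L. The four
#' bands `<3.0`, `[3.0, 3.9)`, `[3.9, 7.8]`, `>7.8` partition the readings,
#' so those four percentages sum to exactly 100 before rounding. Level-3
#' hypoglycemia is a clinical event definition and is never computed from CGM
#' values.
#'
#' @inheritParams descriptive
#' @return A one-row tibble: `tur_l2`, `tur_l1`, `tir_39_78`, `tir_39_100`,
#'   `tar_78`, `tar_100`, each a percentage of non-missing readings.
#' @examples
#' time_in_ranges(c(2.5, 3.5, 5, 5, 5, 6, 7, 8, 8, 10.5))
#' @export
time_in_ranges <- function(x) {
  v <- glucose_values(x)
  if (length(v) == 0) stop("cannot classify an empty interval", call. = FALSE)
  n <- length(v)
  pct <- function(mask) 100 * sum(mask) / n
  tibble::tibble(
    tur_l2 = pct(v < 3.0),
    tur_l1 = pct(v >= 3.0 & v < 3.9),
    tir_39_78 = pct(v >= 3.9 & v <= 7.8),
    tir_39_100 = pct(v >= 3.9 & v <= 10.0),
    tar_78 = pct(v > 7.8),
    tar_100 = pct(v > 10.0)
  )
}

#' Per-intervention metrics report
#'
#' The tabular workhorse: one row per (intervention, scope) pair, where scope
#' is the full segment (`"total"`) and its nocturnal clock window
#' (`"nocturnal"`), carrying `n`, the number of days/nights spanned, all
#' [descriptive()] fields and all [time_in_ranges()] percentages.
#'
#' @param trace A CGM trace.
#' @param schedule Optional intervention schedule; `NULL` treats the whole
#'   trace as one `"all-data"` segment.
#' @param window Nocturnal [clock_window()].
#' @param digits Decimal places for reported concentrations and percentages
#'   (default 1, the tabulation convention); `NULL` for full precision.
#' @return A tibble, interventions in schedule order, `total` before
#'   `nocturnal`.
#' @export
interval_report <- function(trace, schedule = NULL, window = clock_window(),
                            digits = 1) {
  groups <- split_by_intervention(trace, schedule)
  rows <- purrr::imap(groups, function(seg, lab) {
    noct <- extract_clock_window(seg, window)
    scopes <- list(total = seg)
    scopes[[format(window)]] <- noct
    purrr::imap(scopes, function(sub, scope) {
      if (nrow(sub) == 0) {
        return(NULL)
      }
      days <- length(unique(as.Date(format(sub$timestamp, "%Y-%m-%d"))))
      if (scope != "total") {
        days <- nrow(nights_of(sub, window, min_completeness = 0))
      }
      dplyr::bind_cols(
        tibble::tibble(intervention = lab, scope = scope, days = days),
        descriptive(sub),
        time_in_ranges(sub),
        tibble::tibble(missing_pct = 100 * mean(is.na(sub$glucose)))
      )
    }) |> purrr::compact() |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(digits)) {
    num <- setdiff(
      names(out)[vapply(out, is.numeric, logical(1))],
      c("n", "days")
    )
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(num), ~ round(.x, digits)))
  }
  out
}
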