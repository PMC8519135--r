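#' Clock-of-day analysis windows
#'
#' Diurnal variation in diet and physical activity confounds glucose
#' homeostasis, so the nocturnal 01:00-05:00 interval is analysed separately.
#' Windows are half-open `[start, end)` on the device-local clock: at a 5-min
#' cadence the default window holds exactly 48 samples per night (192 over 4
#' nights).
#'
#' @param start,end Clock times as `"HH:MM"` strings.
#' @return A `clock_window` object.
#' @examples
#' clock_window() # 01:00-05:00
#' @export
clock_window <- function(start = "01:00", end = "05:00") {
  s <- parse_clock(start)
  e <- parse_clock(end)
  if (s == e) stop("window is empty under the half-open convention", call. = FALSE)
  structure(list(start_min = s, end_min = e, start = start, end = end),
    class = "clock_window"
  )
}

parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) stop("clock time must be 'HH:MM', got ", x, call. = FALSE)
  h <- as.numeric(m[2])
  mi <- as.numeric(m[3])
  if (h >= 24 || mi >= 60) stop("invalid clock time ", x, call. = FALSE)
  h * 60 + mi
}

#' @export
print.clock_window <- function(x, ...) {
  cat("<clock window ", x$start, "-", x$end, " (half-open)>\n", sep = "")
  invisible(x)
}

#' @export
format.clock_window <- function(x, ...) paste0(x$start, "-", x$end)

# Logical mask of samples whose time of day lies in [start, end); windows
# crossing midnight wrap.
in_window <- function(timestamp, window) {
  m <- clock_minutes(timestamp)
  if (window$start_min < window$end_min) {
    m >= window$start_min & m < window$end_min
  } else {
    m >= window$start_min | m < window$end_min
  }
}

#' Extract the samples inside a clock window
#'
#' Retains samples whose time of day lies in `[start, end)` on any date;
#' ordering is preserved and the operation is idempotent.
#'
#' @param trace A CGM trace.
#' @param window A [clock_window()].
#' @return A CGM trace (possibly empty).
#' @export
extract_clock_window <- function(trace, window = clock_window()) {
  rewrap_trace(trace[in_window(trace$timestamp, window), ], trace)
}

#' Intervention schedules
#'
#' An intervention schedule is a tibble with columns `label`, `start`, `end`
#' (POSIXct) and optionally `dose_text`, describing the labelled diet/drug
#' phases by which all metrics are partitioned. Segments are half-open
#' `[start, end)`; overlaps are an error.
#'
#' @param label Character labels.
#' @param start,end POSIXct interval bounds, `start < end`.
#' @param dose_text Optional free-text dose description.
#' @return A tibble sorted by `start`.
#' @export
intervention_schedule <- function(label, start, end, dose_text = NA_character_) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  if (any(!(start < end))) stop("every intervention needs start < end", call. = FALSE)
  sched <- tibble::tibble(
    label = as.character(label), start = start, end = end,
    dose_text = rep_len(dose_text, length(label))
  )
  sched <- dplyr::arrange(sched, .data$start)
  check_no_overlap(sched)
  sched
}

check_no_overlap <- function(sched) {
  if (nrow(sched) > 1) {
    bad <- which(sched$start[-1] < sched$end[-nrow(sched)])
    if (length(bad) > 0) {
      stop(
        "overlapping interventions: ",
        paste(sprintf(
          "'%s' overlaps '%s'",
          sched$label[bad], sched$label[bad + 1]
        ), collapse = "; "),
        call. = FALSE
      )
    }
  }
  invisible(sched)
}

#' Read an intervention schedule from CSV or YAML
#'
#' CSV needs columns `label,start,end[,dose_text]`; YAML a list of mappings
#' with the same keys. Datetimes are `"YYYY-MM-DD HH:MM[:SS]"` in device-local
#' clock time.
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` vs CSV).
#' @param tz Timezone label for parsed datetimes.
#' @return A schedule tibble (see [intervention_schedule()]).
#' @export
read_schedule <- function(path, tz = "UTC") {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- purrr::map_dfr(raw, function(x) {
      tibble::tibble(
        label = x$label, start = x$start, end = x$end,
        dose_text = x$dose_text %||% NA_character_
      )
    })
  } else {
    df <- readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    if (!"dose_text" %in% names(df)) df$dose_text <- NA_character_
  }
  intervention_schedule(
    df$label,
    parse_device_time(df$start, tz = tz),
    parse_device_time(df$end, tz = tz),
    df$dose_text
  )
}

#' Assign each sample to its intervention
#'
#' Adds an `intervention` column: the label of the unique intervention whose
#' `[start, end)` contains the sample, or `"unassigned"` outside all
#' segments. A sample exactly on the boundary of abutting segments belongs to
#' the later one (half-open rule).
#'
#' @param trace A CGM trace.
#' @param schedule A schedule tibble; `NULL` assigns everything to
#'   `"all-data"`.
#' @return The trace with an `intervention` column.
#' @export
assign_interventions <- function(trace, schedule = NULL) {
  if (is.null(schedule)) {
    out <- trace
    out$intervention <- "all-data"
    return(rewrap_trace(out, trace))
  }
  check_no_overlap(dplyr::arrange(schedule, .data$start))
  lab <- rep("unassigned", nrow(trace))
  for (i in seq_len(nrow(schedule))) {
    hit <- trace$timestamp >= schedule$start[i] & trace$timestamp < schedule$end[i]
    lab[hit] <- schedule$label[i]
  }
  out <- trace
  out$intervention <- lab
  rewrap_trace(out, trace)
}

#' @rdname assign_interventions
#' @return `split_by_intervention()`: a named list of traces, one per label
#'   present (group sizes always sum to the trace length).
#' @export
split_by_intervention <- function(trace, schedule = NULL) {
  tagged <- assign_interventions(trace, schedule)
  labs <- unique(tagged$intervention)
  out <- lapply(labs, function(l) {
    rewrap_trace(tagged[tagged$intervention == l, names(trace)], trace)
  })
  names(out) <- labs
  out
}

#' Per-night nocturnal windows
#'
#' Splits the in-window samples by calendar date (a night is labelled by the
#' date its window starts on) and flags incomplete nights. Nights holding
#' fewer than `min_completeness` of the expected samples are flagged and, by
#' default, excluded from spectral and CUSUM analyses downstream.
#'
#' @param trace A CGM trace.
#' @param window A [clock_window()].
#' @param min_completeness Fraction of expected samples below which a night
#'   is flagged incomplete (default 0.8).
#' @return A tibble with one row per night: `night` (Date), `n`, `expected`,
#'   `complete`, and a `data` list-column of per-night traces.
#' @export
nights_of <- function(trace, window = clock_window(), min_completeness = 0.8) {
  win <- extract_clock_window(trace, window)
  if (nrow(win) == 0) {
    return(tibble::tibble(
      night = as.Date(character(0)), n = integer(0),
      expected = integer(0), complete = logical(0), data = list()
    ))
  }
  # label by the date the window starts on: samples before midnight in a
  # wrapped window belong to that evening's date, samples after midnight to
  # the previous day only if the window wraps
  m <- clock_minutes(win$timestamp)
  night_date <- as.Date(format(win$timestamp, "%Y-%m-%d"))
  if (window$start_min > window$end_min) {
    night_date[m < window$end_min] <- night_date[m < window$end_min] - 1
  }
  cad <- trace_cadence(trace)
  dur_min <- (window$end_min - window$start_min) %% (24 * 60)
  expected <- floor(dur_min / cad)
  dates <- sort(unique(night_date))
  tibble::tibble(
    night = dates,
    n = vapply(dates, function(d) sum(night_date == d), integer(1)),
    expected = as.integer(expected)
  ) |>
    dplyr::mutate(
      complete = .data$n >= min_completeness * .data$expected,
      data = lapply(dates, function(d) rewrap_trace(win[night_date == d, ], trace))
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
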