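#' CGM trace objects
#'
#' A CGM trace is a tibble with one row per sensor reading and columns
#' `timestamp` (POSIXct, naive device-local clock), `glucose` (mmol/L) and
#' `clipped` (logical; `TRUE` where the device reported below its validated
#' floor and the reading was set to the floor). The nominal sampling cadence
#' (minutes) and an opaque patient label travel as attributes; every verb in
#' the package also accepts a plain tibble with these columns.
#'
#' @param x A data frame with columns `timestamp`, `glucose` and optionally
#'   `clipped`.
#' @param cadence_min Nominal sampling interval in minutes (Dexcom devices
#'   report every 5 minutes, 288 readings per day).
#' @param patient_id Opaque patient label carried into reports.
#' @return A `cgm_trace` tibble sorted by timestamp.
#' @examples
#' tr <- as_cgm_trace(tibble::tibble(
#'   timestamp = as.POSIXct("2024-01-01 00:00", tz = "UTC") + 300 * (0:3),
#'   glucose = c(4.8, 5.1, 5.0, 4.9)
#' ))
#' trace_cadence(tr)
#' @export
as_cgm_trace <- function(x, cadence_min = 5, patient_id = NA_character_) {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("timestamp", "glucose"), names(x))
  if (length(missing) > 0) {
    stop("trace is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!inherits(x$timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct", call. = FALSE)
  }
  if (cadence_min <= 0) stop("`cadence_min` must be > 0", call. = FALSE)
  out <- tibble::as_tibble(x)
  if (!"clipped" %in% names(out)) out$clipped <- FALSE
  out <- dplyr::arrange(out, .data$timestamp)
  dup <- duplicated(out$timestamp)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) dropped (first kept)",
      call. = FALSE
    )
    out <- out[!dup, ]
  }
  validate_trace_values(out)
  structure(out,
    class = c("cgm_trace", class(tibble::tibble())),
    cadence_min = cadence_min,
    patient_id = patient_id
  )
}

validate_trace_values <- function(x) {
  if (nrow(x) > 0 && (any(!is.finite(x$glucose)) || any(x$glucose <= 0))) {
    stop("glucose values must be finite and > 0", call. = FALSE)
  }
  invisible(x)
}

#' @rdname as_cgm_trace
#' @param trace A CGM trace (or plain tibble with a `timestamp` column).
#' @export
trace_cadence <- function(trace) {
  cad <- attr(trace, "cadence_min")
  if (!is.null(cad)) {
    return(cad)
  }
  if (nrow(trace) < 2) {
    return(5)
  }
  stats::median(as.numeric(diff(trace$timestamp), units = "mins"))
}

#' @rdname as_cgm_trace
#' @export
trace_patient <- function(trace) {
  pid <- attr(trace, "patient_id")
  if (is.null(pid)) NA_character_ else pid
}

# Re-wrap a tibble derived from `trace`, preserving cadence/patient metadata.
rewrap_trace <- function(x, trace) {
  structure(tibble::as_tibble(x),
    class = c("cgm_trace", class(tibble::tibble())),
    cadence_min = trace_cadence(trace),
    patient_id = trace_patient(trace)
  )
}

# Hours since the first sample, used for load curves and event placement.
trace_hours <- function(trace) {
  if (nrow(trace) == 0) {
    return(numeric(0))
  }
  as.numeric(trace$timestamp - trace$timestamp[1], units = "hours")
}

# Minutes since local midnight for each sample (clock arithmetic, no tz math).
clock_minutes <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' @export
print.cgm_trace <- function(x, ...) {
  cat(
    "# CGM trace:", nrow(x), "samples, cadence", trace_cadence(x), "min",
    if (!is.na(trace_patient(x))) paste0("(patient ", trace_patient(x), ")"),
    "\n"
  )
  NextMethod()
}

#' Plot a CGM trace
#'
#' Draws glucose against time with the physiological 3.9-7.8 mmol/L band
#' shaded and the 2.2 mmol/L device floor marked. Clipped samples are
#' highlighted.
#'
#' @param object A CGM trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cgm_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timestamp, y = .data$glucose)) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf, ymin = 3.9, ymax = 7.8,
      alpha = 0.12, fill = "seagreen"
    ) +
    ggplot2::geom_hline(yintercept = 2.2, linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$clipped),
      colour = "firebrick", size = 1
    ) +
    ggplot2::labs(x = NULL, y = "glucose (mmol/L)")
}
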