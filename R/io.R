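#' Read a Dexcom-CLARITY-style CGM CSV export
#'
#' Parses a CSV export of estimated glucose values (EGV) into a [as_cgm_trace()]
#' tibble in mmol/L. Non-glucose rows (calibrations, alerts, device events) are
#' skipped, `"Low"` readings are converted to clipped samples at the 2.2 mmol/L
#' device floor, duplicate timestamps are dropped (first kept) and the result
#' is sorted by time. The CLARITY portal does not fix a unit at export time, so
#' the unit is declared by the caller.
#'
#' @param path Path to the CSV file.
#' @param units `"mmol"` (mmol/L, default) or `"mgdl"`; mg/dL values are
#'   converted on ingestion so the canonical in-memory unit is always mmol/L.
#' @param col_map Named list locating the columns, each entry a regular
#'   expression matched case-insensitively against the header. Defaults match
#'   Dexcom CLARITY headers (`Timestamp (YYYY-MM-DDThh:mm:ss)`, `Event Type`,
#'   `Glucose Value (mmol/L)`).
#' @param delim Field delimiter.
#' @param decimal_mark Decimal mark used in the glucose column.
#' @param cadence_min Nominal cadence recorded on the trace.
#' @param patient_id Optional patient label.
#' @param tz Timezone label applied to parsed timestamps. Timestamps are
#'   treated as naive device-local clock time (nocturnal windows are
#'   clock-based), so this is a label, not a conversion.
#' @return A `cgm_trace` tibble.
#' @seealso [write_trace_csv()], [clip_floor()]
#' @export
read_dexcom_csv <- function(path,
                            units = c("mmol", "mgdl"),
                            col_map = list(
                              timestamp = "timestamp",
                              event_type = "event +type",
                              glucose = "glucose +value"
                            ),
                            delim = ",",
                            decimal_mark = ".",
                            cadence_min = 5,
                            patient_id = NA_character_,
                            tz = "UTC") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path,
    delim = delim,
    locale = readr::locale(decimal_mark = decimal_mark),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )

  find_col <- function(pattern) {
    hit <- grep(pattern, names(raw), ignore.case = TRUE)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  ts_col <- find_col(col_map$timestamp)
  gl_col <- find_col(col_map$glucose)
  ev_col <- find_col(col_map$event_type)
  if (is.na(ts_col) || is.na(gl_col)) {
    stop("not a recognised CGM export: need a timestamp and a glucose column",
      call. = FALSE
    )
  }

  if (!is.na(ev_col)) {
    raw <- raw[grepl("EGV", raw[[ev_col]], ignore.case = TRUE), , drop = FALSE]
  }
  raw <- raw[!is.na(raw[[gl_col]]) & raw[[gl_col]] != "", , drop = FALSE]
  if (nrow(raw) == 0) stop("no glucose rows found in ", path, call. = FALSE)

  gl_txt <- trimws(raw[[gl_col]])
  low <- grepl("^low$", gl_txt, ignore.case = TRUE)
  high <- grepl("^high$", gl_txt, ignore.case = TRUE)
  if (any(high)) {
    warning(sum(high), " 'High' reading(s) mapped to the 22.2 mmol/L display ",
      "ceiling; no validated upper clipping is applied",
      call. = FALSE
    )
  }
  if (decimal_mark != ".") gl_txt <- gsub(decimal_mark, ".", gl_txt, fixed = TRUE)
  value <- suppressWarnings(as.numeric(gl_txt))
  if (units == "mgdl") value <- mgdl_to_mmol(value)
  value[low] <- 2.2
  value[high] <- 22.2

  ts <- parse_device_time(raw[[ts_col]], tz = tz)
  bad <- is.na(ts) | is.na(value)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable timestamp or glucose dropped",
      call. = FALSE
    )
  }
  keep <- !bad
  if (!any(keep)) stop("no parseable glucose rows in ", path, call. = FALSE)

  trace <- as_cgm_trace(
    tibble::tibble(
      timestamp = ts[keep],
      glucose = value[keep],
      clipped = low[keep]
    ),
    cadence_min = cadence_min, patient_id = patient_id
  )
  clip_floor(trace)
}

# Dexcom exports use ISO-like "YYYY-MM-DDThh:mm:ss"; be liberal about the 'T'.
parse_device_time <- function(x, tz = "UTC") {
  x <- sub("T", " ", trimws(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = tz, format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Write a canonical trace CSV (and optional JSON metadata sidecar)
#'
#' The canonical on-disk form is `timestamp` (ISO-8601), `glucose` (mmol/L)
#' and `clipped` (0/1). A round trip through [write_trace_csv()] and
#' [read_trace_csv()] reproduces timestamps exactly and values to well below
#' 0.01 mmol/L.
#'
#' @param trace A CGM trace.
#' @param path Output CSV path.
#' @param sidecar If `TRUE`, also write `<path>.json` with cadence, patient
#'   label and sample count.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = FALSE) {
  out <- tibble::tibble(
    timestamp = format(trace$timestamp, "%Y-%m-%dT%H:%M:%S"),
    glucose = trace$glucose,
    clipped = as.integer(trace$clipped)
  )
  readr::write_csv(out, path)
  if (sidecar) {
    meta <- list(
      cadence_min = trace_cadence(trace),
      patient_id = trace_patient(trace),
      n = nrow(trace),
      unit = "mmol/L"
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @inheritParams read_dexcom_csv
#' @export
read_trace_csv <- function(path, cadence_min = 5, patient_id = NA_character_,
                           tz = "UTC") {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      timestamp = readr::col_character(),
      glucose = readr::col_double(),
      clipped = readr::col_integer()
    ), progress = FALSE
  )
  as_cgm_trace(
    tibble::tibble(
      timestamp = parse_device_time(raw$timestamp, tz = tz),
      glucose = raw$glucose,
      clipped = raw$clipped > 0
    ),
    cadence_min = cadence_min, patient_id = patient_id
  )
}

#' Enforce the validated device floor
#'
#' Dexcom sensors are validated down to 2.2 mmol/L (40 mg/dL); sub-floor
#' readings are replaced by the floor rather than dropped, because omitting
#' them would bias descriptive statistics upwards during hypoglycemia.
#' Idempotent; all other samples pass through unchanged.
#'
#' @param trace A CGM trace.
#' @param floor Floor in mmol/L.
#' @return The trace with sub-floor values set to `floor` and flagged
#'   `clipped`.
#' @export
clip_floor <- function(trace, floor = 2.2) {
  below <- trace$glucose < floor
  trace$clipped <- trace$clipped | below
  trace$glucose[below] <- floor
  trace
}

#' Glucose unit conversion
#'
#' Conversion between mg/dL and mmol/L using the molar mass of glucose
#' (18.016 mg/dL per mmol/L). The two functions are exact inverses.
#'
#' @param x Glucose concentration(s), `>= 0`.
#' @return Converted concentration(s).
#' @examples
#' mgdl_to_mmol(180.16) # 10
#' mgdl_to_mmol(40) # ~2.22, the validated floor
#' @export
mgdl_to_mmol <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("glucose cannot be negative", call. = FALSE)
  x / 18.016
}

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("glucose cannot be negative", call. = FALSE)
  x * 18.016
}

#' Carbohydrate delivery rate per body mass
#'
#' Converts a carbohydrate delivery rate in g/hour (as prescribed for
#' continuous gastric drip feeding) to mg/kg/minute, the unit in which
#' endogenous glucose production is expressed, so that dietary delivery can be
#' compared against the patient's predicted requirement.
#'
#' @param rate_g_per_h Carbohydrate delivery, g/hour, `> 0` (0 allowed as a
#'   limit).
#' @param weight_kg Body mass in kg, `> 0`.
#' @param digits Decimal places in the reported rate (clinical convention: 1).
#'   `NULL` for full precision.
#' @return Delivery rate in mg/kg/minute.
#' @examples
#' carb_rate(10.4, 37.4) # 4.6 mg/kg/min
#' @export
carb_rate <- function(rate_g_per_h, weight_kg, digits = 1) {
  if (any(weight_kg <= 0)) stop("weight must be > 0", call. = FALSE)
  if (any(rate_g_per_h < 0)) stop("delivery rate cannot be negative", call. = FALSE)
  out <- 1000 * rate_g_per_h / (weight_kg * 60)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
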