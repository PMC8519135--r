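# Shared fixture builders: uniform-grid traces from plain value vectors.

t0 <- function(clock = "00:00:00", date = "2024-01-01") {
  as.POSIXct(paste(date, clock), tz = "UTC")
}

uniform_trace <- function(values, start = t0(), cadence_min = 5, ...) {
  as_cgm_trace(
    tibble::tibble(
      timestamp = start + (seq_along(values) - 1) * cadence_min * 60,
      glucose = values
    ),
    cadence_min = cadence_min, ...
  )
}

# A Dexcom-CLARITY-style export written to a temp file; `glucose` entries may
# be numbers or the "Low"/"High" device flags.
write_dexcom_fixture <- function(timestamps, glucose, event_type = "EGV",
                                 path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    "Timestamp (YYYY-MM-DDThh:mm:ss)" = timestamps,
    "Event Type" = rep_len(event_type, length(timestamps)),
    "Glucose Value (mmol/L)" = as.character(glucose),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  path
}
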