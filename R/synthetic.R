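#' Synthetic CGM trace configuration
#'
#' Describes a synthetic trace as a baseline level plus sinusoidal components,
#' additive events (hypoglycemic dips, meal/starch excursions), Gaussian
#' sensor noise and the 2.2 mmol/L device floor. Traces generated from the
#' same configuration (including `seed`) are bit-identical, which makes every
#' downstream analysis stage verifiable against known ground truth.
#'
#' @param baseline Baseline glucose, mmol/L.
#' @param components Tibble of sinusoidal components, see [sinusoid()].
#' @param noise_sd Standard deviation of additive Gaussian sensor noise,
#'   mmol/L.
#' @param events Tibble of additive events, see [cgm_event()].
#' @param duration_h Trace duration, hours.
#' @param cadence_min Sampling interval, minutes. Samples sit at
#'   `t = 0, cadence, 2*cadence, ...` strictly below `duration_h` (half-open
#'   grid), giving exactly 288 samples/day at 5 minutes.
#' @param start First sample clock time; defaults to midnight so that
#'   nocturnal-window arithmetic is deterministic.
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param ar1 Optional AR(1) coefficient in `[0, 1)` for autocorrelated
#'   sensor noise; 0 (default) gives independent noise.
#' @return A `synth_config` list.
#' @export
synth_config <- function(baseline = 5,
                         components = sinusoid(numeric(0), numeric(0)),
                         noise_sd = 0,
                         events = cgm_event(character(0), numeric(0), numeric(0), numeric(0)),
                         duration_h = 24,
                         cadence_min = 5,
                         start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                         seed = 1L,
                         ar1 = 0) {
  stopifnot(
    duration_h > 0, cadence_min > 0, noise_sd >= 0,
    ar1 >= 0, ar1 < 1,
    all(components$frequency >= 0), all(components$amplitude >= 0)
  )
  structure(
    list(
      baseline = baseline, components = components, noise_sd = noise_sd,
      events = events, duration_h = duration_h, cadence_min = cadence_min,
      start = start, seed = as.integer(seed), ar1 = ar1
    ),
    class = "synth_config"
  )
}

#' @rdname synth_config
#' @param frequency Cycles per hour.
#' @param amplitude mmol/L.
#' @param phase Radians.
#' @export
sinusoid <- function(frequency, amplitude, phase = 0) {
  tibble::tibble(
    frequency = frequency, amplitude = amplitude,
    phase = rep_len(phase, length(frequency))
  )
}

#' @rdname synth_config
#' @param type `"hypo_dip"` (smooth raised-cosine negative excursion) or
#'   `"meal_excursion"` (asymmetric rise/decay triangle, peak at one third of
#'   the event duration).
#' @param start_h Event onset, hours from trace start.
#' @param magnitude Peak deflection, mmol/L (positive number; dips subtract).
#' @export
cgm_event <- function(type, start_h, duration_h, magnitude) {
  if (length(type) > 0 && !all(type %in% c("hypo_dip", "meal_excursion"))) {
    stop("event type must be 'hypo_dip' or 'meal_excursion'", call. = FALSE)
  }
  tibble::tibble(
    type = type, start_h = start_h,
    duration_h = duration_h, magnitude = magnitude
  )
}

#' Generate a synthetic CGM trace
#'
#' Evaluates `baseline + sum(amplitude * sin(2*pi*frequency*t + phase))` on
#' the half-open sampling grid, adds event terms and seeded Gaussian noise,
#' then applies the 2.2 mmol/L device floor via [clip_floor()].
#'
#' @param config A [synth_config()].
#' @return A `cgm_trace` tibble.
#' @examples
#' cfg <- synth_config(
#'   baseline = 5,
#'   components = sinusoid(frequency = 1, amplitude = 1),
#'   duration_h = 24
#' )
#' nrow(generate_trace(cfg)) # 288
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  t_h <- seq(0, config$duration_h - 1e-9, by = config$cadence_min / 60)
  t_h <- t_h[t_h < config$duration_h]
  n <- length(t_h)

  value <- rep(config$baseline, n)
  if (nrow(config$components) > 0) {
    for (i in seq_len(nrow(config$components))) {
      cmp <- config$components[i, ]
      value <- value +
        cmp$amplitude * sin(2 * pi * cmp$frequency * t_h + cmp$phase)
    }
  }
  if (nrow(config$events) > 0) {
    for (i in seq_len(nrow(config$events))) {
      value <- value + event_term(config$events[i, ], t_h)
    }
  }
  if (config$noise_sd > 0) {
    value <- value + local_seed(config$seed, {
      eps <- stats::rnorm(n, sd = config$noise_sd)
      if (config$ar1 > 0) {
        # AR(1) filter rescaled to keep the marginal sd at noise_sd
        eps <- stats::filter(eps, config$ar1, method = "recursive") *
          sqrt(1 - config$ar1^2)
        eps <- as.numeric(eps)
      }
      eps
    })
  }

  clip_floor(as_cgm_trace(
    tibble::tibble(
      timestamp = config$start + t_h * 3600,
      glucose = pmax(value, 1e-6),
      clipped = FALSE
    ),
    cadence_min = config$cadence_min,
    patient_id = "synthetic"
  ))
}

# Additive event shapes; both return 0 outside [start, start + duration].
event_term <- function(ev, t_h) {
  u <- (t_h - ev$start_h) / ev$duration_h
  inside <- u >= 0 & u <= 1
  out <- numeric(length(t_h))
  if (ev$type == "hypo_dip") {
    # raised cosine: smooth dip reaching -magnitude at the event midpoint
    out[inside] <- -ev$magnitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  } else {
    # asymmetric triangle: fast rise (first third), slower linear decay
    peak <- 1 / 3
    rise <- inside & u <= peak
    fall <- inside & u > peak
    out[rise] <- ev$magnitude * u[rise] / peak
    out[fall] <- ev$magnitude * (1 - u[fall]) / (1 - peak)
  }
  out
}

# Evaluate `expr` under a fixed seed and restore the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Starch-load curve specification
#'
#' A load curve is anchored by three knots: the pre-load initial value at
#' time 0, the maximum at `t_max_min`, and the end value at `end_time_min`
#' (the descriptors by which monitored starch loads are summarised).
#'
#' @param initial,max_value,end_value mmol/L.
#' @param t_max_min,end_time_min Minutes from load start,
#'   `0 < t_max_min < end_time_min`.
#' @param shape `"piecewise_linear"` (summarisation recovers the spec
#'   exactly) or `"smooth"` (monotone Hermite segments through the same
#'   knots).
#' @return A `load_curve_spec` list.
#' @export
load_curve_spec <- function(initial, max_value, t_max_min, end_value,
                            end_time_min, shape = c("piecewise_linear", "smooth")) {
  shape <- match.arg(shape)
  if (!(t_max_min > 0 && t_max_min < end_time_min)) {
    stop("need 0 < t_max_min < end_time_min", call. = FALSE)
  }
  if (max_value < initial || max_value < end_value) {
    stop("max_value must be >= initial and >= end_value", call. = FALSE)
  }
  structure(
    list(
      initial = initial, max_value = max_value, t_max_min = t_max_min,
      end_value = end_value, end_time_min = end_time_min, shape = shape
    ),
    class = "load_curve_spec"
  )
}

#' Generate a starch-load glucose curve
#'
#' @param spec A [load_curve_spec()].
#' @param cadence_min Sampling interval, minutes. When the knot times are
#'   multiples of the cadence, the grid passes through the knots exactly and
#'   [load_summary()] recovers the spec fields exactly (piecewise-linear
#'   shape).
#' @param start Timestamp of load start.
#' @return A `cgm_trace` covering `[0, end_time_min]` inclusive.
#' @export
generate_load_curve <- function(spec, cadence_min = 5,
                                start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC")) {
  stopifnot(inherits(spec, "load_curve_spec"))
  t_min <- seq(0, spec$end_time_min, by = cadence_min)
  if (t_min[length(t_min)] < spec$end_time_min) {
    t_min <- c(t_min, spec$end_time_min)
  }
  knots_x <- c(0, spec$t_max_min, spec$end_time_min)
  knots_y <- c(spec$initial, spec$max_value, spec$end_value)
  value <- if (spec$shape == "piecewise_linear") {
    stats::approx(knots_x, knots_y, xout = t_min)$y
  } else {
    stats::splinefun(knots_x, knots_y, method = "monoH.FC")(t_min)
  }
  clip_floor(as_cgm_trace(
    tibble::tibble(
      timestamp = start + t_min * 60,
      glucose = value,
      clipped = FALSE
    ),
    cadence_min = cadence_min, patient_id = "synthetic"
  ))
}

#' Remove samples inside dropout intervals
#'
#' Emulates sensor dropouts (incomplete CGM data) by deleting samples whose
#' time since trace start falls in any of the given half-open intervals.
#'
#' @param trace A CGM trace.
#' @param gaps List of `c(start_h, end_h)` pairs, hours from trace start.
#' @return The trace with in-gap samples removed; all others unchanged.
#' @export
inject_gaps <- function(trace, gaps) {
  if (length(gaps) == 0 || nrow(trace) == 0) {
    return(trace)
  }
  t_h <- trace_hours(trace)
  drop <- rep(FALSE, length(t_h))
  for (g in gaps) {
    stopifnot(length(g) == 2, g[1] <= g[2])
    drop <- drop | (t_h >= g[1] & t_h < g[2])
  }
  rewrap_trace(trace[!drop, ], trace)
}
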