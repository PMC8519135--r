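#' Trapezoidal area under the glucose curve
#'
#' Total AUC of concentration against time in hours, above the zero baseline
#' (not incremental above the initial value). Additive over concatenated
#' segments.
#'
#' @param trace A CGM trace (or tibble with `timestamp` and `glucose`).
#' @return AUC in mmol/L * h.
#' @examples
#' # constant 5 mmol/L for 2 h -> 10
#' @export
auc_trapezoid <- function(trace) {
  if (nrow(trace) < 2) stop("AUC needs at least 2 samples", call. = FALSE)
  t_h <- as.numeric(trace$timestamp - trace$timestamp[1], units = "hours")
  sum(diff(t_h) * (utils::head(trace$glucose, -1) + utils::tail(trace$glucose, -1)) / 2)
}

#' Summarise a single starch-load curve
#'
#' Computes the per-load descriptors by which monitored starch loads are
#' tabulated: initial/maximum/end glucose, time to maximum and end time
#' (minutes from load start, i.e. the first sample), rising slope
#' `(max - initial) / t_max` and falling slope `(end - max) / (t_end - t_max)`
#' in mmol/L/h, total trapezoidal AUC, and the full [descriptive()] block.
#' On ties the earliest maximum is taken; when the maximum falls on the last
#' sample the falling slope is reported as 0 with `fall_degenerate = TRUE`.
#'
#' @param trace A CGM trace covering one load, starting at the load start.
#' @return A one-row tibble. Slopes are full precision; round at report time.
#' @examples
#' spec <- load_curve_spec(4.0, 8.4, 185, 3.0, 475)
#' load_summary(generate_load_curve(spec))[, c("slope_rise", "slope_fall")]
#' @export
load_summary <- function(trace) {
  if (nrow(trace) == 0) stop("empty load trace", call. = FALSE)
  t_min <- as.numeric(trace$timestamp - trace$timestamp[1], units = "mins")
  g <- trace$glucose
  i_max <- which.max(g) # earliest occurrence on ties
  t_max <- t_min[i_max]
  t_end <- t_min[length(t_min)]
  single <- length(g) < 2

  slope_rise <- if (single) {
    NA_real_
  } else if (t_max == 0) {
    0 # maximum at the first sample: no rising limb
  } else {
    (g[i_max] - g[1]) / (t_max / 60)
  }
  fall_degenerate <- !single && t_max == t_end
  slope_fall <- if (single) {
    NA_real_
  } else if (fall_degenerate) {
    0
  } else {
    (g[length(g)] - g[i_max]) / ((t_end - t_max) / 60)
  }

  dplyr::bind_cols(
    tibble::tibble(
      initial = g[1],
      max_value = g[i_max],
      t_max_min = t_max,
      end_time_min = t_end,
      end_value = g[length(g)],
      slope_rise = slope_rise,
      slope_fall = slope_fall,
      fall_degenerate = fall_degenerate,
      auc = if (single) NA_real_ else auc_trapezoid(trace)
    ),
    descriptive(trace)
  )
}

#' Compare crossover arms with per-patient pairing
#'
#' Per-arm means are taken over all available loads in each arm (patients
#' with a missing opposite arm still contribute to their own arm's mean); the
#' two-tailed paired t-test uses only patients with both arms. This is the
#' convention under which published group tables of a partial crossover are
#' internally consistent.
#'
#' @param loads A tibble with columns `patient`, `arm`, and the metric
#'   column(s); one row per load (at most one per patient per arm).
#' @param metrics Character vector of metric column names to compare.
#' @return A tibble with one row per metric: arm labels and means, per-arm
#'   load counts, `n_pairs`, `mean_diff` (arm A minus arm B over complete
#'   pairs), `t_stat` and `p_value` (two-tailed; `NA` with fewer than 2
#'   complete pairs).
#' @export
compare_arms <- function(loads, metrics) {
  stopifnot(all(c("patient", "arm") %in% names(loads)))
  arms <- sort(unique(loads$arm))
  if (length(arms) != 2) stop("need exactly 2 arms, got ", length(arms), call. = FALSE)
  missing <- setdiff(metrics, names(loads))
  if (length(missing) > 0) {
    stop("metric column(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(metrics, function(m) {
    a <- loads[loads$arm == arms[1] & !is.na(loads[[m]]), ]
    b <- loads[loads$arm == arms[2] & !is.na(loads[[m]]), ]
    paired <- dplyr::inner_join(
      a[, c("patient", m)], b[, c("patient", m)],
      by = "patient", suffix = c("_a", "_b")
    )
    n_pairs <- nrow(paired)
    if (n_pairs >= 2) {
      tt <- stats::t.test(paired[[paste0(m, "_a")]], paired[[paste0(m, "_b")]],
        paired = TRUE
      )
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
      md <- unname(tt$estimate)
    } else {
      t_stat <- p <- md <- NA_real_
    }
    tibble::tibble(
      metric = m,
      arm_a = arms[1], arm_b = arms[2],
      mean_a = mean(a[[m]]), mean_b = mean(b[[m]]),
      n_a = nrow(a), n_b = nrow(b),
      n_pairs = n_pairs, mean_diff = md,
      t_stat = t_stat, p_value = p
    )
  })
}

#' Reference starch-load descriptors (published crossover study)
#'
#' Per-patient, per-arm curve descriptors from a randomized double-blind
#' crossover of uncooked cornstarch (UCCS) versus an extended-release starch
#' (Glycosade) in 11 hepatic GSD patients: 12-hour monitored starch loads
#' summarised exactly as [load_summary()] reports them. Two Glycosade loads
#' are incomplete (CGM started after the glucose peak) and carry `NA`
#' descriptors; they are excluded from paired analyses but their patients
#' still contribute UCCS loads to arm means.
#'
#' Used as the worked-example input for [compare_arms()] and as ground truth
#' for slope arithmetic: every complete row satisfies
#' `slope_rise = (max - initial)/(t_max/60)` and
#' `slope_fall = (end_value - max)/((end_time - t_max)/60)` to within one
#' unit of the printed decimal.
#'
#' @return A tibble with one row per load: `patient`, `age_y`, `sex`,
#'   `gsd_type`, `arm`, `n`, `median`, `min`, `max`, `range`, `sd`,
#'   `variance`, `cv_percent`, `initial`, `t_max_min`, `end_time_min`,
#'   `end_value`, `slope_rise`, `slope_fall`, `auc`.
#' @export
starch_load_reference <- function() {
  uccs <- tibble::tribble(
    ~patient, ~age_y, ~sex, ~gsd_type, ~n, ~median, ~min, ~max, ~sd, ~variance, ~cv_percent, ~initial, ~t_max_min, ~end_time_min, ~end_value, ~slope_rise, ~slope_fall, ~auc,
    "II-1", 22, "F", "Ia", 96, 5.0, 3.0, 8.4, 1.5, 2.3, 29.4, 4.0, 185, 475, 3.0, 1.4, -1.1, 41,
    "II-2", 8, "M", "IIIa", 93, 4.9, 3.6, 8.7, 1.4, 1.8, 26.4, 4.7, 40, 460, 3.6, 6.0, -0.7, 41,
    "II-3", 7, "M", "IIIa", 108, 4.9, 3.2, 7.9, 1.1, 1.1, 22.0, 4.9, 70, 535, 3.2, 2.5, -0.6, 45,
    "II-4", 2, "M", "IX", 98, 5.6, 4.1, 9.3, 1.0, 1.1, 17.5, 5.1, 100, 485, 5.2, 2.6, -0.6, 47,
    "II-5", 12, "M", "IX", 146, 4.3, 3.2, 8.1, 1.0, 0.9, 21.7, 5.0, 55, 725, 4.8, 3.4, -0.3, 55,
    "II-6", 13, "M", "IX", 146, 4.7, 3.3, 8.6, 1.0, 1.0, 20.4, 3.3, 40, 725, 4.3, 7.9, -0.4, 59,
    "II-7", 12, "F", "IIIa", 143, 4.4, 2.5, 7.4, 1.1, 1.2, 24.4, 4.9, 35, 710, 2.5, 4.4, -0.4, 54,
    "II-8", 15, "F", "Ia", 120, 5.4, 3.4, 6.2, 0.6, 0.4, 11.5, 3.4, 100, 595, 3.7, 1.7, -0.3, 52,
    "II-9", 2, "M", "IX", 86, 3.9, 2.0, 12.1, 2.5, 6.2, 56.8, 5.5, 40, 425, 2.5, 9.9, -1.5, 31,
    "II-10", 6, "M", "IX", 122, 5.0, 4.1, 10.2, 1.4, 2.0, 25.5, 5.2, 45, 605, 4.9, 6.6, -0.6, 55,
    "II-11", 10, "M", "IIIa", 120, 5.5, 4.3, 9.9, 1.2, 1.4, 20.3, 4.9, 50, 595, 4.3, 5.9, -0.6, 59
  )
  uccs$arm <- "UCCS"
  gly <- tibble::tribble(
    ~patient, ~age_y, ~sex, ~gsd_type, ~n, ~median, ~min, ~max, ~sd, ~variance, ~cv_percent, ~initial, ~t_max_min, ~end_time_min, ~end_value, ~slope_rise, ~slope_fall, ~auc,
    "II-1", 22, "F", "Ia", 96, 5.1, 3.1, 7.3, 1.1, 1.3, 21.2, 4.1, 215, 475, 3.1, 0.9, -1.0, 41,
    "II-2", 8, "M", "IIIa", 73, NA, NA, NA, NA, NA, NA, NA, NA, 550, 4.3, NA, NA, NA,
    "II-3", 7, "M", "IIIa", 61, NA, NA, NA, NA, NA, NA, NA, NA, 475, 4.7, NA, NA, NA,
    "II-4", 2, "M", "IX", 108, 4.7, 3.3, 7.9, 0.9, 0.9, 18.4, 4.9, 75, 535, 4.9, 2.5, -0.4, 44,
    "II-5", 12, "M", "IX", 146, 3.7, 3.2, 7.1, 0.9, 0.8, 22.5, 4.8, 40, 725, 4.8, 3.4, -0.2, 49,
    "II-6", 13, "M", "IX", 144, 5.2, 3.7, 7.5, 0.7, 0.5, 13.2, 3.7, 40, 715, 4.9, 5.7, -0.2, 63,
    "II-7", 12, "F", "IIIa", 108, 5.2, 3.6, 6.8, 0.9, 0.8, 18.4, 6.6, 90, 535, 3.7, 0.1, -0.4, 44,
    "II-8", 15, "F", "Ia", 122, 5.8, 4.7, 7.4, 0.7, 0.5, 12.1, 5.8, 115, 605, 5.0, 0.8, -0.3, 59,
    "II-9", 2, "M", "IX", 98, 4.7, 3.9, 8.7, 1.3, 1.8, 25.0, 4.1, 45, 485, 4.2, 6.1, -0.6, 42,
    "II-10", 6, "M", "IX", 122, 3.9, 3.2, 8.8, 1.2, 1.5, 27.3, 4.4, 60, 605, 3.8, 4.4, -0.6, 44,
    "II-11", 10, "M", "IIIa", 145, 5.9, 4.2, 9.7, 1.4, 2.1, 21.5, 7.8, 40, 725, 4.9, 2.8, -0.4, 78
  )
  gly$arm <- "Glycosade"
  out <- dplyr::bind_rows(uccs, gly)
  out$range <- out$max - out$min
  dplyr::select(
    out, "patient", "age_y", "sex", "gsd_type", "arm", "n", "median",
    "min", "max", "range", "sd", "variance", "cv_percent", "initial",
    "t_max_min", "end_time_min", "end_value", "slope_rise", "slope_fall", "auc"
  )
}
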