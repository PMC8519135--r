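#' First and second order derivatives of a glucose trace
#'
#' glucose' (rate of change) and glucose'' (rate of change of the rate) in
#' mmol/L per minute and per minute squared, using three-point finite
#' differences on the actual timestamp spacing: nonuniform central
#' differences on interior points (exact for quadratics) and one-sided
#' three-point formulas at the boundaries. Any pair of samples more than
#' `gap_factor` cadences apart breaks differentiation: the adjacent samples
#' are masked (`gap = TRUE`, derivatives `NA`).
#'
#' @param trace A CGM trace with at least 3 samples.
#' @param gap_factor Gap threshold in multiples of the nominal cadence
#'   (default 2).
#' @return The trace columns plus `d1`, `d2`, `gap`.
#' @export
derivatives <- function(trace, gap_factor = 2) {
  n <- nrow(trace)
  if (n < 2) stop("derivatives need at least 2 samples", call. = FALSE)
  t <- as.numeric(trace$timestamp - trace$timestamp[1], units = "mins")
  g <- trace$glucose
  cad <- trace_cadence(trace)

  d1 <- d2 <- rep(NA_real_, n)
  if (n >= 3) {
    h1 <- t[2:(n - 1)] - t[1:(n - 2)] # left spacing
    h2 <- t[3:n] - t[2:(n - 1)] # right spacing
    # slope form of the nonuniform 3-point stencils: exact through
    # quadratics, and constant/linear input gives exactly zero (no
    # cancellation noise to smear the derivative bins)
    s1 <- (g[2:(n - 1)] - g[1:(n - 2)]) / h1 # left slopes
    s2 <- (g[3:n] - g[2:(n - 1)]) / h2 # right slopes
    d1[2:(n - 1)] <- (h1 * s2 + h2 * s1) / (h1 + h2)
    d2[2:(n - 1)] <- 2 * (s2 - s1) / (h1 + h2)
    # one-sided boundary extrapolation of the same stencils
    d1[1] <- s1[1] - h1[1] * (s2[1] - s1[1]) / (h1[1] + h2[1])
    d1[n] <- s2[n - 2] + h2[n - 2] * (s2[n - 2] - s1[n - 2]) / (h1[n - 2] + h2[n - 2])
    d2[1] <- d2[2]
    d2[n] <- d2[n - 1]
  } else {
    d1[] <- (g[2] - g[1]) / (t[2] - t[1])
  }

  gap_after <- c(diff(t) > gap_factor * cad, FALSE)
  gap_before <- c(FALSE, diff(t) > gap_factor * cad)
  gap <- gap_after | gap_before
  d1[gap] <- NA_real_
  d2[gap] <- NA_real_

  out <- tibble::as_tibble(trace)
  out$d1 <- d1
  out$d2 <- d2
  out$gap <- gap
  rewrap_trace(out, trace)
}

#' CUSUM method A: deviation from a reference mean
#'
#' The cumulative sum `CUSUM_t = sum_{i<=t} (glucose_i - reference)`. With
#' `reference = "self"` (the interval's own mean) the terminal value is zero
#' by construction and the curve displays within-interval drifts; a fixed
#' reference mean taken from a baseline period instead displays sustained
#' departures from earlier behaviour across intervals.
#'
#' @param x A numeric glucose vector or a CGM trace/tibble with a `glucose`
#'   column.
#' @param reference `"self"` or a numeric reference mean (mmol/L).
#' @return For a numeric input, a numeric CUSUM vector; for a data frame, the
#'   input with `cusum` and `cusum_reference` columns.
#' @examples
#' cusum_a(c(4, 6, 5)) # -1 0 0
#' @export
cusum_a <- function(x, reference = "self") {
  v <- glucose_values(x)
  if (length(v) == 0) stop("empty series", call. = FALSE)
  ref <- if (identical(reference, "self")) mean(v) else {
    stopifnot(is.numeric(reference), length(reference) == 1)
    reference
  }
  cs <- cumsum(v - ref)
  if (!is.data.frame(x)) {
    return(cs)
  }
  out <- tibble::as_tibble(x)
  out$cusum <- cs
  out$cusum_reference <- ref
  out
}

#' Fit a per-patient hypercube predictor of glucose from its derivatives
#'
#' Bins the observed (glucose', glucose'') plane into an equal-width grid and
#' stores the mean observed glucose per cell: a nonparametric per-patient
#' regression of absolute glucose on its first and second derivatives
#' ("hypercube regression"). Prediction looks up the cell of a new
#' (glucose', glucose'') pair; an empty cell falls back to the nearest
#' nonempty cell by bin-index (Euclidean) distance, ties broken toward the
#' lower linear index.
#'
#' @param trace A CGM trace (derivatives are computed internally via
#'   [derivatives()]).
#' @param bins Integer vector `c(bins_d1, bins_d2)`, default `c(8, 8)`.
#' @return A `hypercube_model` with `edges_d1`, `edges_d2`, `cell_mean`,
#'   `cell_n` matrices and training metadata. Supports [predict()],
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_hypercube <- function(trace, bins = c(8, 8)) {
  stopifnot(length(bins) == 2, all(bins >= 1))
  d <- derivatives(trace)
  train <- d[!d$gap & !is.na(d$d1) & !is.na(d$d2), ]
  if (nrow(train) == 0) stop("no unmasked samples to train on", call. = FALSE)

  edges_d1 <- bin_edges(train$d1, bins[1])
  edges_d2 <- bin_edges(train$d2, bins[2])
  i1 <- bin_index(train$d1, edges_d1)
  i2 <- bin_index(train$d2, edges_d2)

  cell_mean <- matrix(NA_real_, bins[1], bins[2])
  cell_n <- matrix(0L, bins[1], bins[2])
  for (k in seq_len(nrow(train))) {
    cell_n[i1[k], i2[k]] <- cell_n[i1[k], i2[k]] + 1L
  }
  sums <- matrix(0, bins[1], bins[2])
  for (k in seq_len(nrow(train))) {
    sums[i1[k], i2[k]] <- sums[i1[k], i2[k]] + train$glucose[k]
  }
  cell_mean[cell_n > 0] <- sums[cell_n > 0] / cell_n[cell_n > 0]

  structure(
    list(
      edges_d1 = edges_d1, edges_d2 = edges_d2,
      cell_mean = cell_mean, cell_n = cell_n,
      bins = as.integer(bins), n_train = nrow(train),
      patient_id = trace_patient(trace),
      train_range = range(train$glucose)
    ),
    class = "hypercube_model"
  )
}

bin_edges <- function(x, k) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5) * 1e-8 # degenerate spread
  seq(r[1], r[2], length.out = k + 1)
}

bin_index <- function(x, edges) {
  k <- length(edges) - 1
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(idx, 1L), k)
}

#' @export
print.hypercube_model <- function(x, ...) {
  cat(
    "<hypercube model: ", x$bins[1], "x", x$bins[2], " bins over (glucose', glucose''), ",
    sum(x$cell_n > 0), " nonempty cells, n_train = ", x$n_train, ">\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_hypercube
#' @param object A fitted `hypercube_model`.
#' @param newdata A CGM trace, or a data frame with `d1` and `d2` columns.
#' @param ... Unused.
#' @export
predict.hypercube_model <- function(object, newdata, ...) {
  if (!all(c("d1", "d2") %in% names(newdata))) {
    newdata <- derivatives(newdata)
  }
  i1 <- bin_index(newdata$d1, object$edges_d1)
  i2 <- bin_index(newdata$d2, object$edges_d2)
  nonempty <- which(object$cell_n > 0, arr.ind = TRUE)
  pred <- rep(NA_real_, nrow(newdata))
  for (k in seq_len(nrow(newdata))) {
    if (is.na(newdata$d1[k]) || is.na(newdata$d2[k])) next
    if (object$cell_n[i1[k], i2[k]] > 0) {
      pred[k] <- object$cell_mean[i1[k], i2[k]]
    } else {
      dist2 <- (nonempty[, 1] - i1[k])^2 + (nonempty[, 2] - i2[k])^2
      best <- which(dist2 == min(dist2))
      # tie-break: lower linear (column-major) index
      lin <- (nonempty[best, 2] - 1) * object$bins[1] + nonempty[best, 1]
      cell <- nonempty[best[which.min(lin)], , drop = FALSE]
      pred[k] <- object$cell_mean[cell[1], cell[2]]
    }
  }
  pred
}

#' @exportS3Method generics::tidy
tidy.hypercube_model <- function(x, ...) {
  nonempty <- which(x$cell_n > 0, arr.ind = TRUE)
  tibble::tibble(
    bin_d1 = nonempty[, 1],
    bin_d2 = nonempty[, 2],
    d1_mid = (x$edges_d1[nonempty[, 1]] + x$edges_d1[nonempty[, 1] + 1]) / 2,
    d2_mid = (x$edges_d2[nonempty[, 2]] + x$edges_d2[nonempty[, 2] + 1]) / 2,
    n = x$cell_n[nonempty],
    glucose_mean = x$cell_mean[nonempty]
  )
}

#' @exportS3Method generics::glance
glance.hypercube_model <- function(x, ...) {
  tibble::tibble(
    bins_d1 = x$bins[1], bins_d2 = x$bins[2],
    n_cells = prod(x$bins), n_nonempty = sum(x$cell_n > 0),
    n_train = x$n_train,
    glucose_min = x$train_range[1], glucose_max = x$train_range[2]
  )
}

#' CUSUM method B: residuals against the patient's own dynamics
#'
#' `CUSUM_t = sum_{i<=t} (glucose_calculated_i - glucose_i)`, where
#' `glucose_calculated` is the [fit_hypercube()] prediction from the first
#' and second derivatives. A sustained positive trend means observed glucose
#' runs below what the patient's own dynamics predict, and vice versa.
#' Gap-masked samples contribute a zero increment and are flagged.
#'
#' @param trace A CGM trace.
#' @param model A fitted `hypercube_model` (typically trained on a baseline
#'   period of the same patient).
#' @return The trace columns plus `d1`, `d2`, `gap`, `predicted`, `residual`
#'   (predicted minus observed; 0 where masked) and `cusum`.
#' @export
cusum_b <- function(trace, model) {
  if (!inherits(model, "hypercube_model")) {
    stop("`model` must be a fitted hypercube_model", call. = FALSE)
  }
  d <- derivatives(trace)
  pred <- predict(model, d)
  resid <- pred - d$glucose
  resid[is.na(resid)] <- 0 # masked samples contribute nothing
  out <- tibble::as_tibble(d)
  out$predicted <- pred
  out$residual <- resid
  out$cusum <- cumsum(resid)
  rewrap_trace(out, trace)
}

#' Plot a CUSUM series
#'
#' @param data Output of [cusum_a()] (data-frame form) or [cusum_b()].
#' @return A ggplot object.
#' @export
plot_cusum <- function(data) {
  stopifnot("cusum" %in% names(data))
  x <- if ("timestamp" %in% names(data)) data$timestamp else seq_len(nrow(data))
  ggplot2::ggplot(data, ggplot2::aes(x = x, y = .data$cusum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = NULL, y = "CUSUM (mmol/L \u00b7 samples)")
}
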