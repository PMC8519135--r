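test_that("derivatives vanish on constants and are exact on ramps and quadratics", {
  const <- uniform_trace(rep(5, 20))
  d <- derivatives(const)
  expect_true(all(d$d1 == 0))
  expect_true(all(d$d2 == 0))

  ramp <- uniform_trace(4 + 0.1 * (0:19)) # +0.1 mmol/L per 5-min step
  dr <- derivatives(ramp)
  expect_equal(dr$d1, rep(0.02, 20), tolerance = 1e-12)
  expect_equal(dr$d2, rep(0, 20), tolerance = 1e-12)

  a <- 2e-4
  t_min <- 5 * (0:30)
  quad <- uniform_trace(4 + a * t_min^2)
  dq <- derivatives(quad)
  expect_equal(dq$d2, rep(2 * a, 31), tolerance = 1e-9) # exact for quadratics
  expect_equal(dq$d1, 2 * a * t_min, tolerance = 1e-9)
})

test_that("differentiation is linear and respects gap masking", {
  set.seed(31)
  x <- uniform_trace(stats::runif(40, 4, 8))
  y <- uniform_trace(stats::runif(40, 4, 8))
  comb <- uniform_trace(2 * x$glucose + 3 * y$glucose)
  expect_equal(
    derivatives(comb)$d1, 2 * derivatives(x)$d1 + 3 * derivatives(y)$d1
  )
  # a 30-min hole masks the samples flanking it
  gapped <- inject_gaps(uniform_trace(stats::runif(60, 4, 8)), list(c(1, 1.5)))
  dg <- derivatives(gapped)
  expect_true(any(dg$gap))
  expect_true(all(is.na(dg$d1[dg$gap])))
  expect_true(all(!is.na(dg$d1[!dg$gap])))
  expect_error(derivatives(uniform_trace(5)), "2 samples")
})

test_that("method-A CUSUM matches hand computation and self-terminates at zero", {
  expect_equal(cusum_a(c(4, 6, 5)), c(-1, 0, 0))
  expect_equal(cusum_a(rep(5, 10), reference = 5), rep(0, 10))
  set.seed(77)
  for (i in 1:50) {
    v <- stats::runif(sample(2:300, 1), 2.2, 12)
    expect_equal(cusum_a(v)[length(v)], 0, tolerance = 1e-10)
  }
  # translation covariance: shifting values and reference together
  v <- stats::runif(50, 3, 9)
  expect_equal(cusum_a(v, reference = 5), cusum_a(v + 2, reference = 7))
})

test_that("CUSUM on a trace returns the series alongside its reference", {
  tr <- uniform_trace(c(4, 6, 5))
  out <- cusum_a(tr)
  expect_equal(out$cusum, c(-1, 0, 0))
  expect_equal(out$cusum_reference[1], 5)
  out2 <- cusum_a(tr, reference = 4)
  expect_equal(out2$cusum, c(0, 2, 3))
})

test_that("a constant trace fits a single-cell hypercube that predicts it", {
  const <- uniform_trace(rep(5.5, 30))
  m <- fit_hypercube(const)
  expect_equal(sum(m$cell_n > 0), 1) # all derivatives exactly (0, 0)
  expect_equal(unique(stats::predict(m, const)), 5.5)
  cb <- cusum_b(const, m)
  expect_true(all(cb$cusum == 0))
})

test_that("the hypercube separates dynamical regimes on a two-slope toy", {
  # alternating ramps of slope +s and -s: two derivative regimes
  s <- 0.04 # mmol/L per minute
  seg <- 12
  v <- 5 + cumsum(rep(c(rep(s * 5, seg), rep(-s * 5, seg)), 8))
  tr <- uniform_trace(v)
  m <- fit_hypercube(tr, bins = c(8, 8))
  d <- derivatives(tr)
  up <- stats::predict(m, d[which(abs(d$d1 - s) < 1e-9), ])
  down <- stats::predict(m, d[which(abs(d$d1 + s) < 1e-9), ])
  expect_gte(sum(m$cell_n > 0), 2)
  expect_false(isTRUE(all.equal(mean(up), mean(down))))
})

test_that("method-B residuals sum to zero over the training trace", {
  cfg <- synth_config(
    baseline = 5.5, components = sinusoid(0.4, 1.2), noise_sd = 0.15,
    duration_h = 24, seed = 5
  )
  tr <- generate_trace(cfg)
  m <- fit_hypercube(tr)
  cb <- cusum_b(tr, m)
  expect_equal(mean(cb$residual), 0, tolerance = 1e-6)
  expect_equal(cb$cusum[nrow(cb)], 0, tolerance = 1e-4)
})

test_that("method-B CUSUM stays trendless on training data but drifts on shifts", {
  # noise-free sinusoid over 10 cycles: the model tracks its own dynamics
  tr <- generate_trace(synth_config(
    baseline = 6, components = sinusoid(1, 1), duration_h = 10, cadence_min = 5
  ))
  m <- fit_hypercube(tr)
  cb <- cusum_b(tr, m)
  drift <- stats::coef(stats::lm(cb$cusum ~ seq_len(nrow(cb))))[2]
  expect_lt(abs(drift), 0.01) # no per-sample trend
  # +1 mmol/L shift: residual -1 per sample accumulates linearly
  shifted <- tr
  shifted$glucose <- shifted$glucose + 1
  cbs <- cusum_b(shifted, m)
  expect_equal(cbs$cusum[nrow(cbs)], -nrow(cbs), tolerance = 0.05 * nrow(cbs))
  expect_error(cusum_b(tr, list()), "hypercube_model")
})

test_that("hypercube models expose tidy and glance summaries", {
  tr <- generate_trace(synth_config(
    baseline = 5, components = sinusoid(0.5, 1), noise_sd = 0.1,
    duration_h = 24, seed = 8
  ))
  m <- fit_hypercube(tr, bins = c(6, 4))
  td <- tidy(m)
  expect_true(all(c("bin_d1", "bin_d2", "n", "glucose_mean") %in% names(td)))
  expect_equal(sum(td$n), m$n_train)
  gl <- glance(m)
  expect_equal(gl$n_cells, 24)
  expect_equal(gl$n_nonempty, nrow(td))
  # cell means stay inside the training range
  expect_true(all(td$glucose_mean >= gl$glucose_min - 1e-12))
  expect_true(all(td$glucose_mean <= gl$glucose_max + 1e-12))
})

test_that("empty-cell predictions fall back to the nearest populated cell", {
  tr <- generate_trace(synth_config(
    baseline = 5, components = sinusoid(0.5, 1), duration_h = 24
  ))
  m <- fit_hypercube(tr, bins = c(8, 8))
  # probe far outside the observed derivative range
  probe <- tibble::tibble(d1 = c(-10, 10), d2 = c(-10, 10))
  p <- stats::predict(m, probe)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= m$train_range[1] & p <= m$train_range[2]))
})
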