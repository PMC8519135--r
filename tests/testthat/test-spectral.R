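sin_window <- function(amplitude = 1, freq_cph = 1, baseline = 5, n = 48,
                       cadence_min = 5, phase = 0) {
  t_h <- (seq_len(n) - 1) * cadence_min / 60
  baseline + amplitude * sin(2 * pi * freq_cph * t_h + phase)
}

test_that("a constant window has an all-zero amplitude spectrum", {
  sp <- amplitude_spectrum(rep(5, 48), cadence_min = 5)
  expect_equal(nrow(sp), 24) # floor(n/2) bins
  expect_true(all(abs(sp$amplitude) < 1e-12))
})

test_that("bin-aligned sinusoids are recovered at exactly their amplitude", {
  sp <- amplitude_spectrum(sin_window(1, 1), cadence_min = 5)
  expect_equal(sp$amplitude[sp$k == 4], 1, tolerance = 1e-9) # 1 c/h over 4 h
  expect_equal(sp$frequency_cph[sp$k == 4], 1)
  expect_true(all(abs(sp$amplitude[sp$k != 4]) < 1e-9))
  # linearity: two bin-aligned components superpose without cross-talk
  two <- sin_window(0.8, 0.5) + sin_window(0.3, 2, baseline = 0)
  sp2 <- amplitude_spectrum(two, cadence_min = 5)
  expect_equal(sp2$amplitude[sp2$k == 2], 0.8, tolerance = 1e-9)
  expect_equal(sp2$amplitude[sp2$k == 8], 0.3, tolerance = 1e-9)
  expect_true(all(abs(sp2$amplitude[!sp2$k %in% c(2, 8)]) < 1e-9))
})

test_that("the frequency axis maps bins to cycles per hour and per night", {
  # 3 cycles per 4-h night = 0.75 cycles/hour at bin k = 3
  sp <- amplitude_spectrum(sin_window(1, 0.75), cadence_min = 5)
  peak <- sp[which.max(sp$amplitude), ]
  expect_equal(peak$k, 3)
  expect_equal(peak$frequency_cph, 0.75)
  comp <- detect_components(sp)
  expect_equal(comp$cycles_per_night[comp$dominant], 3)
})

test_that("spectral energy is conserved (Parseval, with the Nyquist convention)", {
  set.seed(14)
  for (i in 1:20) {
    v <- stats::runif(48, 3, 9)
    centred <- v - mean(v)
    sp <- amplitude_spectrum(v, cadence_min = 5)
    amp <- sp$amplitude
    nyq <- length(amp)
    energy <- sum((amp[-nyq] / 2)^2 * 2) + (amp[nyq] / 2)^2
    expect_equal(mean(centred^2), energy, tolerance = 1e-6)
  }
})

test_that("amplitude recovery degrades gracefully under sensor noise", {
  errs <- vapply(1:25, function(s) {
    tr <- generate_trace(synth_config(
      baseline = 5, components = sinusoid(1, 1), noise_sd = 0.2,
      duration_h = 4, seed = s
    ))
    sp <- amplitude_spectrum(tr)
    abs(sp$amplitude[sp$k == 4] - 1)
  }, numeric(1))
  expect_lt(mean(errs), 0.1) # within 10% on average at sd 0.2, n = 48
})

test_that("component detection counts peaks, not leakage, and breaks ties low", {
  sp <- amplitude_spectrum(sin_window(1, 1), cadence_min = 5)
  comp <- detect_components(sp)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$frequency_cph, 1)
  # all-zero spectrum: nothing detected
  expect_equal(nrow(detect_components(amplitude_spectrum(rep(5, 48)))), 0)
  # two equal-amplitude components: dominant is the lower frequency
  two <- sin_window(0.6, 0.5) + sin_window(0.6, 2, baseline = 0)
  c2 <- detect_components(amplitude_spectrum(two, cadence_min = 5))
  expect_equal(nrow(c2), 2)
  expect_equal(c2$frequency_cph[c2$dominant], 0.5)
  # non-bin-aligned component: leakage lobes are not counted as components
  leaky <- 5 + sin(2 * pi * 1.13 * (0:47) * 5 / 60)
  cl <- detect_components(amplitude_spectrum(leaky, cadence_min = 5))
  expect_lte(nrow(cl), 2)
})

test_that("raising the threshold never increases the component count", {
  set.seed(21)
  v <- 5 + 0.9 * sin(2 * pi * (0:47) / 12) + stats::rnorm(48, sd = 0.3)
  sp <- amplitude_spectrum(v, cadence_min = 5)
  counts <- vapply(
    seq(0.05, 1, by = 0.05),
    function(th) nrow(detect_components(sp, threshold = th)), numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("the spectrogram stacks one spectrum per eligible night", {
  tr <- generate_trace(synth_config(
    baseline = 5, components = sinusoid(1, 1), duration_h = 7 * 24
  ))
  sg <- build_spectrogram(tr)
  expect_s3_class(sg, "cgm_spectrogram")
  expect_equal(length(unique(sg$night)), 7)
  st <- stability_summary(sg)
  expect_equal(nrow(st), 7)
  expect_true(all(st$n_frequencies == 1))
  expect_true(all(st$dominant_frequency_cph == 1))
  expect_equal(st$dominant_amplitude, rep(1, 7), tolerance = 1e-9)
  expect_equal(st$dominant_cycles_per_night, rep(4, 7))
})

test_that("incomplete nights are excluded and quiet nights detect nothing", {
  tr <- generate_trace(synth_config(
    baseline = 5, components = sinusoid(1, 1), duration_h = 3 * 24
  ))
  # hollow out most of night 2's window
  holey <- inject_gaps(tr, list(c(25, 28)))
  expect_message(sg <- build_spectrogram(holey), "excluded")
  expect_equal(length(unique(sg$night)), 2)
  expect_equal(nrow(attr(sg, "excluded")), 1)
  # a flat night yields zero components in the stability table
  flat_night <- generate_trace(synth_config(baseline = 5, duration_h = 24))
  st <- stability_summary(build_spectrogram(flat_night))
  expect_equal(st$n_frequencies, 0)
  expect_true(is.na(st$dominant_frequency_cph))
  # empty trace: empty spectrogram with a warning
  empty <- uniform_trace(rep(5, 10), start = t0("12:00:00"))
  expect_warning(sge <- build_spectrogram(empty), "no eligible nights")
  expect_equal(nrow(sge), 0)
})

test_that("an injected extra component raises that night's frequency count", {
  base <- synth_config(
    baseline = 5, components = sinusoid(1, 1), duration_h = 24
  )
  night1 <- generate_trace(base)
  cfg2 <- synth_config(
    baseline = 5, components = sinusoid(c(1, 3), c(1, 0.6)), duration_h = 24,
    start = as.POSIXct("2024-01-02 00:00:00", tz = "UTC")
  )
  night2 <- generate_trace(cfg2)
  both <- as_cgm_trace(dplyr::bind_rows(
    tibble::as_tibble(night1), tibble::as_tibble(night2)
  ))
  st <- stability_summary(build_spectrogram(both))
  expect_equal(st$n_frequencies, c(1, 2))
  # amplitude doubling doubles the dominant amplitude (DFT linearity)
  dbl <- generate_trace(synth_config(
    baseline = 5, components = sinusoid(1, 2), duration_h = 24
  ))
  st2 <- stability_summary(build_spectrogram(dbl))
  expect_equal(st2$dominant_amplitude, 2, tolerance = 1e-9)
})

test_that("too-short windows are refused", {
  expect_error(amplitude_spectrum(rep(5, 5)), "too short")
})
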