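mk_trace <- function(x, fs = 1000, units = "nA") {
  pe_trace(seq(0, by = 1 / fs, length.out = length(x)), x, units = units)
}

test_that("median detrending preserves constants and flattens ramps", {
  const <- mk_trace(rep(2.5, 5000))
  expect_equal(detrend_trace(const)$x, rep(2.5, 5000))
  # slow ramp: interior becomes the global mean
  ramp <- mk_trace(seq(0, 1, length.out = 8000))
  d <- detrend_trace(ramp)
  interior <- d$x[2000:6000]
  expect_lt(max(abs(interior - mean(ramp$x))), 1e-6)
})

test_that("brief events survive median detrending nearly intact", {
  set.seed(1)
  n <- 10000
  x <- rnorm(n, 0, 0.01)
  bump <- 3000:3100  # 100 ms bump of 0.3 nA
  x[bump] <- x[bump] + 0.3
  d <- detrend_trace(mk_trace(x))
  expect_gt(max(d$x[bump]), 0.27)  # amplitude essentially intact
})

test_that("candidate detection finds isolated events and merges close ones", {
  set.seed(2)
  fs <- 1000
  x <- rnorm(30 * fs, 0, 0.01)
  starts <- c(5, 15, 25)
  for (s in starts) {
    idx <- (s * fs):(s * fs + 300)
    x[idx] <- x[idx] + 0.3
  }
  tr <- detrend_trace(mk_trace(x, fs))
  cand <- detect_candidates(tr)
  expect_equal(nrow(cand), 3L)
  for (i in seq_along(starts)) {
    expect_lte(cand$start[i], starts[i])
    expect_gte(cand$end[i], starts[i] + 0.3)
  }
  # flat noise alone yields nothing
  quiet <- detrend_trace(mk_trace(rnorm(10 * fs, 0, 0.01), fs))
  expect_equal(nrow(detect_candidates(quiet)), 0L)
  # two excursions 100 ms apart merge through their padding
  y <- rnorm(10 * fs, 0, 0.01)
  y[3000:3200] <- y[3000:3200] + 0.3
  y[3300:3500] <- y[3300:3500] + 0.3
  tr2 <- detrend_trace(mk_trace(y, fs))
  expect_equal(nrow(detect_candidates(tr2)), 1L)
})

test_that("event refinement anchors the start before the upstroke", {
  fs <- 1000
  n <- 12 * fs
  x <- numeric(n)
  rise_at <- 4 * fs
  seg <- rise_at:(rise_at + 399)
  x[seg] <- seq(0, 0.4, length.out = 400)           # rise
  x[(rise_at + 400):(rise_at + 799)] <- 0.4          # plateau
  dec <- (rise_at + 800):(rise_at + 1199)
  x[dec] <- seq(0.4, 0, length.out = 400)            # decay, then flat
  tr <- mk_trace(x, fs)
  ev <- refine_event(tr, list(start = 3.5, end = 5.8))
  expect_false(ev$flagged)
  expect_equal(ev$start, 4 - 0.2, tolerance = 2 / fs)
  expect_gte(ev$end, 5.1)
  # idempotent on its own output
  ev2 <- refine_event(tr, list(start = ev$start, end = ev$end))
  expect_equal(ev2$start, ev$start, tolerance = 1e-12)
  expect_equal(ev2$end, ev$end, tolerance = 1e-12)
})

test_that("monotone traces with no flat tail are flagged", {
  tr <- mk_trace(seq(0, 1, length.out = 4000))
  ev <- refine_event(tr, list(start = 0.5, end = 3.5))
  expect_true(ev$flagged)
  expect_equal(ev$end, 3.5)
})

test_that("first-order smoothing behaves as a moving average", {
  fs <- 10000
  ramp <- mk_trace(seq(0, 1, length.out = 2 * fs), fs)
  expect_equal(denoise_trace(ramp)$x[200:19800], ramp$x[200:19800],
               tolerance = 1e-9)
  set.seed(3)
  noise <- mk_trace(rnorm(fs), fs)
  sm <- denoise_trace(noise)
  win <- round(0.01 * fs) + 1  # 101-point window
  expect_equal(var(sm$x[500:9500]), var(noise$x) / win, tolerance = 0.3)
  # a 200 Hz sinusoid is strongly attenuated
  t <- seq(0, 1, by = 1 / fs)
  s200 <- denoise_trace(mk_trace(sin(2 * pi * 200 * t), fs))
  expect_lt(max(abs(s200$x[1000:9000])), 1 / 10)
})

test_that("Welch spectra localise a pure tone and normalise to unit area", {
  fs <- 1000
  x <- sin(2 * pi * 6 * seq(0, 3, by = 1 / fs))
  sp <- welch_psd(x, fs, unit_area = TRUE)
  expect_equal(sp$frequency_hz[which.max(sp$power)], 6, tolerance = 0.3)
  df <- sp$frequency_hz[2] - sp$frequency_hz[1]
  expect_equal(sum(sp$power) * df, 1, tolerance = 1e-10)
  expect_true(all(sp$power >= 0))
})

test_that("event spectra skip too-short events with a warning", {
  tr <- mk_trace(rnorm(3000))
  expect_warning(out <- event_spectrum(tr, list(start = 0.1, end = 0.2)),
                 "skipped")
  expect_null(out)
})

test_that("averaged spectra are max-one and unit-scale invariant", {
  set.seed(4)
  g <- generate_trace(synth_spec(duration_s = 30, event_rate = 0.3,
                                 rhythm_fraction = 1, seed = 8))
  det <- detrend_trace(g$trace)
  sp <- event_spectra(det, g$truth)
  expect_equal(max(sp$power), 1)
  # scaling the signal leaves the normalised spectrum unchanged
  det10 <- pe_trace(det$t, det$x * 10, units = "nA")
  sp10 <- event_spectra(det10, g$truth)
  expect_equal(sp$power, sp10$power, tolerance = 1e-10)
})

test_that("peak classification separates rhythm, lobe and noise", {
  fs <- 1000
  # rhythmic: envelope plus 6 Hz modulation
  tt <- seq(0, 0.9, by = 1 / fs)
  env <- exp(-tt / 0.25) - exp(-tt / 0.05)
  rhythmic <- env * (1 + 0.8 * sin(2 * pi * 6 * tt))
  sp_r <- welch_psd(rhythmic, fs, unit_area = TRUE)
  expect_equal(classify_peak(sp_r)$peak_hz, 6, tolerance = 1)
  # arrhythmic: bare envelope has only the low-frequency lobe
  sp_a <- welch_psd(env, fs, unit_area = TRUE)
  cl_a <- classify_peak(sp_a)
  expect_true(is.na(cl_a$peak_hz))
  expect_false(is.na(cl_a$fwhm_hz))
  # white noise averaged over events: flat, no peak
  set.seed(5)
  specs <- lapply(1:8, function(i) welch_psd(rnorm(800), fs, unit_area = TRUE))
  avg <- list(frequency_hz = specs[[1]]$frequency_hz,
              power = rowMeans(sapply(specs, function(s) s$power)))
  expect_true(is.na(classify_peak(avg)$peak_hz))
})

test_that("label-shuffled pair correlation behaves at its extremes", {
  ident <- data.frame(f1 = c(3, 6, 9, 11), f2 = c(3, 6, 9, 11))
  r <- peak_pair_correlation(ident, n_shuffles = 200, seed = 1)
  expect_equal(r$mean, 1)
  expect_equal(r$median, 1)
  set.seed(6)
  indep <- data.frame(f1 = runif(40, 2, 12), f2 = runif(40, 2, 12))
  r0 <- peak_pair_correlation(indep, n_shuffles = 500, seed = 2)
  expect_lt(abs(r0$mean), 0.25)
  shared <- runif(12, 3, 11)
  jit <- data.frame(f1 = shared + rnorm(12, 0, 0.3),
                    f2 = shared + rnorm(12, 0, 0.3))
  rj <- peak_pair_correlation(jit, n_shuffles = 500, seed = 3)
  expect_gt(rj$mean, 0.8)
  expect_error(peak_pair_correlation(data.frame(f1 = 1:2, f2 = 1:2)),
               "at least 3")
})
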