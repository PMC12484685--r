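# Intracellular-trace analysis: detrending, two-pass event detection,
# denoising, within-event Welch spectra, rhythmicity classification and
# paired-recording peak correlation.

#' Detrend a recording with a running median
#'
#' Removes slow non-stationarity by subtracting the centred running median
#' (window `window_s`, default 3 s) re-anchored at the global mean:
#' \eqn{\hat x(t) = x(t) - (med_w[x](t) - \langle x \rangle)}.  The running
#' median is robust to brief event excursions, so events pass through nearly
#' unchanged while baseline drift is removed.  Edges use shrinking windows.
#'
#' @param trace A [pe_trace()].
#' @param window_s Median window width in seconds.
#' @return Detrended [pe_trace()].
#' @export
detrend_trace <- function(trace, window_s = 3) {
  fs <- trace_fs(trace)
  k <- round(window_s * fs)
  if (k %% 2 == 0) k <- k + 1L
  if (k >= nrow(trace))
    stop("trace shorter than the detrending window", call. = FALSE)
  med <- as.numeric(runmed(trace$x, k, endrule = "median"))
  rebuild_trace(trace, trace$x - (med - mean(trace$x)))
}

#' Default event-detection threshold by units
#'
#' 5 mV for current-clamp, 0.15 nA for voltage-clamp recordings.
#' @param units `"mV"` or `"nA"`.
#' @return Threshold in the trace units.
#' @export
default_threshold <- function(units) {
  switch(units, mV = 5, nA = 0.15,
         stop("unknown units: ", units, call. = FALSE))
}

#' First-pass detection of candidate event windows
#'
#' Finds contiguous periods where the detrended signal deviates from its
#' average by more than `threshold`, pads each period (200 ms before, 500 ms
#' after) and merges padded windows that overlap.
#'
#' @param trace A detrended [pe_trace()] (see [detrend_trace()]).
#' @param threshold Deviation threshold; defaults by units (5 mV / 0.15 nA).
#' @param pad_before,pad_after Padding in seconds.
#' @return Data frame with columns `start`, `end` (seconds); zero rows if
#'   nothing crosses threshold.
#' @export
detect_candidates <- function(trace, threshold = NULL,
                              pad_before = 0.2, pad_after = 0.5) {
  if (is.null(threshold)) threshold <- default_threshold(trace_units(trace))
  dev <- abs(trace$x - mean(trace$x))
  above <- dev > threshold
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  win <- data.frame(start = trace$t[starts[runs]] - pad_before,
                    end = trace$t[ends[runs]] + pad_after)
  win$start <- pmax(win$start, trace$t[1])
  win$end <- pmin(win$end, trace$t[nrow(trace)])
  # merge overlapping padded windows
  merged <- win[1, , drop = FALSE]
  for (i in seq_len(nrow(win))[-1]) {
    if (win$start[i] <= merged$end[nrow(merged)]) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], win$end[i])
    } else {
      merged <- rbind(merged, win[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Refine a candidate window to event start and end
#'
#' Automates the by-eye marking rule: the event starts 200 ms before the
#' initial upstroke (first time the smoothed derivative exceeds 10% of the
#' window's maximum slope) and ends at the last point before the signal
#' returns to a roughly flat slope (absolute smoothed slope below 5% of the
#' maximum slope sustained for at least `flat_s` seconds).  If no qualifying
#' flat region exists the window end is kept and the event flagged.
#'
#' @param trace A detrended [pe_trace()].
#' @param window List or one-row data frame with `start` and `end` (seconds).
#' @param lead_s Lead time subtracted before the upstroke (seconds).
#' @param flat_s Required duration of the flat tail (seconds).
#' @param slope_frac,flat_frac Upstroke and flatness thresholds as fractions
#'   of the maximum in-window slope.
#' @return List of class `"event_window"`: `start`, `end`, `flagged`.
#' @export
refine_event <- function(trace, window, lead_s = 0.2, flat_s = 1,
                         slope_frac = 0.1, flat_frac = 0.05) {
  fs <- trace_fs(trace)
  sm <- denoise_trace(trace)
  slope <- c(0, diff(sm$x)) * fs
  i0 <- max(1L, which.min(abs(trace$t - window$start)))
  i1 <- min(nrow(trace), which.min(abs(trace$t - window$end)))
  smax <- max(abs(slope[i0:i1]))
  if (smax == 0)
    return(structure(list(start = window$start, end = window$end,
                          flagged = TRUE), class = "event_window"))
  up_rel <- which(slope[i0:i1] > slope_frac * smax)
  if (!length(up_rel))
    return(structure(list(start = window$start, end = window$end,
                          flagged = TRUE), class = "event_window"))
  iup <- i0 + up_rel[1] - 1L
  start <- max(trace$t[1], trace$t[iup] - lead_s)

  # scan forward (allowed to look slightly past the window) for a sustained
  # flat region; the event ends just before it starts
  flat_n <- round(flat_s * fs)
  scan_end <- min(nrow(trace), i1 + round(2 * flat_s * fs))
  is_flat <- abs(slope[iup:scan_end]) < flat_frac * smax
  r <- rle(is_flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= flat_n)
  if (length(ok)) {
    iflat <- iup + starts[ok[1]] - 1L
    end <- trace$t[max(i0, iflat - 1L)]
    flagged <- FALSE
  } else {
    end <- window$end
    flagged <- TRUE
  }
  structure(list(start = start, end = max(end, start + 1 / fs),
                 flagged = flagged), class = "event_window")
}

#' Smooth a trace with a first-order Savitzky-Golay filter
#'
#' First-order local polynomial smoothing over a window of roughly 10 ms
#' (rescaled to the sampling rate), equivalent to a centred moving average;
#' attenuates power above ~100 Hz.
#'
#' @param trace A [pe_trace()].
#' @param window_s Smoothing window in seconds (default 10 ms).
#' @return Smoothed [pe_trace()].
#' @export
denoise_trace <- function(trace, window_s = 0.01) {
  fs <- trace_fs(trace)
  n <- max(3L, round(window_s * fs))
  if (n %% 2 == 0) n <- n + 1L
  if (n >= nrow(trace)) n <- nrow(trace) - (1 - nrow(trace) %% 2)
  rebuild_trace(trace, signal::sgolayfilt(trace$x, p = 1, n = n))
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram: Hann-tapered segments with 50% overlap,
#' per-segment mean and linear-trend removal.  One-sided spectrum.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param seg_s Segment length in seconds (capped at the signal length).
#' @param overlap Fractional overlap between segments.
#' @param unit_area Normalise the power to unit area.
#' @return List with `frequency_hz` and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 1, overlap = 0.5, unit_area = FALSE,
                      pad = 4) {
  nseg <- min(length(x), max(8L, round(seg_s * fs)))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  tt <- seq_len(nseg)
  X <- cbind(1, tt)
  nfft <- nseg * max(1L, as.integer(pad))  # zero-padding refines the grid
  nout <- nfft %/% 2 + 1L
  acc <- numeric(nout)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- seg - lm.fit(X, seg)$fitted.values  # mean + linear trend
    P <- Mod(fft(c(seg * w, numeric(nfft - nseg))))^2
    acc <- acc + P[seq_len(nout)]
  }
  acc <- acc / length(starts)
  freq <- (seq_len(nout) - 1L) * fs / nfft
  if (unit_area) {
    df <- fs / nfft
    acc <- acc / (sum(acc) * df)
  }
  list(frequency_hz = freq, power = acc)
}

#' Within-event power spectrum
#'
#' Pipeline for a single event: denoise, restrict to the event window,
#' remove mean and linear trend, Welch periodogram, unit-area normalisation.
#'
#' @param trace A detrended [pe_trace()].
#' @param event An event window (list with `start`, `end`).
#' @param min_s Minimum event length in seconds; shorter events are skipped
#'   (returns `NULL` with a warning).
#' @param seg_s Welch segment length (capped at the event length; long
#'   enough that slow 2-3 Hz rhythms in multi-second events resolve from
#'   the envelope lobe).
#' @return List with `frequency_hz`, `power` (unit area), or `NULL`.
#' @export
event_spectrum <- function(trace, event, min_s = 0.25, seg_s = 2) {
  if (event$end - event$start < min_s) {
    warning(sprintf("event [%.3f, %.3f] shorter than %g s: skipped",
                    event$start, event$end, min_s), call. = FALSE)
    return(NULL)
  }
  sm <- denoise_trace(trace)
  sel <- sm$t >= event$start & sm$t <= event$end
  x <- sm$x[sel]
  welch_psd(x, trace_fs(trace), seg_s = min(seg_s, length(x) / trace_fs(trace)),
            unit_area = TRUE)
}

#' Average event spectra for a recording
#'
#' Computes the unit-area spectrum of every event, averages across events on
#' the frequency grid of the longest event, and normalises the average to a
#' maximum of one.
#'
#' @param trace A detrended [pe_trace()].
#' @param events Data frame of event windows (`start`, `end`).
#' @param ... Passed to [event_spectrum()].
#' @return List of class `"event_spectrum"` with `frequency_hz`, `power`
#'   (max 1), `n_events`, `peak_hz`.
#' @export
event_spectra <- function(trace, events, ...) {
  specs <- list()
  for (i in seq_len(nrow(events))) {
    s <- event_spectrum(trace, events[i, ], ...)
    if (!is.null(s)) specs[[length(specs) + 1L]] <- s
  }
  if (!length(specs))
    return(structure(list(frequency_hz = numeric(0), power = numeric(0),
                          n_events = 0L, peak_hz = NULL),
                     class = "event_spectrum"))
  lens <- vapply(specs, function(s) length(s$frequency_hz), integer(1))
  fgrid <- specs[[which.max(lens)]]$frequency_hz
  mat <- vapply(specs, function(s)
    approx(s$frequency_hz, s$power, fgrid, rule = 2)$y,
    numeric(length(fgrid)))
  avg <- rowMeans(mat)
  pow <- avg / max(avg)
  pk <- classify_peak(list(frequency_hz = fgrid, power = pow))
  structure(list(frequency_hz = fgrid, power = pow,
                 n_events = length(specs), peak_hz = pk$peak_hz),
            class = "event_spectrum")
}

#' Spectra of the non-event periods
#'
#' Applies the within-event spectral pipeline to every non-event period
#' longer than `min_s` (default 100 ms) and averages.
#'
#' @inheritParams event_spectra
#' @param min_s Minimum non-event period length (seconds).
#' @export
nonevent_spectra <- function(trace, events, min_s = 0.1, ...) {
  bounds <- c(trace$t[1], as.vector(t(events[, c("start", "end")])),
              trace$t[nrow(trace)])
  n <- length(bounds)
  gaps <- data.frame(start = bounds[seq(1, n - 1, by = 2)],
                     end = bounds[seq(2, n, by = 2)])
  gaps <- gaps[gaps$end - gaps$start > min_s, , drop = FALSE]
  event_spectra(trace, gaps, min_s = min_s, ...)
}

#' Classify a spectrum as peaked or non-peaked
#'
#' Searches a frequency band (default 1-20 Hz) of a max-one-normalised
#' spectrum for a local maximum that stands clear of the low-frequency
#' envelope lobe.  Event spectra always carry broad low-frequency power from
#' the event envelope itself, so a qualifying rhythm peak must be separated
#' from lower frequencies by an interior spectral valley (a local minimum at
#' `0 < f <` peak) whose depth is at least `prominence` of the peak height;
#' a monotone lobe whose maximum merely falls inside the band does not
#' qualify.  Flat, noise-like spectra are rejected up front by comparing the
#' in-band power with the power in the octave above the band.  Returns the
#' peak frequency, or `NA` plus the full-width-at-half-maximum of the
#' low-frequency lobe for non-peaked spectra.
#'
#' @param spectrum List with `frequency_hz` and `power`.
#' @param band Search band in Hz.
#' @param prominence Minimum depth of the separating valley as a fraction of
#'   the peak height.
#' @param smooth_hz Width of the moving-average smoothing applied before
#'   peak detection (suppresses raw-periodogram roughness; a genuine rhythm
#'   peak is wider than this for sub-second events).
#' @param flat_factor Flatness gate: the mean in-band power must exceed the
#'   mean power of the octave above the band by this factor, otherwise the
#'   spectrum carries no low-frequency structure at all (noise-like) and no
#'   peak is reported.
#' @param min_height Minimum peak height relative to the spectrum maximum
#'   (guards against spurious wiggles in the spectral tail).
#' @return List with `peak_hz` (`NA_real_` if none) and `fwhm_hz`.
#' @export
classify_peak <- function(spectrum, band = c(1, 20), prominence = 0.2,
                          smooth_hz = 1, flat_factor = 2, min_height = 0.1) {
  f <- spectrum$frequency_hz
  p <- spectrum$power
  if (!length(p)) return(list(peak_hz = NA_real_, fwhm_hz = NA_real_))
  if (length(f) > 2L && smooth_hz > 0) {
    df <- f[2] - f[1]
    k <- round(smooth_hz / df)
    if (k %% 2 == 0) k <- k + 1L
    if (k >= 3L && k < length(p)) {
      ps <- as.numeric(stats::filter(p, rep(1 / k, k), sides = 2))
      na <- is.na(ps)
      ps[na] <- p[na]
      p <- ps
    }
  }
  p <- p / max(p)
  n <- length(p)
  # FWHM of the low-frequency lobe
  half <- which(p >= 0.5)
  fwhm <- if (length(half)) diff(range(f[half])) else NA_real_
  in_band <- which(f >= band[1] & f <= band[2])
  if (length(in_band) < 3L) return(list(peak_hz = NA_real_, fwhm_hz = fwhm))
  hf <- which(f > band[2] & f <= 2 * band[2])
  if (length(hf) >= 5L &&
      mean(p[in_band]) <= flat_factor * mean(p[hf]))
    return(list(peak_hz = NA_real_, fwhm_hz = fwhm))  # flat, noise-like
  interior <- 2:(n - 1L)
  is_min <- c(FALSE, p[interior] <= p[interior - 1L] &
                     p[interior] <= p[interior + 1L], FALSE)
  is_max <- c(FALSE, p[interior] >= p[interior - 1L] &
                     p[interior] >= p[interior + 1L], FALSE)
  best_f <- NA_real_
  best_h <- -Inf
  for (i in intersect(in_band, which(is_max))) {
    valleys <- which(is_min[seq_len(i - 1L)])
    valleys <- valleys[valleys > 1L]  # DC bin is an edge, not a valley
    if (!length(valleys)) next
    depth <- p[i] - min(p[valleys])
    if (p[i] >= min_height && depth >= prominence * p[i] && p[i] > best_h) {
      best_h <- p[i]
      best_f <- f[i]
    }
  }
  list(peak_hz = best_f, fwhm_hz = fwhm)
}

#' Label-shuffled correlation of paired peak frequencies
#'
#' For simultaneously recorded channel pairs there is no natural assignment
#' of "cell 1" and "cell 2"; the Pearson correlation of peak frequencies is
#' therefore computed over random within-pair label assignments and the
#' distribution is summarised by its mean and median.
#'
#' @param pairs Data frame with columns `f1`, `f2` (peak frequencies in Hz;
#'   rows with any `NA` are dropped).
#' @param n_shuffles Number of random labelings.
#' @param seed Integer seed.
#' @return List with `correlations`, `mean`, `median`, `n_pairs`.
#' @export
peak_pair_correlation <- function(pairs, n_shuffles = 10000, seed = 1) {
  pairs <- pairs[stats::complete.cases(pairs[, c("f1", "f2")]), , drop = FALSE]
  n <- nrow(pairs)
  if (n < 3L)
    stop("need at least 3 pairs with peak frequencies", call. = FALSE)
  set.seed(seed)
  rho <- numeric(n_shuffles)
  f1 <- pairs$f1
  f2 <- pairs$f2
  for (k in seq_len(n_shuffles)) {
    flip <- runif(n) < 0.5
    a <- ifelse(flip, f2, f1)
    b <- ifelse(flip, f1, f2)
    rho[k] <- if (sd(a) == 0 || sd(b) == 0) 1 else cor(a, b)
  }
  list(correlations = rho, mean = mean(rho), median = median(rho),
       n_pairs = n)
}

#' Full detection pipeline on a raw trace
#'
#' Convenience wrapper: detrend, first-pass candidate detection, per-window
#' refinement, spectra and peak classification.
#'
#' @param trace Raw [pe_trace()].
#' @param threshold Detection threshold (defaults by units).
#' @param ... Passed to [detect_candidates()].
#' @return List with `events` (data frame `start`, `end`, `flagged`,
#'   `peak_hz`), `spectrum` (averaged event spectrum), `detrended` trace.
#' @export
detect_events <- function(trace, threshold = NULL, ...) {
  det <- detrend_trace(trace)
  cand <- detect_candidates(det, threshold = threshold, ...)
  if (!nrow(cand)) {
    return(list(events = data.frame(start = numeric(0), end = numeric(0),
                                    flagged = logical(0),
                                    peak_hz = numeric(0)),
                spectrum = NULL, detrended = det))
  }
  refined <- lapply(seq_len(nrow(cand)), function(i)
    refine_event(det, cand[i, ]))
  events <- data.frame(
    start = vapply(refined, `[[`, numeric(1), "start"),
    end = vapply(refined, `[[`, numeric(1), "end"),
    flagged = vapply(refined, `[[`, logical(1), "flagged"))
  events$peak_hz <- vapply(seq_len(nrow(events)), function(i) {
    s <- tryCatch(
      suppressWarnings(event_spectrum(det, events[i, ])),
      error = function(e) NULL)
    if (is.null(s)) NA_real_
    else classify_peak(s)$peak_hz
  }, numeric(1))
  avg <- suppressWarnings(event_spectra(det, events))
  list(events = events, spectrum = avg, detrended = det)
}
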