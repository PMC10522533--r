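# Largest prime factor of n.
largest_prime_factor <- function(n) {
  p <- 2L; mx <- 1L
  while (n > 1) {
    if (n %% p == 0) { mx <- max(mx, p); while (n %% p == 0) n <- n %/% p }
    p <- p + 1L
    if (p * p > n) { if (n > 1) mx <- max(mx, n); break }
  }
  mx
}

# The sample count within `dev` of n whose largest prime factor is
# smallest (ties: closest to n). Keeps FFTs fast for awkward durations.
fft_friendly_n <- function(n, dev = 2L) {
  cand <- n + c(0L, -1L, 1L, -2L, 2L)[seq_len(2L * dev + 1L)]
  cand[which.min(vapply(cand, function(x) as.numeric(largest_prime_factor(x)),
                        numeric(1)))]
}

# Evaluate the frequency response of an IIR filter (b, a) at angular
# frequencies w (radians/sample).
iir_response <- function(b, a, w) {
  zi <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- zi %*% b
  zi <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- zi %*% a
  as.vector(num / den)
}

# Apply a zero-phase filter to every row of a channels x samples matrix by
# multiplying the spectrum with the squared magnitude response |H(f)|^2 —
# the frequency-domain equivalent of forward-backward (filtfilt) filtering,
# vectorized across channels via mvfft.
zero_phase_filter_matrix <- function(data, rate, mag2) {
  n <- ncol(data)
  nfft <- stats::nextn(n, 2)   # zero-pad: fast FFT length, no circular wrap
  f <- (0:(nfft - 1)) * rate / nfft
  f <- pmin(f, rate - f)
  g <- mag2(2 * pi * f / rate)
  padded <- rbind(t(data), matrix(0, nfft - n, nrow(data)))
  sp <- stats::mvfft(padded) * g
  out <- t(Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft)
  dimnames(out) <- dimnames(data)
  out
}

# Squared magnitude response of the standard preprocessing chain:
# 4th-order Butterworth band-pass `band`, plus notches (2nd-order
# Butterworth band-stop, width `notch_width`) at each of `notches`.
preprocess_mag2 <- function(rate, band = c(0.1, 100), notches = c(50, 100),
                            notch_width = 0.5) {
  bp <- signal::butter(4, band / (rate / 2), type = "pass")
  nfs <- lapply(notches, function(f0)
    signal::butter(2, c(f0 - notch_width / 2, f0 + notch_width / 2) / (rate / 2),
                   type = "stop"))
  function(w) {
    g <- Mod(iir_response(bp$b, bp$a, w))^2
    for (nf in nfs) g <- g * Mod(iir_response(nf$b, nf$a, w))^2
    g
  }
}

#' Preprocess a raw EEG recording
#'
#' The standard preprocessing contract: zero-phase 4th-order Butterworth
#' band-pass from 0.1 to 100 Hz, zero-phase notch filters at 50 and 100 Hz
#' (0.5 Hz wide) against power-line noise, then down-sampling to 256 Hz.
#' Zero-phase filtering is applied in the frequency domain (the squared
#' Butterworth magnitude response, equivalent to forward-backward
#' filtering); because the band-pass limits content to 100 Hz, below the
#' 128 Hz target Nyquist, down-sampling is plain decimation.
#'
#' @param rec An [eeg_recording()] at 512 Hz.
#' @param band Band-pass edges in Hz (default `c(0.1, 100)`).
#' @param notches Notch centre frequencies in Hz (default `c(50, 100)`).
#' @param notch_width Width of each notch in Hz (default 0.5).
#' @param down_to Target sampling rate (default 256; must divide `rec$rate`).
#' @return The filtered, down-sampled [eeg_recording()].
#' @export
preprocess <- function(rec, band = c(0.1, 100), notches = c(50, 100),
                       notch_width = 0.5, down_to = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != 512)
    stop("preprocess expects a 512 Hz recording, got ", rec$rate, " Hz")
  if (rec$rate %% down_to != 0)
    stop("down_to must divide the recording rate")
  data <- zero_phase_filter_matrix(rec$data, rec$rate,
                                   preprocess_mag2(rec$rate, band, notches,
                                                   notch_width))
  dec <- rec$rate / down_to
  keep <- seq(1, ncol(data), by = dec)
  events <- rec$events
  if (nrow(events)) events$sample <- (events$sample - 1L) %/% dec + 1L
  eeg_recording(data[, keep, drop = FALSE], down_to, rec$channel_names,
                rec$positions, events, rec$meta)
}

#' Segment a continuous recording into sequence trials
#'
#' Extracts one segment per sequence-onset event, from `pre_s` before the
#' event to `seq_dur_s + post_s` after it (default 2 + 57.6 + 2 = 61.6 s).
#'
#' @param rec An [eeg_recording()] with events.
#' @param seq_dur_s Sequence duration in seconds (default 57.6).
#' @param pre_s,post_s Margin before/after the sequence (default 2 s each).
#' @param code Event code marking sequence onsets (default `"seq_onset"`).
#' @return A list of [eeg_recording()] trials (empty if no events).
#' @export
segment_trials <- function(rec, seq_dur_s = 57.6, pre_s = 2, post_s = 2,
                           code = "seq_onset") {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events[rec$events$code == code, , drop = FALSE]
  n_len <- round((pre_s + seq_dur_s + post_s) * rec$rate)
  lapply(seq_len(nrow(ev)), function(i) {
    onset <- ev$sample[i]
    start <- onset - round(pre_s * rec$rate)
    if (start < 1 || start + n_len - 1 > ncol(rec$data))
      stop("event at sample ", onset, " yields a segment outside the recording")
    eeg_recording(rec$data[, start:(start + n_len - 1), drop = FALSE],
                  rec$rate, rec$channel_names, rec$positions,
                  events = data.frame(sample = round(pre_s * rec$rate) + 1L,
                                      code = code, stringsAsFactors = FALSE),
                  meta = rec$meta)
  })
}

#' Nearest-neighbour indices by scalp position
#'
#' For a given channel, the `k` closest other good channels by Euclidean
#' distance in 2-D position space.
#'
#' @param positions Channels x 2 position matrix (named rows).
#' @param channel Channel name.
#' @param good Names of channels eligible as neighbours.
#' @param k Number of neighbours (default 3).
#' @return Character vector of `k` neighbour names, closest first.
#' @export
nearest_neighbours <- function(positions, channel, good, k = 3) {
  good <- setdiff(good, channel)
  if (length(good) < k) stop("need at least ", k, " good channels")
  d <- sqrt((positions[good, 1] - positions[channel, 1])^2 +
              (positions[good, 2] - positions[channel, 2])^2)
  good[order(d)][seq_len(k)]
}

#' Interpolate bad channels from their nearest neighbours
#'
#' Replaces each bad channel with the mean of its three closest good
#' channels (Euclidean distance in 2-D scalp coordinates).
#'
#' @param rec An [eeg_recording()] with positions.
#' @param bad Character vector of bad channel names.
#' @param k Number of neighbours to average (default 3).
#' @return The repaired [eeg_recording()].
#' @export
interpolate_channels <- function(rec, bad, k = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(bad)) return(rec)
  if (is.null(rec$positions))
    stop("recording has no channel positions; cannot interpolate")
  unknown <- setdiff(bad, rec$channel_names)
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  good <- setdiff(rec$channel_names, bad)
  if (length(good) < k) stop("need at least ", k, " good channels")
  for (ch in bad) {
    nb <- nearest_neighbours(rec$positions, ch, good, k)
    rec$data[ch, ] <- colMeans(rec$data[nb, , drop = FALSE])
  }
  rec
}

#' Re-reference a recording or trial
#'
#' `"average"` subtracts the per-sample mean across the 128 scalp channels
#' (used in the frequency-domain analysis); `"linked_mastoids"` subtracts
#' the mean of the two mastoid channels (used in the time-domain analysis).
#'
#' @param rec An [eeg_recording()].
#' @param scheme `"average"` or `"linked_mastoids"`.
#' @param mastoids Mastoid channel names (default `c("M1", "M2")`).
#' @return The re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, scheme = c("average", "linked_mastoids"),
                        mastoids = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  scheme <- match.arg(scheme)
  if (scheme == "average") {
    scalp <- scalp_channels(rec, mastoids)
    ref <- colMeans(rec$data[scalp, , drop = FALSE])
  } else {
    if (!all(mastoids %in% rec$channel_names))
      stop("mastoid channel(s) missing: ",
           paste(setdiff(mastoids, rec$channel_names), collapse = ", "))
    ref <- colMeans(rec$data[mastoids, , drop = FALSE])
  }
  rec$data <- sweep(rec$data, 2, ref)
  rec
}

#' Crop trials past the fade-in and average them in the time domain
#'
#' Re-segments each 61.6 s trial from `start_s` after sequence onset
#' (removing the fade-in) to a length of `length_s` (default 52.8 s — an
#' integer number of both target cycles, 44, and base cycles, 132), then
#' averages the cropped trials sample-by-sample. Averaging attenuates all
#' activity not phase-locked to the stimulation.
#'
#' Cropped windows are quantized to the sample grid; among the counts
#' within two samples (at most 4 ms) of the requested duration, the one
#' with the smoothest prime factorization is used so that the subsequent
#' per-channel FFTs stay O(N log N) — the bin resolution moves by less
#' than 2e-6 Hz and every tagged frequency keeps its bin.
#'
#' @param trials List of [eeg_recording()] trials (same channels and rate),
#'   each with a sequence-onset event.
#' @param start_s Crop start relative to sequence onset (default 2 s).
#' @param length_s Crop length in seconds (default 52.8).
#' @return An [eeg_recording()] holding the averaged cropped data.
#' @export
crop_and_average <- function(trials, start_s = 2, length_s = 52.8) {
  if (!length(trials)) stop("empty trial group: nothing to average")
  rate <- trials[[1]]$rate
  n_len <- fft_friendly_n(round(length_s * rate))
  acc <- NULL
  for (tr in trials) {
    stopifnot(inherits(tr, "eeg_recording"))
    if (tr$rate != rate) stop("trials have mixed sampling rates")
    onset <- tr$events$sample[tr$events$code == "seq_onset"][1]
    if (is.na(onset)) stop("trial lacks a seq_onset event")
    start <- onset + round(start_s * rate)
    if (start + n_len - 1 > ncol(tr$data))
      stop("crop window exceeds trial length")
    seg <- tr$data[, start:(start + n_len - 1), drop = FALSE]
    acc <- if (is.null(acc)) seg else acc + seg
  }
  avg <- acc / length(trials)
  eeg_recording(avg, rate, trials[[1]]$channel_names, trials[[1]]$positions,
                meta = c(trials[[1]]$meta, list(n_averaged = length(trials))))
}

#' Amplitude spectrum of an averaged trial
#'
#' Single-sided FFT amplitude spectrum per channel, 2/N normalization (a
#' bin-centred sinusoid of amplitude a reads a at its bin). For the default
#' 52.8 s crop the resolution is 1/52.8 = 0.0189 Hz.
#'
#' @param avg An [eeg_recording()] (typically from [crop_and_average()]).
#' @return An [amplitude_spectrum_set()].
#' @export
amplitude_spectrum <- function(avg) {
  stopifnot(inherits(avg, "eeg_recording"))
  amplitude_spectrum_matrix(avg$data, avg$rate)
}
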