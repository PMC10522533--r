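#' Equalize a waveform's overall energy (RMS)
#'
#' Rescales the samples so their root-mean-square amplitude equals
#' `target_rms`. Stimuli presented in a sequence are equalized so that no
#' category differs in overall energy.
#'
#' @param w A [waveform].
#' @param target_rms Desired RMS amplitude (> 0).
#' @return The rescaled [waveform].
#' @export
rms_equalize <- function(w, target_rms) {
  stopifnot(inherits(w, "waveform"), target_rms > 0)
  r <- wav_rms(w)
  if (r == 0) stop("silent stimulus: RMS is zero, cannot equalize")
  w$samples <- w$samples * (target_rms / r)
  w
}

#' Apply raised onset/offset amplitude ramps
#'
#' Linearly ramps the first and last `ramp_ms` milliseconds from/to zero to
#' avoid onset clicks. The ramp is a monotone 0 to 1 envelope; samples
#' between the ramps are untouched.
#'
#' @param w A [waveform].
#' @param ramp_ms Ramp duration in milliseconds (default 10).
#' @return The ramped [waveform].
#' @export
apply_ramps <- function(w, ramp_ms = 10) {
  stopifnot(inherits(w, "waveform"), ramp_ms >= 0)
  if (ramp_ms == 0) return(w)
  n_ramp <- round(ramp_ms / 1000 * w$rate)
  n <- length(w$samples)
  if (2 * n_ramp > n)
    stop("ramp (", ramp_ms, " ms) longer than half the waveform")
  if (n_ramp > 0) {
    env <- seq(0, 1, length.out = n_ramp)
    w$samples[1:n_ramp] <- w$samples[1:n_ramp] * env
    w$samples[(n - n_ramp + 1):n] <- w$samples[(n - n_ramp + 1):n] * rev(env)
  }
  w
}

# Single-sided amplitude spectrum of a numeric vector; returns freq + amp,
# normalization 2/N so a bin-centred sinusoid of amplitude a reads a.
single_sided_spectrum <- function(x, rate) {
  n <- length(x)
  sp <- stats::fft(x)
  half <- floor(n / 2) + 1L
  amp <- Mod(sp[1:half]) / n
  amp[-1] <- 2 * amp[-1]
  if (n %% 2 == 0) amp[half] <- amp[half] / 2   # Nyquist bin is not doubled
  list(freq = (0:(half - 1L)) * rate / n, amp = amp)
}

#' Spectral centre of gravity
#'
#' Power-weighted mean frequency of the single-sided spectrum, computed over
#' the whole (rectangular-windowed) waveform.
#'
#' @param w A [waveform].
#' @return Frequency in Hz.
#' @export
spectral_cog <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (wav_rms(w) == 0) stop("silent stimulus: spectral COG undefined")
  sp <- single_sided_spectrum(w$samples, w$rate)
  p <- sp$amp^2
  p[1] <- 0  # DC carries no frequency information
  sum(sp$freq * p) / sum(p)
}

# Normalized autocorrelation of x at integer lags 0..max_lag (biased
# estimator, normalized by lag-0), after mean removal.
norm_autocorr <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  # zero-padded autocorrelation via the power spectrum
  sp <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[1:(max_lag + 1L)]
  if (ac[1] <= 0) return(rep(0, max_lag + 1L))
  ac <- ac / ac[1]
  # unbiased lag normalization so a pure periodic signal keeps r ~ 1
  ac * n / pmax(n - (0:max_lag), 1)
}

#' Estimate the fundamental frequency (pitch) of a waveform
#'
#' Autocorrelation-peak pitch over the full waveform: the highest normalized
#' autocorrelation peak with lag inside `[1/fmax, 1/fmin]`. Returns `NA`
#' when the peak autocorrelation falls below `voicing_threshold` (aperiodic
#' input).
#'
#' @param w A [waveform].
#' @param fmin,fmax Pitch search range in Hz.
#' @param voicing_threshold Minimum normalized autocorrelation for a frame
#'   to count as voiced (default 0.45).
#' @return Fundamental frequency in Hz, or `NA` if unvoiced.
#' @export
estimate_pitch <- function(w, fmin = 75, fmax = 600, voicing_threshold = 0.45) {
  stopifnot(inherits(w, "waveform"), fmin > 0, fmax > fmin)
  if (wav_duration(w) < 2 / fmin)
    stop("waveform too short to estimate pitch down to ", fmin, " Hz")
  lag_min <- max(2L, floor(w$rate / fmax))
  lag_max <- ceiling(w$rate / fmin)
  ac <- norm_autocorr(w$samples, lag_max)
  cand <- ac[(lag_min + 1L):(lag_max + 1L)]
  k <- which.max(cand)
  r <- cand[k]
  if (!is.finite(r) || r < voicing_threshold) return(NA_real_)
  lag <- lag_min + k - 1L
  # parabolic interpolation around the peak for sub-sample lag precision
  if (lag > lag_min && lag < lag_max) {
    y1 <- ac[lag]; y2 <- ac[lag + 1L]; y3 <- ac[lag + 2L]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps)
      lag <- lag + 0.5 * (y1 - y3) / denom
  }
  w$rate / lag
}

#' Harmonicity-to-noise ratio
#'
#' `10 log10(r / (1 - r))` where `r` is the normalized autocorrelation at
#' the pitch period: the dB ratio of periodic to aperiodic energy. Values
#' are capped at `cap_db` (a pure periodic signal has `r -> 1`). Returns
#' `NA` for unvoiced input.
#'
#' @param w A [waveform].
#' @param fmin,fmax Pitch search range passed to [estimate_pitch()].
#' @param cap_db Maximum reported HNR in dB (default +60).
#' @return HNR in dB, or `NA` if unvoiced.
#' @export
hnr <- function(w, fmin = 75, fmax = 600, cap_db = 60) {
  f0 <- estimate_pitch(w, fmin, fmax)
  if (is.na(f0)) return(NA_real_)
  lag_max <- ceiling(w$rate / fmin)
  ac <- norm_autocorr(w$samples, lag_max)
  # local integer peak near the pitch lag, then parabolic peak-value
  # estimate (a linear interpolation at a fractional lag would understate
  # r for strongly periodic signals)
  l0 <- round(w$rate / f0)
  l0 <- max(2L, min(l0, lag_max - 1L))
  while (l0 > 2L && ac[l0] > ac[l0 + 1L]) l0 <- l0 - 1L
  while (l0 < lag_max - 1L && ac[l0 + 2L] > ac[l0 + 1L]) l0 <- l0 + 1L
  y1 <- ac[l0]; y2 <- ac[l0 + 1L]; y3 <- ac[l0 + 2L]
  denom <- y1 - 2 * y2 + y3
  r <- if (denom < 0) y2 - (y1 - y3)^2 / (8 * denom) else y2
  if (r >= 1 - 10^(-cap_db / 10)) return(cap_db)
  if (r <= 0) return(-cap_db)
  min(cap_db, 10 * log10(r / (1 - r)))
}

#' Hilbert (analytic-signal) amplitude envelope
#'
#' Magnitude of the analytic signal obtained by zeroing negative
#' frequencies in the FFT; same length and rate as the input.
#'
#' @param w A [waveform].
#' @return A [waveform] holding the non-negative envelope.
#' @export
hilbert_envelope <- function(w) {
  stopifnot(inherits(w, "waveform"))
  w$samples <- Mod(analytic_signal(w$samples))
  w
}

# Analytic signal via the frequency-domain method: double positive
# frequencies, zero negative ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  sp <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(sp * h, inverse = TRUE) / n
}

#' Acoustic feature summary of a waveform
#'
#' Computes the features used to match stimuli across emotion categories:
#' spectral centre of gravity, pitch, HNR and RMS.
#'
#' @param w A [waveform].
#' @return A one-row `data.frame` with columns `label`, `category`, `cog`,
#'   `pitch`, `hnr`, `rms`, `duration`.
#' @export
acoustic_features <- function(w) {
  stopifnot(inherits(w, "waveform"))
  data.frame(
    label = w$label,
    category = w$category,
    cog = spectral_cog(w),
    pitch = estimate_pitch(w),
    hnr = hnr(w),
    rms = wav_rms(w),
    duration = wav_duration(w),
    stringsAsFactors = FALSE)
}
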