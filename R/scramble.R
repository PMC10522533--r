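#' Frequency-scramble a waveform
#'
#' Control-stimulus construction: shuffles FFT coefficients within
#' consecutive spectral windows of `window_hz`, then reapplies the original
#' temporal envelope. This preserves the coarse frequency content and the
#' envelope of the sound while destroying harmonicity and intelligibility.
#'
#' Pipeline: extract the Hilbert envelope, FFT the waveform, permute the
#' positive-frequency coefficients within each `window_hz` window (one
#' seeded permutation per window; DC and Nyquist untouched; Hermitian
#' symmetry restored so the output is real), inverse FFT, apply the
#' original envelope, re-equalize RMS, and apply onset/offset ramps.
#'
#' Applying the envelope has two readings, controlled by `envelope`. The
#' default `"impose"` first divides the scrambled carrier by its own
#' analytic magnitude and then multiplies by the original envelope, so the
#' output's temporal envelope equals the original exactly — which is what
#' makes paired intact/scrambled sequences indistinguishable in their
#' envelope spectra, the property the control sequences exist to provide.
#' `"multiply"` multiplies the raw scrambled carrier by the envelope; the
#' carrier's own Rayleigh-like magnitude fluctuations then dilute the
#' coherent envelope by about 11% after RMS equalization.
#'
#' @param w A [waveform].
#' @param window_hz Width of each scrambling window in Hz (default 200).
#' @param seed Integer seed making the permutations reproducible.
#' @param mode `"joint"` permutes complex coefficients (magnitude and phase
#'   travel together); `"independent"` shuffles magnitudes and phases with
#'   two independent permutations per window.
#' @param envelope `"impose"` (default) or `"multiply"`; see Details.
#' @param ramp_ms Ramp applied after scrambling (default 10 ms).
#' @param target_rms Equalization level applied before the final ramps.
#'   Defaults to the input's measured RMS; when scrambling a whole
#'   equalized stimulus set, pass the set's shared level so intact and
#'   scrambled items go through the identical equalize-then-ramp path (a
#'   per-item target would leave scrambled items systematically quieter by
#'   the input's own ramp loss).
#' @param permute If `FALSE`, the identity permutation is used (the signal
#'   still passes through the envelope/RMS/ramp path); useful for isolating
#'   the effect of the permutation itself.
#' @return The scrambled [waveform] (same length, rate and RMS as input).
#' @export
scramble_frequency <- function(w, window_hz = 200, seed = NULL,
                               mode = c("joint", "independent"),
                               envelope = c("impose", "multiply"),
                               ramp_ms = 10, target_rms = NULL,
                               permute = TRUE) {
  stopifnot(inherits(w, "waveform"))
  mode <- match.arg(mode)
  envelope <- match.arg(envelope)
  n <- length(w$samples)
  df <- w$rate / n
  if (window_hz <= df)
    stop("scrambling window (", window_hz,
         " Hz) narrower than one frequency bin (", signif(df, 4), " Hz)")
  env <- hilbert_envelope(w)$samples
  if (is.null(target_rms)) target_rms <- wav_rms(w)
  sp <- stats::fft(w$samples)
  if (permute)
    sp <- with_seed(seed, permute_spectrum(sp, n, df, window_hz, mode))
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  if (envelope == "impose") {
    a <- Mod(analytic_signal(y))
    y <- y / pmax(a, 1e-3 * max(a))     # flatten the carrier's own envelope
  }
  y <- y * env
  out <- waveform(y, w$rate, label = paste0(w$label, "_scr"),
                  category = w$category)
  out <- rms_equalize(out, target_rms)
  apply_ramps(out, ramp_ms)
}

# Permute positive-frequency FFT coefficients within consecutive windows of
# `window_hz`, then mirror to restore Hermitian symmetry.
permute_spectrum <- function(sp, n, df, window_hz, mode) {
  half_last <- floor((n - 1) / 2)        # positive bins 1..half_last (excl. DC/Nyquist)
  if (half_last < 1L) return(sp)
  bins <- 1:half_last
  win <- floor(bins * df / window_hz)    # windows aligned from 0 Hz
  for (wid in unique(win)) {
    idx <- bins[win == wid] + 1L         # 1-based FFT indices
    if (length(idx) < 2L) next
    if (mode == "joint") {
      sp[idx] <- sp[idx][sample(length(idx))]
    } else {
      mags <- Mod(sp[idx]); phs <- Arg(sp[idx])
      sp[idx] <- mags[sample(length(idx))] * exp(1i * phs[sample(length(idx))])
    }
  }
  # mirror: FFT bin n+2-k is the conjugate of bin k (1-based indices)
  idxpos <- bins + 1L
  sp[n + 2L - idxpos] <- Conj(sp[idxpos])
  sp
}
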