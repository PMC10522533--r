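#' Amplitude spectrum set
#'
#' Container for per-channel single-sided amplitude spectra: a channels x
#' bins matrix plus the bin resolution. Bin `k` (1-based) corresponds to
#' frequency `(k-1) * df`.
#'
#' @param amps Numeric matrix (channels x bins) of non-negative amplitudes,
#'   or a vector for a single channel.
#' @param df Frequency resolution in Hz (1 / segment duration).
#' @return An object of class `amplitude_spectrum_set`.
#' @export
amplitude_spectrum_set <- function(amps, df) {
  if (is.null(dim(amps))) amps <- matrix(amps, nrow = 1)
  stopifnot(all(amps >= 0), df > 0)
  structure(list(amps = amps, df = df,
                 freq = (seq_len(ncol(amps)) - 1L) * df),
            class = "amplitude_spectrum_set")
}

#' @export
print.amplitude_spectrum_set <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum_set> %d channel(s) x %d bins, df = %.4g Hz (0-%.4g Hz)\n",
              nrow(x$amps), ncol(x$amps), x$df, max(x$freq)))
  invisible(x)
}

# Nearest bin index (1-based) for frequency f at resolution df.
freq_to_bin <- function(f, df) as.integer(round(f / df)) + 1L

#' Single-sided amplitude spectrum of a multichannel matrix
#'
#' Applies the FFT along rows of a channels x samples matrix with 2/N
#' normalization (a bin-centred sinusoid of amplitude a reads a at its bin).
#'
#' @param data Channels x samples numeric matrix (or vector).
#' @param rate Sampling rate in Hz.
#' @return An [amplitude_spectrum_set()].
#' @export
amplitude_spectrum_matrix <- function(data, rate) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  n <- ncol(data)
  half <- floor(n / 2) + 1L
  sp <- t(apply(data, 1, function(x) {
    a <- Mod(stats::fft(x)[1:half]) / n
    a[-1] <- 2 * a[-1]
    if (n %% 2 == 0) a[half] <- a[half] / 2
    a
  }))
  rownames(sp) <- rownames(data)
  amplitude_spectrum_set(sp, rate / n)
}
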