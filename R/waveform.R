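#' Mono waveform container
#'
#' Lightweight container for a single-channel sound: a numeric sample vector
#' plus its sampling rate. All stimulus-level processing in the package
#' operates on `waveform` objects.
#'
#' @param samples Numeric vector of samples (arbitrary amplitude units).
#' @param rate Sampling rate in Hz (positive).
#' @param label Optional free-text label.
#' @param category Optional emotion category, one of
#'   `"anger"`, `"disgust"`, `"fear"`, `"happiness"`, `"sadness"`, or `NA`.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate, label = "", category = NA_character_) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (!is.na(category))
    category <- match.arg(category, emotion_categories())
  structure(
    list(samples = samples, rate = rate, label = as.character(label),
         category = category),
    class = "waveform")
}

#' The five emotion categories used throughout the package
#' @return Character vector of category names.
#' @export
emotion_categories <- function() {
  c("anger", "disgust", "fear", "happiness", "sadness")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$rate, wav_duration(x)))
  if (nzchar(x$label)) cat(" label:", x$label)
  if (!is.na(x$category)) cat(" category:", x$category)
  cat("\n")
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A `waveform`.
#' @return Duration in seconds.
#' @export
wav_duration <- function(w) length(w$samples) / w$rate

#' Root-mean-square amplitude
#' @param w A `waveform` or numeric vector.
#' @return RMS value.
#' @export
wav_rms <- function(w) {
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  sqrt(mean(x^2))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All seeded operations in the package go through
# this so that library-level randomness never perturbs user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
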