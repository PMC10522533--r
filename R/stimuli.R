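#' Generate one synthetic vocalization
#'
#' Produces a 350 ms voiced, vowel-like sound: a harmonic complex at a
#' per-item fundamental, shaped by two formant-like spectral resonances,
#' amplitude-modulated by a smooth random syllabic envelope, mixed with a
#' small aperiodic (noise) component, RMS-equalized and ramped. The
#' generator draws all item parameters from the same distributions for
#' every emotion category, emulating a stimulus set whose categories are
#' matched in spectral centre of gravity, pitch and HNR.
#'
#' @param category Emotion category label for the item.
#' @param rate Sampling rate in Hz (default 8000).
#' @param duration_s Duration in seconds (default 0.350).
#' @param target_rms RMS amplitude after equalization (default 0.1).
#' @param seed Integer seed for the item's random parameters.
#' @param label Optional stimulus id.
#' @return A [waveform].
#' @export
synth_vocalization <- function(category, rate = 8000, duration_s = 0.350,
                               target_rms = 0.1, seed = NULL,
                               label = paste0(category, "_", seed)) {
  with_seed(seed, {
    n <- round(duration_s * rate)
    t <- (0:(n - 1)) / rate
    f0 <- stats::runif(1, 140, 260)               # adult vocal range
    n_harm <- floor(min(rate / 2 - 1, 3000) / f0)
    # two formant-like resonances shaping harmonic amplitudes
    fmt1 <- stats::runif(1, 400, 900)
    fmt2 <- stats::runif(1, 1200, 2400)
    bw1 <- 200; bw2 <- 350
    phases <- stats::runif(n_harm, 0, 2 * pi)
    x <- numeric(n)
    # slow random pitch glide (+-6%) makes items heterogeneous
    glide <- 1 + stats::runif(1, -0.06, 0.06) * t / duration_s
    for (h in seq_len(n_harm)) {
      fh <- h * f0
      a <- exp(-((fh - fmt1) / bw1)^2) + 0.6 * exp(-((fh - fmt2) / bw2)^2) +
        0.05 * (f0 / fh)
      x <- x + a * cos(2 * pi * fh * glide * t + phases[h])
    }
    # syllabic amplitude modulation: raised random low-frequency envelope
    fm <- stats::runif(1, 3, 8)
    env <- 0.55 + 0.45 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
    x <- x * env
    # aperiodic (breath) component: ~5% of the periodic power
    noise <- stats::rnorm(n)
    x <- x / stats::sd(x) + 0.22 * noise / stats::sd(noise)
    w <- waveform(x, rate, label = label, category = category)
    apply_ramps(rms_equalize(w, target_rms), 10)
  })
}

#' Generate the synthetic stimulus set used to build sequences
#'
#' Mirrors the composition of the validated experimental set: 84 unique
#' vocalizations, 12 each of anger, disgust and sadness and 24 each of fear
#' and happiness (the frequent categories need twice as many items so every
#' unique sound can appear exactly twice per 144-slot sequence).
#'
#' @param rate Sampling rate in Hz (default 8000).
#' @param target_rms RMS amplitude all items are equalized to (default 0.1).
#' @param seed Integer master seed.
#' @param counts Named integer vector of items per category.
#' @return A list of [waveform] objects (a "stimulus set"), with names equal
#'   to the item labels.
#' @export
make_stimulus_set <- function(rate = 8000, target_rms = 0.1, seed = 1,
                              counts = c(anger = 12, disgust = 12,
                                         fear = 24, happiness = 24,
                                         sadness = 12)) {
  stopifnot(all(names(counts) %in% emotion_categories()))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, sum(counts)))
  out <- list(); k <- 0L
  for (cat in names(counts)) {
    for (i in seq_len(counts[[cat]])) {
      k <- k + 1L
      lab <- sprintf("%s_%02d", cat, i)
      out[[lab]] <- synth_vocalization(cat, rate = rate,
                                       target_rms = target_rms,
                                       seed = seeds[k], label = lab)
    }
  }
  out
}

#' Frequency-scramble every item of a stimulus set
#'
#' @param stimuli A stimulus set (named list of [waveform]s).
#' @param window_hz Scrambling window width in Hz.
#' @param seed Integer master seed (one sub-seed per item).
#' @param target_rms Shared equalization level, matching the level the
#'   intact set was equalized to (default 0.1, the [make_stimulus_set()]
#'   default) so both sets follow the identical equalize-then-ramp path.
#' @return A named list of scrambled [waveform]s, same names and order.
#' @export
scramble_stimulus_set <- function(stimuli, window_hz = 200, seed = 1,
                                  target_rms = 0.1) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(stimuli)))
  out <- mapply(function(w, s) scramble_frequency(w, window_hz, seed = s,
                                                  target_rms = target_rms),
                stimuli, seeds, SIMPLIFY = FALSE)
  names(out) <- names(stimuli)
  out
}
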