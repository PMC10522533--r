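#' Simulation specification for synthetic FPAS EEG
#'
#' Encodes the response model the frequency-tagging analysis presumes: a
#' steady-state response at the base presentation rate (2.5 Hz) and its
#' harmonics, a category-selective steady-state response at the target rate
#' (0.833 Hz) and its non-base-coincident harmonics, transient target-locked
#' ERP components, all embedded in spatially correlated 1/f^alpha Gaussian
#' noise. Scrambled sequences attenuate the category-selective components by
#' `scrambled_gain` (they share all acoustic periodicity with intact
#' sequences, so the base response is unaffected).
#'
#' Default amplitudes are set so that, relative to the 10 uV 1/f noise
#' floor at a 0.019 Hz bin resolution, the base response is strongly
#' detectable and the target response is detectable after trial averaging —
#' the regime the paradigm is designed for.
#'
#' @param base_amp Amplitudes (uV) of the base-rate harmonics (2.5, 5,
#'   7.5 Hz ...).
#' @param target_amp Amplitudes (uV) of the target harmonics, in order of
#'   the non-base-coincident harmonic numbers `target_harmonics`.
#' @param target_harmonics Integer multiples of the target rate carrying
#'   the category-selective response (default `c(1, 2, 4, 5, 7)`, i.e.
#'   0.83, 1.67, 3.33, 4.17, 5.83 Hz; multiples of 3 coincide with the base
#'   rate).
#' @param erp_components List of target-locked transient components, each a
#'   list with `latency` (s), `width` (s) and `amplitude` (uV). Defaults
#'   place an early (150 ms) and a late (340 ms) component.
#' @param noise_sigma Broadband noise SD per channel in uV (default 10).
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha noise
#'   (default 1).
#' @param phase_jitter_sd SD (radians) of the per-participant jitter around
#'   the population steady-state phases (default 0.35, about 20 degrees).
#'   Phases must be broadly consistent across participants for the
#'   time-domain grand average to retain the tagged responses, as steady
#'   -state latencies are in real data; each participant's phases are
#'   fixed across their trials.
#' @param scrambled_gain Multiplier in \[0, 1\] applied to the
#'   category-selective components (target steady-state + ERPs) in
#'   scrambled sequences (default 0.5).
#' @param n_participants Number of simulated participants (default 24).
#' @param participant_gain_sd SD of the per-participant log-normal response
#'   gain (default 0.2).
#' @param rate Sampling rate in Hz (default 512).
#' @param seed Master seed; fixes the response topographies.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(base_amp = c(1.2, 0.6, 0.3),
                            target_amp = c(0.6, 0.4, 0.3, 0.25, 0.2),
                            target_harmonics = c(1, 2, 4, 5, 7),
                            erp_components = list(
                              list(latency = 0.150, width = 0.060, amplitude = 3),
                              list(latency = 0.340, width = 0.090, amplitude = 4)),
                            noise_sigma = 10, noise_exponent = 1,
                            phase_jitter_sd = 0.35,
                            scrambled_gain = 0.5,
                            n_participants = 24, participant_gain_sd = 0.2,
                            rate = 512, seed = 1) {
  stopifnot(all(base_amp >= 0), all(target_amp >= 0),
            length(target_amp) == length(target_harmonics),
            noise_sigma >= 0, scrambled_gain >= 0, scrambled_gain <= 1,
            n_participants >= 1, participant_gain_sd >= 0)
  layout <- biosemi128_layout()
  pop <- with_seed(seed, list(
    base_topo = smooth_topography(layout$positions[layout$scalp, ]),
    target_topo = smooth_topography(layout$positions[layout$scalp, ]),
    phi_base = stats::runif(length(base_amp), 0, 2 * pi),
    psi_target = stats::runif(length(target_amp), 0, 2 * pi)))
  structure(
    list(base_amp = base_amp, target_amp = target_amp,
         target_harmonics = target_harmonics,
         erp_components = erp_components,
         noise_sigma = noise_sigma, noise_exponent = noise_exponent,
         phase_jitter_sd = phase_jitter_sd,
         scrambled_gain = scrambled_gain,
         n_participants = n_participants,
         participant_gain_sd = participant_gain_sd,
         rate = rate, seed = seed, layout = layout,
         base_topo = pop$base_topo, target_topo = pop$target_topo,
         phi_base = pop$phi_base, psi_target = pop$psi_target),
    class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d participants, noise %g uV (1/f^%g), scrambled gain %g\n",
    x$n_participants, x$noise_sigma, x$noise_exponent, x$scrambled_gain))
  invisible(x)
}

#' Smooth random scalp topography
#'
#' Sum of a few random Gaussian blobs over the channel positions,
#' rescaled to \[0, 1\]. Uses the current RNG state.
#'
#' @param positions Channels x 2 position matrix.
#' @param n_blobs Number of blobs (default 3).
#' @return Numeric vector of per-channel weights in \[0, 1\].
#' @export
smooth_topography <- function(positions, n_blobs = 3) {
  v <- numeric(nrow(positions))
  for (b in seq_len(n_blobs)) {
    ctr <- stats::runif(2, -0.8, 0.8)
    width <- stats::runif(1, 0.25, 0.6)
    d2 <- (positions[, 1] - ctr[1])^2 + (positions[, 2] - ctr[2])^2
    v <- v + stats::runif(1, 0.3, 1) * exp(-d2 / (2 * width^2))
  }
  v <- v - min(v)
  v / max(v)
}

# Spatially correlated 1/f^alpha Gaussian noise: channels x n matrix.
# Spectral shaping of white noise per channel (flat below f_lo), then
# mixing through a smooth distance-based kernel so nearby channels
# correlate (volume-conduction-like); row-normalized to preserve variance.
pink_noise_matrix <- function(n_ch, n, rate, sigma, alpha, positions,
                              f_lo = 0.1, mix_lambda = 0.3) {
  if (sigma == 0) return(matrix(0, n_ch, n))
  nfft <- stats::nextn(n, 2)                  # fast FFT length, then truncate
  f <- (0:(nfft - 1)) * rate / nfft
  f <- pmin(f, rate - f)                      # two-sided frequency axis
  shape <- pmax(f, f_lo)^(-alpha / 2)
  shape[1] <- 0                               # no DC power
  # synthesize directly in the frequency domain: complex Gaussian spectrum
  # shaped by 1/f^(alpha/2); the real part of its inverse FFT is Gaussian
  # noise with the requested power spectrum
  sp <- matrix(complex(real = stats::rnorm(nfft * n_ch),
                       imaginary = stats::rnorm(nfft * n_ch)),
               nfft, n_ch) * shape
  x <- Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
  x <- x * sigma * sqrt(nfft / mean(shape^2))   # per-sample SD = sigma
  k <- exp(-as.matrix(stats::dist(positions))^2 / (2 * mix_lambda^2))
  k <- k / sqrt(rowSums(k^2))
  k %*% t(x)
}

#' Per-participant simulation parameters
#'
#' Draws the participant's multiplicative response gain (log-normal) and
#' their steady-state phases: the population phases of the
#' [simulation_spec()] plus a small per-participant jitter. Phases are
#' fixed across a participant's trials (required for within-participant
#' time-domain averaging) and broadly shared across participants (required
#' for the grand average across participants to retain the responses).
#'
#' @param spec A [simulation_spec()].
#' @param participant Participant index (1-based); seeds the draw together
#'   with `spec$seed`.
#' @return A list with `gain`, `phi_base`, `psi_target`.
#' @export
participant_params <- function(spec, participant) {
  with_seed((as.numeric(spec$seed) * 10007 + participant) %% 2147483647, list(
    gain = stats::rlnorm(1, 0, spec$participant_gain_sd),
    phi_base = spec$phi_base +
      stats::rnorm(length(spec$base_amp), 0, spec$phase_jitter_sd),
    psi_target = spec$psi_target +
      stats::rnorm(length(spec$target_amp), 0, spec$phase_jitter_sd)))
}

# Slot onsets/targets from either a stimulus_sequence or a sequence_spec.
sequence_slot_info <- function(x) {
  if (inherits(x, "stimulus_sequence"))
    return(list(spec = x$spec,
                onset_s = x$slots$onset_s, is_target = x$slots$is_target))
  if (inherits(x, "sequence_spec")) {
    pos <- seq_len(x$n_slots)
    return(list(spec = x,
                onset_s = (pos - 1) * x$slot_dur, is_target = pos %% 3 == 0))
  }
  stop("expected a stimulus_sequence or sequence_spec")
}

#' Simulate one EEG recording of an FPAS trial
#'
#' Generates a 2 s pre + sequence + 2 s post recording (default 61.6 s at
#' 512 Hz, 128 scalp + 2 mastoid channels) containing the steady-state base
#' and target responses, target-locked ERP components, and 1/f noise, with
#' an event marker at sequence onset. For `type = "scrambled"` the
#' category-selective components (target steady state and ERPs) are scaled
#' by `spec$scrambled_gain`.
#'
#' @param seq A `stimulus_sequence` or [sequence_spec()] providing slot
#'   timing.
#' @param spec A [simulation_spec()].
#' @param type `"intact"` or `"scrambled"`.
#' @param participant Participant index (phases and gain are drawn from it,
#'   reproducibly) — see [participant_params()].
#' @param seed Seed for the noise of this trial.
#' @param pre_s,post_s Silence before/after the sequence (default 2 s each).
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(seq, spec, type = c("intact", "scrambled"),
                               participant = 1, seed = 1,
                               pre_s = 2, post_s = 2) {
  type <- match.arg(type)
  info <- sequence_slot_info(seq)
  sspec <- info$spec
  rate <- spec$rate
  n <- round((pre_s + sspec$duration + post_s) * rate)
  layout <- spec$layout
  n_ch <- length(layout$names)
  pp <- participant_params(spec, participant)
  g <- if (type == "intact") 1 else spec$scrambled_gain

  data <- with_seed(seed,
    pink_noise_matrix(n_ch, n, rate, spec$noise_sigma, spec$noise_exponent,
                      layout$positions))

  # response components live on scalp channels, during the sequence only
  seq_idx <- round(pre_s * rate) + seq_len(round(sspec$duration * rate))
  tloc <- (seq_idx - 1) / rate - pre_s        # time since sequence onset
  comp <- numeric(length(seq_idx))            # base response (shared topo)
  for (k in seq_along(spec$base_amp))
    comp <- comp + spec$base_amp[k] *
      cos(2 * pi * k * sspec$base_rate * tloc + pp$phi_base[k])
  tcomp <- numeric(length(seq_idx))           # target steady state
  for (j in seq_along(spec$target_amp))
    tcomp <- tcomp + spec$target_amp[j] *
      cos(2 * pi * spec$target_harmonics[j] * sspec$target_rate * tloc +
            pp$psi_target[j])
  # transient target-locked ERP kernels on the target onset train
  erp <- numeric(length(seq_idx))
  if (length(spec$erp_components)) {
    onsets <- info$onset_s[info$is_target]
    for (cmp in spec$erp_components) {
      for (o in onsets) {
        tt <- tloc - o - cmp$latency
        sel <- abs(tt) < cmp$width / 2      # raised cosine, full width `width`
        if (any(sel))
          erp[sel] <- erp[sel] + cmp$amplitude *
            cos(pi * tt[sel] / cmp$width)^2
      }
    }
  }
  scalp <- which(layout$scalp)
  data[scalp, seq_idx] <- data[scalp, seq_idx] +
    pp$gain * (outer(spec$base_topo, comp) +
                 g * outer(spec$target_topo, tcomp + erp))

  eeg_recording(
    data, rate, layout$names, layout$positions,
    events = data.frame(sample = round(pre_s * rate) + 1L,
                        code = "seq_onset", stringsAsFactors = FALSE),
    meta = list(type = type, participant = participant,
                target_category = sspec$target_category, seed = seed))
}

#' Simulate a full multi-participant FPAS dataset
#'
#' Writes one file per recording (participant x condition x type x trial)
#' and returns a manifest mapping files to their labels. The default trial
#' count mirrors a 40-trial session (10 per condition/type cell over two
#' target categories and two sequence types).
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Directory to write recordings into.
#' @param conditions Target categories to simulate (default fear and
#'   happiness).
#' @param n_trials_per_condition Trials per participant, condition and type
#'   (default 10).
#' @param format `"raw"` (binary + JSON sidecar) or `"edf"`.
#' @param seq_spec_fn Function(condition, participant) returning the
#'   [sequence_spec()] for that cell; defaults to the standard design.
#' @return The manifest `data.frame` (also written as `manifest.csv`), with
#'   columns `file`, `participant`, `condition`, `type`, `trial`, `seed`.
#' @export
simulate_dataset <- function(spec, out_dir,
                             conditions = c("fear", "happiness"),
                             n_trials_per_condition = 10,
                             format = c("raw", "edf"),
                             seq_spec_fn = function(condition, participant)
                               sequence_spec(target_category = condition,
                                             seed = participant)) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); i <- 0L
  for (p in seq_len(spec$n_participants)) {
    for (cond in conditions) {
      sspec <- seq_spec_fn(cond, p)
      for (type in c("intact", "scrambled")) {
        for (tr in seq_len(n_trials_per_condition)) {
          i <- i + 1L
          seed <- (as.numeric(spec$seed) * 1000003 + i) %% 2147483647
          rec <- simulate_recording(sspec, spec, type, participant = p,
                                    seed = seed)
          fname <- sprintf("p%02d_%s_%s_t%02d.%s", p, cond, type, tr,
                           if (format == "raw") "feeg" else "edf")
          path <- file.path(out_dir, fname)
          if (format == "raw") write_eeg_raw(rec, path) else write_edf(rec, path)
          rows[[i]] <- data.frame(file = fname, participant = p,
                                  condition = cond, type = type, trial = tr,
                                  seed = seed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Simulate a detection-task behavioral table
#'
#' Equal-variance Gaussian signal-detection model: on target-present trials
#' the decision variable is N(d', 1), on target-absent trials N(0, 1); the
#' observer responds "yes" above the unbiased criterion d'/2 (criterion
#' parameter 0).
#'
#' @param d_prime_true Generating sensitivity.
#' @param n_trials Total trials (half target-present; must be even).
#' @param seed Integer seed.
#' @param participant Participant id recorded in the table.
#' @param criterion Criterion shift from the unbiased point (default 0).
#' @return A `data.frame` with columns `participant`, `task`, `trial`,
#'   `target_present`, `response` ("yes"/"no").
#' @export
simulate_behavior <- function(d_prime_true, n_trials, seed = 1,
                              participant = 1, criterion = 0) {
  if (n_trials %% 2 != 0) stop("n_trials must be even (half target-present)")
  with_seed(seed, {
    present <- rep(c(TRUE, FALSE), each = n_trials / 2)[sample(n_trials)]
    evidence <- stats::rnorm(n_trials, mean = ifelse(present, d_prime_true, 0))
    yes <- evidence > d_prime_true / 2 + criterion
    data.frame(participant = participant, task = "sequence",
               trial = seq_len(n_trials), target_present = present,
               response = ifelse(yes, "yes", "no"),
               stringsAsFactors = FALSE)
  })
}
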