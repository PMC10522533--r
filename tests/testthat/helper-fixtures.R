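# Shared fixtures: small, fast synthetic objects built in code.

tone <- function(freq, dur = 1, rate = 8000, amp = 1) {
  waveform(amp * sin(2 * pi * freq * (0:(round(dur * rate) - 1)) / rate), rate)
}

# Moving-average smoother for envelope comparisons (removes pitch-rate
# ripple so that the temporal profile itself is compared).
smooth_env <- function(x, n = 81) {
  as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
}

# A reduced stimulus set: enough unique items for a short 24-slot sequence
# (4 unique targets, 2 unique non-targets per other category).
small_stimuli <- function(n_slots = 24, rate = 4000, seed = 1) {
  n_t <- n_slots / 3 / 2          # unique targets
  n_nt <- (n_slots - n_slots / 3) / 2 / 4
  make_stimulus_set(rate = rate, seed = seed,
                    counts = c(anger = n_nt, disgust = n_nt, fear = n_t,
                               happiness = n_nt, sadness = n_nt))
}

# Short-sequence spec for cheap EEG fixtures (9.6 s instead of 57.6 s).
short_seq_spec <- function(seed = 1)
  sequence_spec("fear", n_slots = 24, fade = 0.8, n_attention = 2, seed = seed)

# Tiny in-memory manifest + loader pair for pipeline tests.
mini_manifest <- function(n_participants, n_trials = 1, condition = "fear") {
  man <- expand.grid(participant = seq_len(n_participants),
                     type = c("intact", "scrambled"),
                     trial = seq_len(n_trials), stringsAsFactors = FALSE)
  man$condition <- condition
  man$file <- ""
  man
}

sim_loader <- function(seq_spec, sim_spec, seed_base = 0) {
  function(row)
    simulate_recording(seq_spec, sim_spec, row$type,
                       participant = row$participant,
                       seed = seed_base + row$participant * 131 +
                         row$trial * 17 + (row$type == "intact") * 10007)
}
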