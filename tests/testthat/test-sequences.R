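test_that("sequence_spec derives the design constants", {
  sp <- sequence_spec("fear")
  expect_equal(sp$base_rate, 2.5)
  expect_equal(sp$target_rate, 2.5 / 3)
  expect_equal(sp$duration, 57.6)
  expect_error(sequence_spec(n_slots = 100), "divisible by 3")
})

test_that("build_sequence satisfies the slot-structure invariants across seeds", {
  stim <- make_stimulus_set(seed = 2)
  sp0 <- sequence_spec("fear")
  for (seed in c(1, 7, 19, 23, 101, 555)) {
    sq <- build_sequence(stim, sequence_spec("fear", seed = seed))
    slots <- sq$slots
    expect_equal(nrow(slots), 144)
    # every third slot is the target category, exactly
    expect_identical(which(slots$is_target), seq(3L, 144L, by = 3L))
    expect_true(all(slots$category[slots$is_target] == "fear"))
    expect_true(all(slots$category[!slots$is_target] != "fear"))
    # 24 unique targets and 48 unique non-targets, each used exactly twice
    tt <- table(slots$stimulus_id[slots$is_target])
    nt <- table(slots$stimulus_id[!slots$is_target])
    expect_equal(length(tt), 24); expect_true(all(tt == 2))
    expect_equal(length(nt), 48); expect_true(all(nt == 2))
    # all unique sounds occur once before any repeats, in both streams
    first_half_nt <- slots$stimulus_id[!slots$is_target][1:48]
    expect_equal(length(unique(first_half_nt)), 48)
    first_half_t <- slots$stimulus_id[slots$is_target][1:24]
    expect_equal(length(unique(first_half_t)), 24)
    # equal draw from each non-target category
    expect_true(all(table(slots$category[!slots$is_target]) == 24))
    # onsets on the 0.4 s grid
    expect_equal(slots$onset_s, (1:144 - 1) * 0.4)
    # attention probes: 6, outside fades, not on targets
    att <- slots[slots$is_attention, ]
    expect_equal(nrow(att), 6)
    expect_true(all(att$onset_s >= 2 & att$onset_s + 0.4 <= 55.6))
    expect_true(all(!att$is_target))
  }
  # determinism: same seed, same order
  a <- build_sequence(stim, sequence_spec("fear", seed = 4))
  b <- build_sequence(stim, sequence_spec("fear", seed = 4))
  expect_identical(a$slots, b$slots)
  # insufficient stimuli
  few <- stim[1:20]
  expect_error(build_sequence(few, sp0), "unique")
})

test_that("render_audio produces the 57.6 s sequence with silent ISIs and fades", {
  stim <- small_stimuli()
  sp <- short_seq_spec(seed = 3)
  sq <- build_sequence(stim, sp)
  au <- render_audio(sq, stim)
  expect_equal(length(au$samples), round(sp$duration * 4000))
  expect_equal(wav_duration(au), sp$duration)
  # ISI silence after a mid-sequence stimulus
  mid <- sq$slots$onset_s[8]
  isi <- round((mid + 0.35) * 4000) + 2:(0.05 * 4000 - 1)
  expect_true(all(au$samples[isi] == 0))
  # fade endpoints: first sample silent; gain is 1 past the fade.
  # Render with constant-valued stimuli so the fade ramp is read directly.
  ones <- lapply(stim, function(w) { w$samples <- rep(1, length(w$samples)); w })
  auf <- render_audio(sq, ones)
  expect_equal(auf$samples[1], 0)
  n_fade <- round(sp$fade * 4000)
  g <- seq(0, 1, length.out = n_fade)
  in_stim <- function(i) any(round(sq$slots$onset_s * 4000) < i &
                               i <= round(sq$slots$onset_s * 4000) + 1400)
  probe <- c(5, round(n_fade / 2), n_fade - 5)
  for (i in probe[vapply(probe, in_stim, TRUE)]) {
    slot <- max(which(round(sq$slots$onset_s * 4000) < i))
    att <- sq$slots$is_attention[slot]
    expect_equal(auf$samples[i], g[i] * (if (att) 0.1 else 1),
                 tolerance = 1e-9)
  }
  # mixed sampling rates refuse
  stim_bad <- stim
  stim_bad[[1]]$rate <- 8000
  expect_error(render_audio(sq, stim_bad), "mixed")
  # full-size check: 144 slots at 8 kHz
  stim8 <- make_stimulus_set(seed = 2)
  sq8 <- build_sequence(stim8, sequence_spec("fear", seed = 1))
  au8 <- render_audio(sq8, stim8)
  expect_equal(length(au8$samples), round(57.6 * 8000))
})

test_that("attention probes attenuate the rendered slot by the RMS factor", {
  stim <- small_stimuli()
  sp <- short_seq_spec(seed = 5)
  sq <- build_sequence(stim, sp)
  att_slot <- which(sq$slots$is_attention)[1]
  id <- sq$slots$stimulus_id[att_slot]
  au <- render_audio(sq, stim)
  start <- round(sq$slots$onset_s[att_slot] * 4000)
  seg <- au$samples[start + 1:length(stim[[id]]$samples)]
  expect_equal(seg, stim[[id]]$samples / 10, tolerance = 1e-12)
})
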