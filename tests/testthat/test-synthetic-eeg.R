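test_that("simulated recordings are deterministic and correctly shaped", {
  sp <- short_seq_spec()
  sim <- simulation_spec(n_participants = 2, seed = 5)
  a <- simulate_recording(sp, sim, "intact", participant = 1, seed = 9)
  b <- simulate_recording(sp, sim, "intact", participant = 1, seed = 9)
  expect_identical(a$data, b$data)
  expect_equal(nrow(a$data), 130)
  expect_equal(ncol(a$data), round((2 + sp$duration + 2) * 512))
  expect_equal(a$events$sample, 1025)
  d <- simulate_recording(sp, sim, "intact", participant = 1, seed = 10)
  expect_false(identical(a$data, d$data))
})

test_that("a noiseless single target harmonic lands on its integer-cycle bin", {
  sim <- simulation_spec(base_amp = numeric(0), target_amp = 1,
                         target_harmonics = 1, erp_components = list(),
                         noise_sigma = 0, participant_gain_sd = 0,
                         phase_jitter_sd = 0, n_participants = 1, seed = 2)
  sq <- sequence_spec("fear", seed = 1)
  rec <- simulate_recording(sq, sim, "intact", participant = 1, seed = 1)
  avg <- crop_and_average(segment_trials(rec))
  sp <- amplitude_spectrum(avg)
  ch <- which.max(sim$target_topo)
  bin <- fpas:::freq_to_bin(2.5 / 3, sp$df)   # 44 cycles in 52.8 s
  expect_equal(sp$freq[bin], 44 / 52.8, tolerance = 1e-3)
  expect_equal(unname(sp$amps[ch, bin]), 1, tolerance = 1e-3)
  off <- sp$amps[ch, c(bin - 2, bin + 2)]
  expect_lt(max(off), 0.01)
})

test_that("scrambled recordings attenuate only the category-selective part", {
  sim <- simulation_spec(base_amp = 1, target_amp = 2,
                         target_harmonics = 1, erp_components = list(),
                         noise_sigma = 0, participant_gain_sd = 0,
                         phase_jitter_sd = 0, scrambled_gain = 0.5,
                         n_participants = 1, seed = 3)
  sq <- sequence_spec("fear", seed = 1)
  int <- simulate_recording(sq, sim, "intact", 1, 1)
  scr <- simulate_recording(sq, sim, "scrambled", 1, 1)
  spi <- amplitude_spectrum(crop_and_average(segment_trials(int)))
  sps <- amplitude_spectrum(crop_and_average(segment_trials(scr)))
  tb <- fpas:::freq_to_bin(2.5 / 3, spi$df)
  bb <- fpas:::freq_to_bin(2.5, spi$df)
  ch_t <- which.max(sim$target_topo); ch_b <- which.max(sim$base_topo)
  expect_equal(unname(sps$amps[ch_t, tb] / spi$amps[ch_t, tb]), 0.5,
               tolerance = 1e-3)
  expect_equal(sps$amps[ch_b, bb], spi$amps[ch_b, bb], tolerance = 1e-4)
})

test_that("dataset simulation writes a complete, reproducible manifest", {
  dir1 <- file.path(tempdir(), "fpas_ds1")
  sim <- simulation_spec(n_participants = 2, seed = 4)
  sq_fn <- function(condition, participant) short_seq_spec(seed = participant)
  man <- simulate_dataset(sim, dir1, conditions = "fear",
                          n_trials_per_condition = 2, seq_spec_fn = sq_fn)
  expect_equal(nrow(man), 2 * 1 * 2 * 2)   # participants x cond x type x trials
  expect_true(all(file.exists(file.path(dir1, man$file))))
  rec <- load_recording(file.path(dir1, man$file[1]))
  expect_equal(nrow(rec$data), 130)
  # reproducible gains under the master seed
  g1 <- participant_params(sim, 1)$gain
  g2 <- participant_params(sim, 1)$gain
  expect_identical(g1, g2)
  # degenerate gain limit
  sim0 <- simulation_spec(n_participants = 1, participant_gain_sd = 0)
  expect_equal(participant_params(sim0, 1)$gain, 1)
})

test_that("1/f noise slope is recoverable from the spectrum", {
  sim <- simulation_spec(base_amp = numeric(0), target_amp = numeric(0),
                         target_harmonics = integer(0),
                         erp_components = list(), noise_sigma = 10,
                         noise_exponent = 1, n_participants = 1, seed = 6)
  sq <- short_seq_spec()
  rec <- simulate_recording(sq, sim, "intact", 1, 3)
  sp <- amplitude_spectrum_matrix(rec$data, rec$rate)
  pooled <- colMeans(sp$amps)
  sel <- sp$freq >= 0.5 & sp$freq <= 100
  fit <- stats::lm(log(pooled[sel]^2) ~ log(sp$freq[sel]))
  expect_equal(unname(-stats::coef(fit)[2]), 1, tolerance = 0.2)
})

test_that("behavior simulation matches the signal-detection closed forms", {
  tb0 <- simulate_behavior(0, 10000, seed = 8)
  d0 <- score_detection(tb0)$dprime
  expect_lt(abs(d0), 0.2)
  tb <- simulate_behavior(1.5, 10000, seed = 9)
  expect_equal(score_detection(tb)$dprime, 1.5, tolerance = 0.1)
  tb2 <- simulate_behavior(2, 20000, seed = 10)
  hits <- sum(tb2$target_present & tb2$response == "yes")
  expect_equal(hits / sum(tb2$target_present), stats::pnorm(1),
               tolerance = 0.02)
  expect_error(simulate_behavior(1, 11), "even")
})
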