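test_that("notch_base removes the base rate but spares the target rate", {
  rate <- 512; n <- rate * 30
  t <- (0:(n - 1)) / rate
  lay <- biosemi128_layout()
  data <- rbind(sin(2 * pi * 2.5 * t), sin(2 * pi * 2.5 / 3 * t), 0 * t)
  rec <- eeg_recording(data, rate, lay$names[1:3], lay$positions[1:3, ])
  out <- notch_base(rec)
  core <- 2000:13000
  expect_lt(max(abs(out$data[1, core])), 0.10)
  amp_t <- sqrt(2 * mean(out$data[2, core]^2))
  expect_equal(amp_t, 1, tolerance = 0.05)
  expect_equal(out$data[3, ], rep(0, n))
})

test_that("target epochs follow the 48 - 4 rule and the exact rejection boundary", {
  sq <- sequence_spec("fear", seed = 1)
  sim <- simulation_spec(noise_sigma = 0, n_participants = 1, seed = 2)
  rec <- simulate_recording(sq, sim, "intact", 1, 1)
  trial <- segment_trials(rec)[[1]]
  eps <- extract_target_epochs(trial, sq)
  expect_equal(dim(eps$epochs), c(44, 130, round(0.8 * 512)))
  # a 150 uV spike inside one surviving epoch removes exactly that epoch
  spike <- trial
  info <- fpas:::sequence_slot_info(sq)
  onset3 <- trial$events$sample[1] +
    round(info$onset_s[info$is_target][3] * 512)
  spike$data[5, onset3 + 10] <- 150
  eps2 <- extract_target_epochs(spike, sq)
  expect_equal(dim(eps2$epochs)[1], 43)
  expect_equal(eps2$meta$n_rejected, 1)
  # boundary convention: |amp| exactly at 100 is kept, epsilon above is not
  edge <- trial
  edge$data[, ] <- pmin(pmax(edge$data, -50), 50)
  edge$data[7, onset3 + 20] <- 100
  expect_equal(dim(extract_target_epochs(edge, sq)$epochs)[1], 44)
  edge$data[7, onset3 + 20] <- 100 + 1e-9
  expect_equal(dim(extract_target_epochs(edge, sq)$epochs)[1], 43)
})

test_that("epoch-count equalization subsamples reproducibly to the minimum", {
  mk <- function(n) epoch_set(array(rnorm(n * 2 * 10), c(n, 2, 10)), 512)
  sets <- list(a = mk(40), b = mk(38))
  eq1 <- equalize_epoch_counts(sets, seed = 9)
  eq2 <- equalize_epoch_counts(sets, seed = 9)
  expect_equal(dim(eq1$a$epochs)[1], 38)
  expect_equal(dim(eq1$b$epochs)[1], 38)
  expect_identical(eq1$a$epochs, eq2$a$epochs)
  eq3 <- equalize_epoch_counts(sets, seed = 10)
  expect_false(identical(eq1$a$epochs, eq3$a$epochs))
})

test_that("baseline correction zeroes the pre-target mean and is idempotent", {
  n_pre <- round(0.4 * 512)
  eps <- epoch_set(array(rnorm(5 * 3 * 2 * n_pre) + 7,
                         c(5, 3, 2 * n_pre)), 512)
  bc <- baseline_correct(eps)
  pre_means <- apply(bc$epochs[, , 1:n_pre, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(pre_means)), 1e-9)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$epochs, bc$epochs, tolerance = 1e-12)
})

test_that("pointwise test applies the consecutive-significance rule", {
  rate <- 512
  n_s <- round(0.8 * rate)
  n_ch <- 128; n_p <- 12
  times <- -0.4 + (seq_len(n_s) - 1) / rate
  mk_pair <- function(bump_ms, seed) {
    set.seed(seed)
    bump <- ifelse(abs(times - 0.15) < bump_ms / 2000,
                   cos(pi * (times - 0.15) / (bump_ms / 1000))^2, 0)
    intact <- lapply(1:n_p, function(i) {
      m <- matrix(rnorm(n_ch * n_s, sd = 0.5), n_ch)
      m[1:20, ] <- m[1:20, ] + rep(2 * bump, each = 20)
      m
    })
    scrambled <- lapply(1:n_p, function(i)
      matrix(rnorm(n_ch * n_s, sd = 0.5), n_ch))
    list(intact = intact, scrambled = scrambled)
  }
  # identical data: nothing significant
  same <- lapply(1:n_p, function(i) matrix(rnorm(n_ch * n_s), n_ch))
  res0 <- pointwise_test(same, same, rate)
  expect_equal(nrow(res0$windows), 0)
  # 60 ms difference bump on 20 channels: window overlapping 150 ms
  p60 <- mk_pair(60, 17)
  res60 <- pointwise_test(p60$intact, p60$scrambled, rate)
  hit <- res60$windows[res60$windows$start_s <= 0.18 &
                         res60$windows$end_s >= 0.12, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$channel %in% biosemi128_layout()$names[1:20] |
                    hit$channel %in% as.character(1:20)))
  expect_lt(abs(hit$peak_time_s[which.max(hit$peak_t)] - 0.15), 0.02)
  # 15 ms bump: rejected by the consecutivity rule
  p15 <- mk_pair(15, 18)
  res15 <- pointwise_test(p15$intact, p15$scrambled, rate)
  expect_equal(nrow(res15$windows[res15$windows$start_s <= 0.18 &
                                    res15$windows$end_s >= 0.12, ]), 0)
  # rule arithmetic: at 512 Hz a run must exceed 13 points
  sig13 <- matrix(0, 2, n_s); sig13[1, 100:112] <- 100   # 13 points
  sig14 <- matrix(0, 2, n_s); sig14[1, 100:113] <- 100   # 14 points
  flat <- lapply(1:n_p, function(i) matrix(0, 2, n_s))
  shift13 <- lapply(1:n_p, function(i) sig13 + matrix(rnorm(2 * n_s, sd = 1e-6), 2))
  shift14 <- lapply(1:n_p, function(i) sig14 + matrix(rnorm(2 * n_s, sd = 1e-6), 2))
  expect_equal(nrow(pointwise_test(shift13, flat, rate)$windows), 0)
  w14 <- pointwise_test(shift14, flat, rate)$windows
  expect_equal(nrow(w14), 1)
  expect_equal(w14$n_points, 14)
  expect_error(pointwise_test(p60$intact[1], p60$scrambled[1], rate),
               "at least 2")
})
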