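make_rec <- function(data, rate = 512, events = TRUE) {
  lay <- biosemi128_layout()
  n_ch <- nrow(data)
  eeg_recording(data, rate, lay$names[seq_len(n_ch)],
                lay$positions[seq_len(n_ch), , drop = FALSE],
                events = if (events)
                  data.frame(sample = round(2 * rate) + 1L, code = "seq_onset",
                             stringsAsFactors = FALSE)
                else data.frame(sample = integer(), code = character()))
}

test_that("preprocess attenuates the notched bands, preserves the passband,

           and halves the rate", {
  rate <- 512; n <- rate * 20
  t <- (0:(n - 1)) / rate
  data <- rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t), rnorm(n))
  rec <- make_rec(data, events = FALSE)
  out <- preprocess(rec)
  expect_equal(out$rate, 256)
  expect_equal(ncol(out$data), n / 2)
  core <- 500:4500                       # away from filter edge transients
  amp50 <- max(abs(out$data[1, core]))
  expect_lt(amp50, 10^(-20 / 20))        # > 20 dB down at 50 Hz
  t2 <- (core - 1) / 256
  amp10 <- sqrt(2 * mean(out$data[2, core]^2))
  expect_equal(amp10, 1, tolerance = 0.05)
  # zero-phase contract: peak cross-correlation with the input at lag 0
  ref <- sin(2 * pi * 10 * t2)
  cc <- sapply(-3:3, function(l) {
    idx <- core
    stats::cor(out$data[2, idx], sin(2 * pi * 10 * ((idx - 1 - l) / 256)))
  })
  expect_equal(which.max(cc), 4)         # lag 0
  expect_error(preprocess(make_rec(data, rate = 256, events = FALSE)),
               "512")
})

test_that("segment_trials extracts 61.6 s trials with correct sample counts", {
  rate <- 256
  n <- round(rate * 65)
  rec <- make_rec(matrix(rnorm(2 * n), 2), rate = rate)
  trials <- segment_trials(rec)
  expect_length(trials, 1)
  expect_equal(ncol(trials[[1]]$data), 15770)   # round(61.6 * 256)
  none <- make_rec(matrix(rnorm(2 * n), 2), rate = rate, events = FALSE)
  expect_length(segment_trials(none), 0)
  short <- make_rec(matrix(rnorm(2 * 600), 2), rate = rate)
  expect_error(segment_trials(short), "outside the recording")
})

test_that("channel interpolation averages the three nearest neighbours", {
  lay <- biosemi128_layout()
  n <- 100
  data <- matrix(rnorm(130 * n), 130)
  rec <- eeg_recording(data, 512, lay$names, lay$positions)
  # neighbours carrying an identical signal reproduce it exactly
  nb <- nearest_neighbours(lay$positions, "A1", scalp_channels(rec))
  s <- rnorm(n)
  rec$data[nb, ] <- rep(s, each = 3)
  fixed <- interpolate_channels(rec, "A1")
  expect_equal(fixed$data["A1", ], s)
  expect_equal(interpolate_channels(fixed, "A1")$data["A1", ],
               fixed$data["A1", ])       # idempotent
  expect_error(interpolate_channels(rec, "Zz9"), "unknown")
  nopos <- eeg_recording(data, 512, lay$names)
  expect_error(interpolate_channels(nopos, "A1"), "positions")
})

test_that("neighbour selection matches a brute-force distance sort", {
  lay <- biosemi128_layout()
  good <- lay$names[lay$scalp]
  for (ch in lay$names) {
    got <- nearest_neighbours(lay$positions, ch, good, k = 3)
    others <- setdiff(good, ch)
    d <- sqrt(rowSums((lay$positions[others, , drop = FALSE] -
                         matrix(lay$positions[ch, ], length(others), 2,
                                byrow = TRUE))^2))
    expect_identical(got, others[order(d)][1:3])
  }
})

test_that("re-referencing obeys its algebraic contracts", {
  lay <- biosemi128_layout()
  data <- matrix(rnorm(130 * 50), 130) + 5   # constant offset on all channels
  rec <- eeg_recording(data, 512, lay$names, lay$positions)
  avg <- rereference(rec, "average")
  expect_lt(max(abs(colSums(avg$data[scalp_channels(avg), ]))), 1e-9)
  expect_equal(rereference(avg, "average")$data, avg$data, tolerance = 1e-12)
  # a common offset is removed entirely
  rec2 <- rec; rec2$data <- rec$data + 3
  expect_equal(rereference(rec2, "average")$data, avg$data, tolerance = 1e-9)
  mast <- rereference(rec, "linked_mastoids")
  expect_equal(mast$data["M1", ] + mast$data["M2", ],
               rep(0, 50), tolerance = 1e-9)
  nomast <- eeg_recording(data[1:128, ], 512, lay$names[1:128])
  expect_error(rereference(nomast, "linked_mastoids"), "mastoid")
})

test_that("crop_and_average keeps integer cycles and averages like a mean", {
  expect_equal(52.8 * 2.5 / 3, 44)       # target cycles in the crop
  expect_equal(52.8 * 2.5, 132)          # base cycles in the crop
  rate <- 256
  n <- round(61.6 * rate)
  tr <- make_rec(matrix(rnorm(2 * n), 2), rate = rate)
  avg <- crop_and_average(list(tr, tr, tr))
  one <- crop_and_average(list(tr))
  expect_equal(avg$data, one$data)
  # 52.8 s on the sample grid (FFT-friendly count within 2 samples)
  expect_lte(abs(ncol(avg$data) - 52.8 * rate), 2)
  # independent noise shrinks as 1/sqrt(N)
  set.seed(31)
  mk <- function() make_rec(matrix(rnorm(2 * n), 2), rate = rate)
  sd1 <- sd(crop_and_average(list(mk()))$data)
  sd16 <- sd(crop_and_average(replicate(16, mk(), simplify = FALSE))$data)
  expect_equal(sd16 / sd1, 1 / 4, tolerance = 0.15)
  expect_error(crop_and_average(list()), "empty")
})

test_that("amplitude spectra use 2/N normalization at 0.0189 Hz resolution", {
  rate <- 256
  n <- round(52.8 * rate)
  t <- (0:(n - 1)) / rate
  f44 <- 44 / 52.8                       # exactly 44 cycles in the window
  rec <- make_rec(matrix(sin(2 * pi * f44 * t), 1), rate = rate,
                  events = FALSE)
  sp <- amplitude_spectrum(rec)
  expect_equal(round(sp$df, 4), 0.0189)
  bin <- fpas:::freq_to_bin(f44, sp$df)
  # N = round(52.8 * 256) is 0.2 samples off an exact 44-cycle window, so
  # the bin reads the amplitude to ~1e-4 with matching residual leakage
  expect_equal(unname(sp$amps[1, bin]), 1, tolerance = 1e-3)
  expect_lt(max(sp$amps[1, c(bin - 1, bin + 1)]), 1e-2)
  # Parseval: sum of single-sided powers equals the mean square
  x <- rnorm(n)
  spx <- amplitude_spectrum_matrix(x, rate)
  ms <- mean(x^2)
  a <- spx$amps[1, ]
  nb <- length(a)
  nyq <- if (n %% 2 == 0) a[nb]^2 else a[nb]^2 / 2   # Nyquist only if n even
  power <- a[1]^2 + sum(a[2:(nb - 1)]^2 / 2) + nyq
  expect_equal(power, ms, tolerance = 1e-9)
})
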