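# Brute-force reference for the local-noise rule: offsets 2..13 on each
# side, drop the single max and min of the 24-bin set, then mean/SD.
ref_noise <- function(v, bin) {
  nb <- v[bin + c(-13:-2, 2:13)]
  nb <- nb[-c(which.max(nb), which.min(nb))]
  c(mu = mean(nb), sigma = sd(nb))
}

test_that("noise_stats matches the brute-force rule on random spectra", {
  set.seed(71)
  for (i in 1:2000) {
    v <- rexp(40)
    bin <- sample(14:26, 1)
    got <- noise_stats(v, bin)
    ref <- ref_noise(v, bin)
    expect_identical(c(mu = got$mu, sigma = got$sigma), ref)
  }
  # noise-set size: flat-with-one-outlier window is healed by trimming
  v <- rep(2, 40); v[10] <- 50
  st <- noise_stats(v, 20)
  expect_equal(st$mu, 2); expect_equal(st$sigma, 0)
  flat <- noise_stats(rep(3, 40), 20)
  expect_equal(flat$mu, 3); expect_equal(flat$sigma, 0)
  expect_equal(length(fpas:::noise_offsets(noise_policy())) - 2, 22)
  expect_error(noise_stats(rep(1, 20), 5), "edge")
})

test_that("candidate target harmonics skip the base-coincident bins", {
  hs <- harmonic_frequencies(2.5 / 3, fmax = 5.9, exclude_base = 2.5)
  expect_equal(nrow(hs), 5)
  expect_equal(hs$freq, c(1, 2, 4, 5, 7) * 2.5 / 3, tolerance = 1e-9)
  expect_equal(round(hs$freq, 2), c(0.83, 1.67, 3.33, 4.17, 5.83))
  base <- harmonic_frequencies(2.5, fmax = 7.6, exclude_base = NULL)
  expect_equal(base$freq, c(2.5, 5, 7.5))
})

test_that("harmonic z-scores are definitional against the local noise", {
  set.seed(3)
  nbins <- 400
  df <- 1 / 52.8
  amps <- matrix(rexp(2 * nbins, 2), 2, nbins)
  spec <- amplitude_spectrum_set(amps, df)
  pooled <- colMeans(amps)
  bin <- fpas:::freq_to_bin(2.5 / 3, df)
  ref <- ref_noise(pooled, bin)
  # construct the pooled value to sit exactly 2.32 sigma above mu
  target <- ref[["mu"]] + 2.32 * ref[["sigma"]]
  amps[, bin] <- target
  spec <- amplitude_spectrum_set(amps, df)
  hz <- harmonic_z(spec, 2.5 / 3, fmax = 0.9)
  expect_equal(hz$z[1], 2.32, tolerance = 1e-9)
  expect_equal(hz$bin[1], bin)
})

test_that("harmonic selection counts leading runs and equalizes upward", {
  expect_length(select_harmonics(c(5, 4, 3, 3, 1), c(3, 1, 0, 0, 0)), 4)
  empty <- select_harmonics(c(1, 0.5, 2), c(2.2, 1, 0))
  expect_length(empty, 0)
  expect_equal(attr(empty, "n_selected"), 0L)
  # scrambled run longer than intact: the max rule wins
  expect_length(select_harmonics(c(2.4, 1, 1), c(3, 3, 3)), 3)
  expect_length(select_harmonics(c(2.33, 2.33, 1), c(1, 5, 5)), 2)
})

test_that("quantify returns bsa/snr per channel and sums additively", {
  flat <- amplitude_spectrum_set(matrix(2, 3, 100), 0.02)
  q <- quantify(flat, c(30, 50))
  expect_true(all(q$bsa == 0))
  expect_true(all(q$snr == 1))
  expect_equal(q$summed_bsa, rowSums(q$bsa))
  # injected amplitude on a flat floor
  amps <- matrix(1, 1, 100); amps[1, 40] <- 1 + 0.7
  q2 <- quantify(amplitude_spectrum_set(amps, 0.02), 40)
  expect_equal(unname(q2$bsa[1, 1]), 0.7, tolerance = 1e-9)
  expect_equal(unname(q2$snr[1, 1]), 1.7, tolerance = 1e-9)
  # additivity over bins
  amps3 <- matrix(rexp(100), 1, 100)
  sp3 <- amplitude_spectrum_set(amps3, 0.02)
  q3 <- quantify(sp3, c(30, 60))
  expect_equal(q3$summed_bsa,
               quantify(sp3, 30)$summed_bsa + quantify(sp3, 60)$summed_bsa)
})

test_that("bh_fdr reproduces the step-up procedure exactly", {
  expect_false(any(bh_fdr(rep(1, 10))))
  expect_true(all(bh_fdr(rep(0, 10))))
  expect_true(all(bh_fdr(c(0.001, 0.008, 0.039, 0.041), q = 0.05)))
  # brute-force step-up oracle on random inputs
  step_up <- function(p, q) {
    m <- length(p); o <- order(p); ps <- p[o]
    k <- which(ps <= (1:m) * q / m)
    keep <- logical(m)
    if (length(k)) keep[o[1:max(k)]] <- TRUE
    keep
  }
  set.seed(41)
  for (i in 1:500) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p, 0.05), step_up(p, 0.05))
    expect_identical(bh_fdr(p, 0.2), step_up(p, 0.2))
  }
})

test_that("the intact-scrambled chunk contrast flags exactly the loaded channels", {
  set.seed(13)
  n_ch <- 128; nbins <- 600
  df <- 1 / 52.8
  base <- matrix(1, n_ch, nbins)
  bins <- fpas:::freq_to_bin(c(1, 2, 4, 5, 7) * 2.5 / 3, df)
  intact <- base; scrambled <- base
  loaded <- sample(n_ch, 10)
  intact[loaded, bins] <- intact[loaded, bins] + 0.5
  si <- amplitude_spectrum_set(intact, df)
  ss <- amplitude_spectrum_set(scrambled, df)
  res <- contrast_intact_scrambled(si, ss, bins)
  expect_identical(sort(which(res$sig)), sort(loaded))
  expect_true(all(is.infinite(res$z[loaded])))
  # identical spectra: all z = 0, empty mask
  res0 <- contrast_intact_scrambled(si, si, bins)
  expect_true(all(res0$z == 0))
  expect_false(any(res0$sig))
  # chunks must not overlap
  expect_error(contrast_intact_scrambled(si, ss, c(100, 110)), "overlap")
  # 25-bin chunk geometry: harmonics at the default rates never collide
  expect_gt(min(diff(bins)), 25)
})

test_that("per-participant quantification feeds a paired group test", {
  df <- 1 / 52.8
  mk <- function(amp) {
    a <- matrix(1, 4, 400)
    a[, fpas:::freq_to_bin(2.5 / 3, df)] <- 1 + amp
    amplitude_spectrum_set(a, df)
  }
  ids <- as.character(1:6)
  intact <- setNames(lapply(c(0.9, 1, 1.1, 0.8, 1.2, 1), mk), ids)
  scrambled <- setNames(lapply(c(0.38, 0.52, 0.61, 0.29, 0.7, 0.5), mk), ids)
  res <- per_participant_response(intact, scrambled,
                                  fpas:::freq_to_bin(2.5 / 3, df),
                                  sig_channels = 1:4)
  expect_equal(res$per_participant$intact - res$per_participant$scrambled,
               c(0.9, 1, 1.1, 0.8, 1.2, 1) - c(0.38, 0.52, 0.61, 0.29, 0.7, 0.5),
               tolerance = 1e-9)
  expect_lt(res$p, 0.01)
  # identical conditions give t = 0
  same <- per_participant_response(intact, intact,
                                   fpas:::freq_to_bin(2.5 / 3, df), 1:4)
  expect_equal(same$t, 0)
  # missing condition: excluded with a warning; single pair errors
  expect_warning(
    per_participant_response(intact[1:3], scrambled[2:3],
                             fpas:::freq_to_bin(2.5 / 3, df), 1:4),
    "excluded")
  expect_error(
    suppressWarnings(per_participant_response(intact[1], scrambled[1],
                                              fpas:::freq_to_bin(2.5 / 3, df),
                                              1:4)),
    "at least 2")
})
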