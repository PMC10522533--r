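#' Local-noise estimation policy
#'
#' Defines the noise window used for z-scores, baseline subtraction and
#' SNR: `half_width` bins on each side of the bin of interest, excluding
#' the `skip_adjacent` immediately adjacent bins (spectral leakage) and,
#' if `drop_extremes`, the single maximum and minimum of the whole window.
#' The default (12 bins per side after skipping 1 adjacent bin, i.e.
#' offsets 2..13, then dropping the two extremes) leaves 22 noise bins.
#'
#' @param half_width Bins kept on each side after skipping (default 12).
#' @param skip_adjacent Immediately adjacent bins skipped (default 1).
#' @param drop_extremes Drop the window's max and min (default `TRUE`).
#' @return An object of class `noise_policy`.
#' @export
noise_policy <- function(half_width = 12, skip_adjacent = 1,
                         drop_extremes = TRUE) {
  stopifnot(half_width > skip_adjacent)
  structure(list(half_width = half_width, skip_adjacent = skip_adjacent,
                 drop_extremes = drop_extremes), class = "noise_policy")
}

# Offsets of the noise bins relative to the bin of interest.
noise_offsets <- function(policy) {
  o <- (policy$skip_adjacent + 1):(policy$skip_adjacent + policy$half_width)
  c(-rev(o), o)
}

# Mean/SD of the noise set around `values[center]`, per the policy.
noise_mu_sigma <- function(values, center, policy) {
  nb <- values[center + noise_offsets(policy)]
  if (policy$drop_extremes && length(nb) > 2)
    nb <- nb[-c(which.max(nb), which.min(nb))]
  c(mu = mean(nb), sigma = stats::sd(nb))
}

#' Local-noise statistics at a frequency bin
#'
#' Mean and SD of the surrounding noise bins of an amplitude spectrum,
#' under a [noise_policy()].
#'
#' @param spec An [amplitude_spectrum_set()] or a numeric amplitude vector.
#' @param bin Bin index (1-based; bin k is frequency (k-1)*df).
#' @param policy A [noise_policy()].
#' @return For a vector input, a list with `mu` and `sigma`; for a
#'   spectrum set, a two-column matrix (`mu`, `sigma`) with one row per
#'   channel.
#' @export
noise_stats <- function(spec, bin, policy = noise_policy()) {
  amps <- if (inherits(spec, "amplitude_spectrum_set")) spec$amps
          else matrix(as.numeric(spec), nrow = 1)
  span <- policy$skip_adjacent + policy$half_width
  if (bin - span < 1 || bin + span > ncol(amps))
    stop("bin ", bin, " is closer than ", span, " bins to the spectrum edge")
  res <- t(apply(amps, 1, noise_mu_sigma, center = bin, policy = policy))
  if (nrow(res) == 1L)
    list(mu = unname(res[1, "mu"]), sigma = unname(res[1, "sigma"]))
  else res
}

#' Candidate harmonic frequencies of a tagged response
#'
#' Integer multiples of `f0` up to `fmax`, excluding harmonics that
#' coincide with multiples of `exclude_base` (for the 0.833 Hz target,
#' every third harmonic falls on the 2.5 Hz base response and is excluded).
#'
#' @param f0 Fundamental frequency in Hz.
#' @param fmax Highest frequency considered (default 5.9 Hz, giving the
#'   first 5 non-base-coincident target harmonics).
#' @param exclude_base Base rate whose multiples are skipped (default
#'   2.5 Hz; `NULL` to keep all harmonics).
#' @return Data frame with `k` (harmonic number) and `freq` (Hz).
#' @export
harmonic_frequencies <- function(f0, fmax = 5.9, exclude_base = 2.5) {
  k <- seq_len(floor(fmax / f0 + 1e-9))
  if (!is.null(exclude_base)) {
    # tolerant coincidence test so a rounded f0 (0.833, 0.8333, ...) still
    # excludes the base bins; true non-multiples sit at distance >= 1/3
    ratio <- k * f0 / exclude_base
    k <- k[abs(ratio - round(ratio)) > 0.01]
  }
  data.frame(k = k, freq = k * f0)
}

#' Harmonic z-scores on the channel-pooled spectrum
#'
#' Pools channels (arithmetic mean of amplitude spectra), then computes at
#' each candidate harmonic bin the z-score of the amplitude against the
#' local noise bins: z = (amp - mu) / sigma under the [noise_policy()].
#'
#' @param spec An [amplitude_spectrum_set()].
#' @param f0 Fundamental of the tagged response in Hz.
#' @param policy A [noise_policy()].
#' @param exclude_base Base rate whose coinciding harmonics are skipped
#'   (default 2.5 Hz; use `NULL` when scoring the base response itself).
#' @param fmax Highest harmonic frequency considered.
#' @return Data frame with `k`, `freq`, `bin`, `amp`, `mu`, `sigma`, `z`.
#' @export
harmonic_z <- function(spec, f0, policy = noise_policy(),
                       exclude_base = 2.5, fmax = 5.9) {
  stopifnot(inherits(spec, "amplitude_spectrum_set"))
  pooled <- colMeans(spec$amps)
  hs <- harmonic_frequencies(f0, fmax, exclude_base)
  hs$bin <- freq_to_bin(hs$freq, spec$df)
  stats_ <- t(vapply(hs$bin, function(b)
    noise_mu_sigma(pooled, b, policy), c(mu = 0, sigma = 0)))
  hs$amp <- pooled[hs$bin]
  hs$mu <- stats_[, "mu"]
  hs$sigma <- stats_[, "sigma"]
  hs$z <- ifelse(hs$sigma > 0, (hs$amp - hs$mu) / hs$sigma,
                 ifelse(hs$amp > hs$mu, Inf, 0))
  hs
}

#' Select the significant consecutive harmonics
#'
#' Counts, separately for the intact and the scrambled sequence type, the
#' longest run of significant harmonics (z > threshold) starting at the
#' first candidate; the retained count is the maximum over the two types
#' (responses at the extra non-significant harmonics add only zeros on
#' average, so equalizing upward is harmless). An empty selection flags
#' "no significant response".
#'
#' @param z_intact,z_scrambled Numeric z vectors over the same candidate
#'   harmonics (e.g. the `z` column of [harmonic_z()]).
#' @param threshold Significance threshold (default 2.32, i.e. p < 0.01
#'   one-tailed).
#' @return Integer vector of selected harmonic indices (possibly empty),
#'   with attribute `n_selected`.
#' @export
select_harmonics <- function(z_intact, z_scrambled, threshold = 2.32) {
  stopifnot(length(z_intact) == length(z_scrambled))
  leading_run <- function(z) {
    below <- which(!(z > threshold))
    if (!length(below)) length(z) else below[1] - 1L
  }
  n <- max(leading_run(z_intact), leading_run(z_scrambled))
  structure(seq_len(n), n_selected = n)
}

#' Baseline-subtracted amplitude, SNR and harmonic sum per channel
#'
#' At each selected harmonic bin and channel: baseline-subtracted amplitude
#' bsa = amp - mu and SNR = amp / mu, with mu/sigma from the local noise
#' bins; `summed_bsa` sums bsa over the selected harmonics per channel.
#'
#' @param spec An [amplitude_spectrum_set()].
#' @param harmonic_bins Integer bin indices of the selected harmonics.
#' @param policy A [noise_policy()].
#' @return A list with matrices `bsa` and `snr` (channels x harmonics; SNR
#'   is `NA` where mu = 0) and the vector `summed_bsa` (per channel).
#' @export
quantify <- function(spec, harmonic_bins, policy = noise_policy()) {
  stopifnot(inherits(spec, "amplitude_spectrum_set"))
  n_ch <- nrow(spec$amps)
  bsa <- snr <- matrix(0, n_ch, length(harmonic_bins),
                       dimnames = list(rownames(spec$amps), NULL))
  for (j in seq_along(harmonic_bins)) {
    b <- harmonic_bins[j]
    st <- noise_stats(spec, b, policy)
    if (is.list(st)) st <- matrix(c(st$mu, st$sigma), 1,
                                  dimnames = list(NULL, c("mu", "sigma")))
    bsa[, j] <- spec$amps[, b] - st[, "mu"]
    snr[, j] <- ifelse(st[, "mu"] > 0, spec$amps[, b] / st[, "mu"], NA_real_)
  }
  list(bsa = bsa, snr = snr, summed_bsa = rowSums(bsa))
}

#' Benjamini-Hochberg false discovery rate mask
#'
#' Step-up FDR control: rejects all hypotheses with p at or below the
#' largest p_(k) satisfying p_(k) <= k q / m.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Channel-wise intact minus scrambled contrast at the selected harmonics
#'
#' Subtracts the scrambled from the intact amplitude spectrum, extracts a
#' 25-bin chunk around each selected harmonic (centre + 12 bins each
#' side), sums the chunks element-wise across harmonics, and z-scores the
#' centre (13th) position of the summed chunk per channel against the
#' remaining chunk bins under the noise policy (adjacent bins and the
#' extremes excluded). One-tailed p-values (intact > scrambled) are
#' corrected across channels with Benjamini-Hochberg.
#'
#' @param spec_intact,spec_scrambled [amplitude_spectrum_set()]s sharing
#'   resolution and channels.
#' @param harmonic_bins Selected harmonic bin indices.
#' @param policy A [noise_policy()] (its `half_width` is capped by the
#'   chunk's 12 available side bins).
#' @param q FDR level (default 0.05).
#' @param chunk_half Bins on each side of the harmonic in a chunk
#'   (default 12, i.e. 25-bin chunks).
#' @return Data frame with `channel`, `z`, `p`, `sig` (post-FDR mask).
#' @export
contrast_intact_scrambled <- function(spec_intact, spec_scrambled,
                                      harmonic_bins,
                                      policy = noise_policy(), q = 0.05,
                                      chunk_half = 12) {
  stopifnot(inherits(spec_intact, "amplitude_spectrum_set"),
            inherits(spec_scrambled, "amplitude_spectrum_set"))
  if (abs(spec_intact$df - spec_scrambled$df) > 1e-12)
    stop("spectra have different bin resolutions")
  if (nrow(spec_intact$amps) != nrow(spec_scrambled$amps))
    stop("spectra have different channel sets")
  if (length(harmonic_bins) > 1 &&
      min(diff(sort(harmonic_bins))) < 2 * chunk_half + 1)
    stop("harmonics closer than one chunk width: chunks would overlap")
  diffsp <- spec_intact$amps - spec_scrambled$amps
  width <- 2L * chunk_half + 1L
  acc <- matrix(0, nrow(diffsp), width)
  for (b in harmonic_bins) {
    if (b - chunk_half < 1 || b + chunk_half > ncol(diffsp))
      stop("chunk around bin ", b, " exceeds the spectrum")
    acc <- acc + diffsp[, (b - chunk_half):(b + chunk_half)]
  }
  centre <- chunk_half + 1L
  pol <- noise_policy(half_width = min(policy$half_width,
                                       chunk_half - policy$skip_adjacent),
                      skip_adjacent = policy$skip_adjacent,
                      drop_extremes = policy$drop_extremes)
  z <- apply(acc, 1, function(v) {
    st <- noise_mu_sigma(v, centre, pol)
    if (st["sigma"] > 0) (v[centre] - st["mu"]) / st["sigma"]
    else if (v[centre] > st["mu"]) Inf else 0
  })
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(channel = rownames(diffsp) %||% seq_along(z),
             z = z, p = p, sig = bh_fdr(p, q),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-participant response quantification and group test
#'
#' For each participant, sums the baseline-subtracted amplitude at the
#' (group-determined) harmonic bins and averages it over the
#' (group-determined) significant channels, separately for intact and
#' scrambled spectra; then tests intact - scrambled > 0 with a paired
#' one-tailed t-test.
#'
#' @param spectra_intact,spectra_scrambled Named lists (one
#'   [amplitude_spectrum_set()] per participant; names = participant ids,
#'   matched between lists).
#' @param harmonic_bins Selected harmonic bin indices (group level).
#' @param sig_channels Channel names (or indices) to average over.
#' @param policy A [noise_policy()].
#' @return A list with `per_participant` (data frame: `participant`,
#'   `intact`, `scrambled`) and `t`, `df`, `p`, `cohen_d` of the paired
#'   contrast.
#' @export
per_participant_response <- function(spectra_intact, spectra_scrambled,
                                     harmonic_bins, sig_channels,
                                     policy = noise_policy()) {
  ids <- intersect(names(spectra_intact), names(spectra_scrambled))
  dropped <- setdiff(union(names(spectra_intact), names(spectra_scrambled)), ids)
  if (length(dropped))
    warning("participant(s) missing a condition, excluded: ",
            paste(dropped, collapse = ", "))
  if (length(ids) < 2) stop("need at least 2 complete participants")
  one <- function(spec) {
    q <- quantify(spec, harmonic_bins, policy)
    mean(q$summed_bsa[sig_channels])
  }
  intact <- vapply(spectra_intact[ids], one, 0)
  scrambled <- vapply(spectra_scrambled[ids], one, 0)
  ct <- control_contrast(intact, scrambled)
  list(per_participant = data.frame(participant = ids, intact = intact,
                                    scrambled = scrambled, row.names = NULL,
                                    stringsAsFactors = FALSE),
       t = ct$t, df = ct$df, p = ct$p, cohen_d = ct$cohen_d)
}
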