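#' Notch out the base presentation rate and its harmonics
#'
#' Removes the activity tied to the general sound-presentation rate (2.5,
#' 5, 7.5 Hz) before time-domain epoching, so that the target-locked ERP is
#' not dominated by the periodic base response. Zero-phase 2nd-order
#' Butterworth band-stop filters of `width_hz` are applied in the frequency
#' domain; the 0.833 Hz target response lies well outside the notches and
#' is preserved.
#'
#' @param rec An [eeg_recording()].
#' @param freqs Notch centre frequencies in Hz (default `c(2.5, 5, 7.5)`).
#' @param width_hz Width of each notch (default 0.5).
#' @return The filtered [eeg_recording()].
#' @export
notch_base <- function(rec, freqs = c(2.5, 5, 7.5), width_hz = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * max(freqs))
    stop("sampling rate too low for the requested notches")
  rec$data <- zero_phase_filter_matrix(rec$data, rec$rate,
                                       notch_mag2(rec$rate, freqs, width_hz))
  rec
}

# Squared magnitude response of a cascade of 2nd-order Butterworth
# band-stop filters at `freqs`, each `width_hz` wide.
notch_mag2 <- function(rate, freqs, width_hz = 0.5) {
  nfs <- lapply(freqs, function(f0)
    signal::butter(2, c(f0 - width_hz / 2, f0 + width_hz / 2) / (rate / 2),
                   type = "stop"))
  function(w) {
    g <- rep(1, length(w))
    for (nf in nfs) g <- g * Mod(iir_response(nf$b, nf$a, w))^2
    g
  }
}

#' Set of stimulus-locked epochs
#'
#' @param epochs 3-D array: epochs x channels x samples (microvolts).
#' @param rate Sampling rate in Hz.
#' @param window Epoch window in seconds relative to target onset
#'   (default `c(-0.4, 0.4)`).
#' @param channel_names Channel labels.
#' @param meta Free-form metadata list.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, rate, window = c(-0.4, 0.4),
                      channel_names = NULL, meta = list()) {
  stopifnot(length(dim(epochs)) == 3)
  structure(list(epochs = epochs, rate = rate, window = window,
                 channel_names = channel_names, meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz [%g, %g] s\n",
              d[1], d[2], d[3], x$rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Extract target-locked epochs from a sequence trial
#'
#' One 800 ms epoch per target slot, from 400 ms before target onset (one
#' base cycle, used as baseline) to target offset. The first 2 and last 2
#' target epochs are deleted (they fall in the fade-in/out), and epochs
#' with any sample exceeding `reject_uv` in absolute value in any channel
#' are rejected (the boundary value itself is kept).
#'
#' @param trial An [eeg_recording()] trial with a `seq_onset` event.
#' @param seq A `stimulus_sequence` or [sequence_spec()] giving target
#'   timing.
#' @param reject_uv Artifact rejection threshold in microvolts
#'   (default 100; `Inf` disables rejection).
#' @param drop_edges Number of leading/trailing target epochs to delete
#'   (default 2 each).
#' @return An [epoch_set()] (`meta$n_rejected` counts rejected epochs).
#' @export
extract_target_epochs <- function(trial, seq, reject_uv = 100,
                                  drop_edges = 2) {
  stopifnot(inherits(trial, "eeg_recording"))
  info <- sequence_slot_info(seq)
  onset_sample <- trial$events$sample[trial$events$code == "seq_onset"][1]
  if (is.na(onset_sample)) stop("trial lacks a seq_onset event")
  rate <- trial$rate
  n_ep <- round(0.8 * rate)
  n_pre <- round(0.4 * rate)
  onsets <- info$onset_s[info$is_target]
  if (drop_edges > 0)
    onsets <- onsets[(drop_edges + 1):(length(onsets) - drop_edges)]
  n_ch <- nrow(trial$data)
  keep <- list()
  n_rejected <- 0L
  for (o in onsets) {
    start <- onset_sample + round((o - 0.4) * rate)
    if (start < 1 || start + n_ep - 1 > ncol(trial$data))
      stop("epoch at target onset ", o, " s exceeds the trial")
    ep <- trial$data[, start:(start + n_ep - 1), drop = FALSE]
    if (max(abs(ep)) > reject_uv) n_rejected <- n_rejected + 1L
    else keep[[length(keep) + 1L]] <- ep
  }
  if (!length(keep)) stop("no epochs survive artifact rejection")
  arr <- array(0, c(length(keep), n_ch, n_ep))
  for (i in seq_along(keep)) arr[i, , ] <- keep[[i]]
  epoch_set(arr, rate, channel_names = trial$channel_names,
            meta = c(trial$meta, list(n_rejected = n_rejected)))
}

#' Equalize epoch counts across condition/type cells
#'
#' Seeded random subsampling without replacement down to the smallest
#' count, so that averages across cells carry equal noise.
#'
#' @param epoch_sets List of [epoch_set()]s.
#' @param seed Integer seed.
#' @return List of [epoch_set()]s, all with the same epoch count.
#' @export
equalize_epoch_counts <- function(epoch_sets, seed = 1) {
  n_min <- min(vapply(epoch_sets, function(e) dim(e$epochs)[1], 0L))
  with_seed(seed, lapply(epoch_sets, function(e) {
    n <- dim(e$epochs)[1]
    if (n > n_min) e$epochs <- e$epochs[sort(sample(n, n_min)), , , drop = FALSE]
    e
  }))
}

#' Baseline-correct epochs on the pre-target window
#'
#' Subtracts, per epoch and channel, the mean over the 400 ms pre-target
#' interval (one full base-rate cycle, i.e. the epoch's first half).
#'
#' @param eps An [epoch_set()] whose window starts 400 ms before target
#'   onset.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(eps) {
  stopifnot(inherits(eps, "epoch_set"))
  n_pre <- round(0.4 * eps$rate)
  bl <- apply(eps$epochs[, , seq_len(n_pre), drop = FALSE], c(1, 2), mean)
  eps$epochs <- eps$epochs - as.vector(bl)   # recycles over the 3rd dim
  eps
}

#' Average an epoch set into one channels x samples matrix
#' @param eps An [epoch_set()].
#' @return Channels x samples matrix of the mean epoch.
#' @export
average_epochs <- function(eps) {
  stopifnot(inherits(eps, "epoch_set"))
  m <- apply(eps$epochs, c(2, 3), mean)
  rownames(m) <- eps$channel_names
  m
}

#' Pointwise paired test between intact and scrambled ERPs
#'
#' At each time point and channel, a paired one-tailed t-test (intact >
#' scrambled) across participants; Benjamini-Hochberg correction across
#' channels within each time point; a channel's stretch of significant
#' points is reported as a window only if it lasts strictly longer than
#' `min_dur_ms` (at 512 Hz, more than 13 consecutive points).
#'
#' @param intact_by_participant,scrambled_by_participant Lists (one per
#'   participant, paired by position) of channels x samples matrices of
#'   participant-averaged epochs.
#' @param rate Sampling rate in Hz.
#' @param window Epoch window in seconds (default `c(-0.4, 0.4)`).
#' @param min_dur_ms Minimum window duration in ms (default 25).
#' @param q FDR level (default 0.05).
#' @return A list with `windows` (data frame: `channel`, `start_s`,
#'   `end_s`, `n_points`, `peak_t`, `peak_time_s`) and the `t` matrix
#'   (channels x samples).
#' @export
pointwise_test <- function(intact_by_participant, scrambled_by_participant,
                           rate, window = c(-0.4, 0.4), min_dur_ms = 25,
                           q = 0.05) {
  n_p <- length(intact_by_participant)
  if (n_p != length(scrambled_by_participant))
    stop("conditions have different participant counts")
  if (n_p < 2) stop("need at least 2 participants")
  dims <- dim(intact_by_participant[[1]])
  n_ch <- dims[1]; n_s <- dims[2]
  diffs <- lapply(seq_len(n_p), function(i)
    intact_by_participant[[i]] - scrambled_by_participant[[i]])
  mean_d <- Reduce(`+`, diffs) / n_p
  # two-pass variance: robust against cancellation for large offsets
  ss <- matrix(0, n_ch, n_s)
  for (d in diffs) ss <- ss + (d - mean_d)^2
  sd_d <- sqrt(ss / (n_p - 1))
  tmat <- mean_d / (sd_d / sqrt(n_p))
  tmat[sd_d == 0] <- 0
  pmat <- stats::pt(tmat, df = n_p - 1, lower.tail = FALSE)
  sig <- apply(pmat, 2, bh_fdr, q = q)       # FDR across channels per time point
  n_min <- ceiling(min_dur_ms / 1000 * rate) # runs must be strictly longer

  chn <- rownames(intact_by_participant[[1]]) %||% as.character(seq_len(n_ch))
  times <- window[1] + (seq_len(n_s) - 1) / rate
  rows <- list()
  for (ch in seq_len(n_ch)) {
    r <- rle(as.vector(sig[ch, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths > n_min)) {
      idx <- starts[j]:ends[j]
      pk <- idx[which.max(tmat[ch, idx])]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = chn[ch], start_s = times[starts[j]], end_s = times[ends[j]],
        n_points = r$lengths[j], peak_t = tmat[ch, pk],
        peak_time_s = times[pk], stringsAsFactors = FALSE)
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows)
  else data.frame(channel = character(), start_s = numeric(),
                  end_s = numeric(), n_points = integer(),
                  peak_t = numeric(), peak_time_s = numeric(),
                  stringsAsFactors = FALSE)
  list(windows = windows, t = tmat)
}
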