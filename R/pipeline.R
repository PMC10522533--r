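# Default loader: read manifest rows from files on disk.
file_loader <- function(dir) function(row) load_recording(file.path(dir, row$file))

# Restrict a spectrum set to frequencies up to fmax (memory control when
# holding one spectrum per participant).
trim_spectrum <- function(spec, fmax) {
  keep <- spec$freq <= fmax
  amplitude_spectrum_set(spec$amps[, keep, drop = FALSE], spec$df)
}

#' Frequency-domain analysis of a full dataset
#'
#' Runs the complete frequency-tagging pipeline for one emotion condition:
#' per participant and sequence type, preprocess (optional), segment,
#' average-reference, crop past the fade-in and average trials; FFT the
#' averages; grand-average participants in the time domain and z-score the
#' candidate target harmonics of the pooled grand spectra; select the
#' significant consecutive harmonics (equalized across types); quantify
#' baseline-subtracted amplitude and SNR; contrast intact vs scrambled
#' spectra channel-wise with FDR correction; and quantify each
#' participant's summed response over the significant channels with a
#' paired group test.
#'
#' @param manifest Manifest `data.frame` (see [read_manifest()]).
#' @param loader Function(row) returning the [eeg_recording()] for a
#'   manifest row; defaults to reading `file` from `dir`.
#' @param dir Directory for the default loader.
#' @param condition Emotion condition to analyse (default `"fear"`).
#' @param target_rate,base_rate Tagged frequencies in Hz.
#' @param policy A [noise_policy()].
#' @param z_threshold Harmonic-selection threshold (default 2.32).
#' @param q FDR level (default 0.05).
#' @param fmax Highest candidate harmonic frequency (default 5.9 Hz).
#' @param do_preprocess Apply [preprocess()] to each recording (default
#'   `TRUE`; synthetic recordings that are already band-limited can skip
#'   it).
#' @param reref `"average"` (the standard analysis reference) or `"none"`
#'   (keep the recording reference; used when absolute per-channel
#'   amplitudes must be preserved, e.g. for parameter-recovery checks).
#' @param crop_start_s,crop_length_s Crop window passed to
#'   [crop_and_average()].
#' @param trim_hz Per-participant spectra are kept only up to this
#'   frequency (default 30 Hz).
#' @return A list of class `freqtag_report`; see Details.
#' @details The report contains `grand_spectra` (per type), `harmonics`
#'   (z tables per type), `selected` (harmonic indices), `harmonic_bins`,
#'   `quant` (grand-average [quantify()] output per type), `contrast`
#'   (channel table with FDR mask), `sig_channels`, `group` (per-participant
#'   summed response + paired test), and `base` (z tables at the base rate).
#' @export
analyze_frequency <- function(manifest, loader = NULL, dir = ".",
                              condition = "fear",
                              target_rate = 2.5 / 3, base_rate = 2.5,
                              policy = noise_policy(), z_threshold = 2.32,
                              q = 0.05, fmax = 5.9, do_preprocess = TRUE,
                              reref = c("average", "none"),
                              crop_start_s = 2, crop_length_s = 52.8,
                              trim_hz = 30) {
  if (is.null(loader)) loader <- file_loader(dir)
  reref <- match.arg(reref)
  man <- manifest[manifest$condition == condition, , drop = FALSE]
  if (!nrow(man)) stop("manifest has no rows for condition '", condition, "'")

  spectra <- list(intact = list(), scrambled = list())
  grand <- list(intact = NULL, scrambled = NULL)
  n_grand <- c(intact = 0L, scrambled = 0L)
  template <- NULL
  for (p in sort(unique(man$participant))) {
    for (type in c("intact", "scrambled")) {
      rows <- man[man$participant == p & man$type == type, , drop = FALSE]
      if (!nrow(rows)) next
      trials <- list()
      for (i in seq_len(nrow(rows))) {
        rec <- loader(rows[i, ])
        if (do_preprocess) rec <- preprocess(rec)
        segs <- segment_trials(rec)
        if (reref == "average")
          segs <- lapply(segs, rereference, scheme = "average")
        trials <- c(trials, segs)
      }
      avg <- crop_and_average(trials, crop_start_s, crop_length_s)
      template <- template %||% avg
      grand[[type]] <- if (is.null(grand[[type]])) avg$data
                       else grand[[type]] + avg$data
      n_grand[type] <- n_grand[type] + 1L
      spectra[[type]][[as.character(p)]] <-
        trim_spectrum(amplitude_spectrum(avg), trim_hz)
    }
  }
  grand_spectra <- lapply(names(grand), function(type) {
    g <- eeg_recording(grand[[type]] / n_grand[type], template$rate,
                       template$channel_names, template$positions)
    amplitude_spectrum(g)
  })
  names(grand_spectra) <- names(grand)

  harm <- lapply(grand_spectra, harmonic_z, f0 = target_rate,
                 policy = policy, exclude_base = base_rate, fmax = fmax)
  selected <- select_harmonics(harm$intact$z, harm$scrambled$z, z_threshold)
  harmonic_bins <- harm$intact$bin[selected]
  base <- lapply(grand_spectra, harmonic_z, f0 = base_rate, policy = policy,
                 exclude_base = NULL, fmax = 3 * base_rate - 0.1)

  quant <- contrast <- sig_channels <- group <- NULL
  if (length(harmonic_bins)) {
    quant <- lapply(grand_spectra, quantify, harmonic_bins = harmonic_bins,
                    policy = policy)
    contrast <- contrast_intact_scrambled(grand_spectra$intact,
                                          grand_spectra$scrambled,
                                          harmonic_bins, policy, q)
    sig_channels <- contrast$channel[contrast$sig]
    quant_channels <- if (length(sig_channels)) sig_channels
                      else contrast$channel       # fall back to all channels
    group <- per_participant_response(spectra$intact, spectra$scrambled,
                                      harmonic_bins, quant_channels, policy)
  }
  structure(
    list(condition = condition, grand_spectra = grand_spectra,
         harmonics = harm, selected = selected,
         harmonic_bins = harmonic_bins, quant = quant, contrast = contrast,
         sig_channels = sig_channels, group = group, base = base,
         spectra_by_participant = spectra),
    class = "freqtag_report")
}

#' @export
print.freqtag_report <- function(x, ...) {
  cat(sprintf("<freqtag_report> condition %s: %d harmonic(s) selected",
              x$condition, length(x$harmonic_bins)))
  if (!is.null(x$sig_channels))
    cat(sprintf(", %d significant channel(s)", length(x$sig_channels)))
  if (!is.null(x$group))
    cat(sprintf("; group intact-scrambled p = %.3g", x$group$p))
  cat("\n")
  invisible(x)
}

#' Time-domain analysis of a full dataset
#'
#' Runs the ERP pipeline for one emotion condition: per participant and
#' type, band-pass/notch filter (optional) plus base-rate notches, segment,
#' re-reference to linked mastoids, extract target-locked epochs with
#' artifact rejection, equalize epoch counts across types, baseline-correct
#' and average; then the pointwise paired test with FDR across channels and
#' the consecutive-significance rule.
#'
#' @inheritParams analyze_frequency
#' @param seq_spec A [sequence_spec()] giving target timing (slot onsets
#'   are design constants shared by all sequences).
#' @param reject_uv Epoch rejection threshold (default 100).
#' @param min_dur_ms Consecutive-significance duration (default 25).
#' @param do_bandpass Apply the 0.1-100 Hz band-pass + 50/100 Hz notches at
#'   512 Hz before the base-rate notches (default `TRUE`).
#' @param do_notch Apply the base-rate notches at 2.5/5/7.5 Hz (default
#'   `TRUE`). In paired intact-vs-scrambled contrasts on synthetic data the
#'   base response is identical in both types and cancels exactly, so the
#'   notches (and the band-pass, for band-limited synthetic noise) can be
#'   skipped without changing the contrast.
#' @param equalize_seed Seed for epoch-count equalization.
#' @return A list of class `timedomain_report` with `windows`, `t`,
#'   `averages` (per type: list of per-participant matrices) and `rate`.
#' @export
analyze_timedomain <- function(manifest, loader = NULL, dir = ".",
                               condition = "fear",
                               seq_spec = sequence_spec(target_category = condition),
                               reject_uv = 100, min_dur_ms = 25, q = 0.05,
                               do_bandpass = TRUE, do_notch = TRUE,
                               equalize_seed = 1) {
  if (is.null(loader)) loader <- file_loader(dir)
  man <- manifest[manifest$condition == condition, , drop = FALSE]
  if (!nrow(man)) stop("manifest has no rows for condition '", condition, "'")

  averages <- list(intact = list(), scrambled = list())
  rate <- NULL
  mag2 <- NULL
  for (p in sort(unique(man$participant))) {
    eps_by_type <- list()
    for (type in c("intact", "scrambled")) {
      rows <- man[man$participant == p & man$type == type, , drop = FALSE]
      if (!nrow(rows)) { eps_by_type[type] <- list(NULL); next }
      sets <- list()
      for (i in seq_len(nrow(rows))) {
        rec <- loader(rows[i, ])
        rate <- rate %||% rec$rate
        if (is.null(mag2) && (do_bandpass || do_notch)) {
          # one combined zero-phase pass: band-pass + line notches (when
          # requested) + base-rate notches
          nb <- if (do_notch) notch_mag2(rec$rate, c(2.5, 5, 7.5))
          bp <- if (do_bandpass) preprocess_mag2(rec$rate)
          mag2 <- function(w) {
            g <- rep(1, length(w))
            if (!is.null(bp)) g <- g * bp(w)
            if (!is.null(nb)) g <- g * nb(w)
            g
          }
        }
        if (!is.null(mag2))
          rec$data <- zero_phase_filter_matrix(rec$data, rec$rate, mag2)
        for (tr in segment_trials(rec)) {
          tr <- rereference(tr, "linked_mastoids")
          sets[[length(sets) + 1L]] <-
            extract_target_epochs(tr, seq_spec, reject_uv)
        }
      }
      all_eps <- do.call(abind3, lapply(sets, function(s) s$epochs))
      eps_by_type[[type]] <- epoch_set(all_eps, sets[[1]]$rate,
                                       channel_names = sets[[1]]$channel_names)
    }
    if (any(vapply(eps_by_type, is.null, TRUE))) next
    eps_by_type <- equalize_epoch_counts(eps_by_type,
                                         seed = equalize_seed + p)
    for (type in names(eps_by_type)) {
      avg <- average_epochs(baseline_correct(eps_by_type[[type]]))
      averages[[type]][[as.character(p)]] <- avg
    }
  }
  ids <- intersect(names(averages$intact), names(averages$scrambled))
  res <- pointwise_test(averages$intact[ids], averages$scrambled[ids],
                        rate = rate, min_dur_ms = min_dur_ms, q = q)
  structure(list(windows = res$windows, t = res$t, averages = averages,
                 rate = rate, condition = condition),
            class = "timedomain_report")
}

#' @export
print.timedomain_report <- function(x, ...) {
  cat(sprintf("<timedomain_report> condition %s: %d significant window(s)\n",
              x$condition, nrow(x$windows)))
  if (nrow(x$windows)) {
    best <- x$windows[which.max(x$windows$peak_t), ]
    cat(sprintf("  strongest: %s, %.0f-%.0f ms, peak t = %.2f at %.0f ms\n",
                best$channel, best$start_s * 1000, best$end_s * 1000,
                best$peak_t, best$peak_time_s * 1000))
  }
  invisible(x)
}

# Bind epoch arrays along the first (epoch) dimension.
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}

#' Parse a plain-text key = value configuration file
#'
#' Lines of `key = value`; `#` starts a comment; values are split on
#' commas and converted to numeric where possible.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    vals <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}

#' Run the full synthetic pipeline
#'
#' Simulates a dataset, runs the frequency- and time-domain analyses and
#' the behavioral scoring, and writes a machine-readable summary
#' (`summary.json`) recording all statistics together with the parameters
#' and seeds that produced them. Intended as the single-entry driver for
#' end-to-end runs; every statistic in the summary is traceable to the
#' (stage, parameters, seed) triple logged beside it.
#'
#' @param config Named list or path to a `key = value` file. Recognized
#'   keys (with defaults): `seed` (1), `out_dir` (tempdir), `n_participants`
#'   (4), `n_trials` (1), `condition` ("fear"), `noise_sigma`,
#'   `scrambled_gain`, `stages` (subset of
#'   `c("simulate", "freq", "time", "behavior")`), `d_prime_true` (1.5),
#'   `behavior_trials` (48).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return A list with the stage reports and the summary list (invisibly
#'   written to `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- parse_config(config)
  defaults <- list(seed = 1, out_dir = file.path(tempdir(), "fpas_run"),
                   n_participants = 4, n_trials = 1, condition = "fear",
                   noise_sigma = 10, scrambled_gain = 0.5,
                   stages = c("simulate", "freq", "time", "behavior"),
                   d_prime_true = 1.5, behavior_trials = 48)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- simulation_spec(noise_sigma = cfg$noise_sigma,
                          scrambled_gain = cfg$scrambled_gain,
                          n_participants = cfg$n_participants,
                          seed = cfg$seed)
  summary <- list(parameters = cfg[setdiff(names(cfg), "stages")],
                  stages = list())
  out <- list()

  if ("simulate" %in% cfg$stages) {
    say("simulate: ", cfg$n_participants, " participants x ",
        cfg$n_trials, " trial(s) per type")
    man <- simulate_dataset(spec, cfg$out_dir, conditions = cfg$condition,
                            n_trials_per_condition = cfg$n_trials)
    out$manifest <- man
    summary$stages$simulate <- list(seed = cfg$seed, n_recordings = nrow(man))
  }
  if ("freq" %in% cfg$stages) {
    if (is.null(out$manifest)) stop("stage 'freq' needs stage 'simulate' first")
    say("freq: frequency-domain analysis")
    fr <- analyze_frequency(out$manifest, dir = cfg$out_dir,
                            condition = cfg$condition)
    out$freq <- fr
    summary$stages$freq <- list(
      seed = cfg$seed, n_harmonics = length(fr$harmonic_bins),
      n_sig_channels = length(fr$sig_channels),
      group_t = if (!is.null(fr$group)) fr$group$t,
      group_p = if (!is.null(fr$group)) fr$group$p)
  }
  if ("time" %in% cfg$stages) {
    if (is.null(out$manifest)) stop("stage 'time' needs stage 'simulate' first")
    say("time: time-domain analysis")
    td <- analyze_timedomain(out$manifest, dir = cfg$out_dir,
                             condition = cfg$condition)
    out$time <- td
    summary$stages$time <- list(seed = cfg$seed,
                                n_windows = nrow(td$windows))
  }
  if ("behavior" %in% cfg$stages) {
    say("behavior: d-prime scoring")
    tabs <- lapply(seq_len(cfg$n_participants), function(p)
      simulate_behavior(cfg$d_prime_true, cfg$behavior_trials,
                        seed = cfg$seed * 131 + p, participant = p))
    scored <- score_detection(do.call(rbind, tabs))
    gt <- group_test(scored$dprime)
    out$behavior <- list(scored = scored, group = gt)
    summary$stages$behavior <- list(
      seed = cfg$seed, d_prime_true = cfg$d_prime_true,
      mean_dprime = mean(scored$dprime), t = gt$t, p = gt$p)
  }
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out$summary <- summary
  invisible(out)
}
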