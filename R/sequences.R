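#' Specification of an FPAS stimulation sequence
#'
#' Encodes the design constants of the paradigm: 350 ms stimuli separated by
#' 50 ms of silence give a base presentation rate of 1/(0.350+0.050) =
#' 2.5 Hz; the target category occupies every third slot, so the target rate
#' is base/3 = 0.833 Hz; 144 slots give a 57.6 s sequence with 2 s fade-in
#' and fade-out; 6 attention probes (stimuli attenuated in RMS by a factor
#' of 10) are embedded outside the fades.
#'
#' @param target_category Emotion category presented at every third slot.
#' @param stim_dur Stimulus duration in seconds (default 0.350).
#' @param isi Inter-stimulus silence in seconds (default 0.050).
#' @param n_slots Number of stimulus slots (default 144; must be divisible
#'   by 3).
#' @param fade Fade-in/fade-out duration in seconds (default 2).
#' @param n_attention Number of attention probes (default 6).
#' @param attention_rms_factor RMS attenuation factor for probes (default 10).
#' @param attention_on_targets Allow probes to land on target slots
#'   (default `FALSE`, so probes never perturb the tagged response).
#' @param seed Integer seed driving slot-order randomization.
#' @return An object of class `sequence_spec` with derived fields
#'   `base_rate` (Hz), `target_rate` (Hz) and `duration` (s).
#' @export
sequence_spec <- function(target_category = "fear", stim_dur = 0.350,
                          isi = 0.050, n_slots = 144, fade = 2,
                          n_attention = 6, attention_rms_factor = 10,
                          attention_on_targets = FALSE, seed = 1) {
  target_category <- match.arg(target_category, emotion_categories())
  if (n_slots %% 3 != 0) stop("n_slots must be divisible by 3")
  stopifnot(stim_dur > 0, isi >= 0, fade >= 0, n_attention >= 0)
  slot_dur <- stim_dur + isi
  structure(
    list(target_category = target_category, stim_dur = stim_dur, isi = isi,
         n_slots = n_slots, fade = fade, n_attention = n_attention,
         attention_rms_factor = attention_rms_factor,
         attention_on_targets = attention_on_targets, seed = seed,
         slot_dur = slot_dur,
         base_rate = 1 / slot_dur,
         target_rate = 1 / slot_dur / 3,
         duration = n_slots * slot_dur),
    class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf(
    "<sequence_spec> target=%s  base %.3g Hz, target %.4g Hz, %d slots, %.1f s\n",
    x$target_category, x$base_rate, x$target_rate, x$n_slots, x$duration))
  invisible(x)
}

#' Build an FPAS sequence slot table
#'
#' Places one exemplar of the target category at every third slot and fills
#' the remaining slots with non-target exemplars in seeded random order.
#' Every selected unique sound is used exactly twice, and within both the
#' target and the non-target streams all unique sounds occur once before
#' any sound repeats. Non-target slots draw an equal number of unique items
#' from each non-target category. Attention probes are assigned to random
#' slots outside the fade regions (and, by default, off target slots).
#'
#' @param stimuli A stimulus set (named list of [waveform]s with `category`
#'   fields), e.g. from [make_stimulus_set()].
#' @param spec A [sequence_spec()].
#' @return An object of class `stimulus_sequence`: a list with the slot
#'   `data.frame` (`position`, `stimulus_id`, `category`, `onset_s`,
#'   `is_target`, `is_attention`) and the spec.
#' @export
build_sequence <- function(stimuli, spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  cats <- vapply(stimuli, function(w) w$category, character(1))
  ids <- names(stimuli)
  n_target_slots <- spec$n_slots / 3
  n_nontarget_slots <- spec$n_slots - n_target_slots
  n_unique_targets <- n_target_slots / 2
  n_unique_nontargets <- n_nontarget_slots / 2
  target_ids <- ids[cats == spec$target_category]
  if (length(target_ids) < n_unique_targets)
    stop("need at least ", n_unique_targets, " unique '", spec$target_category,
         "' stimuli, got ", length(target_ids))
  other_cats <- setdiff(unique(cats), spec$target_category)
  per_cat <- n_unique_nontargets / length(other_cats)
  if (per_cat != round(per_cat))
    stop("non-target slot count not divisible across ", length(other_cats),
         " non-target categories")
  short <- other_cats[vapply(other_cats, function(cc) sum(cats == cc), 0) < per_cat]
  if (length(short))
    stop("need at least ", per_cat, " unique stimuli per non-target category; ",
         "short: ", paste(short, collapse = ", "))

  with_seed(spec$seed, {
    tsel <- sample(target_ids, n_unique_targets)
    # all unique targets once, then all again in a fresh order
    torder <- c(sample(tsel), sample(tsel))
    ntsel <- unlist(lapply(other_cats, function(cc)
      sample(ids[cats == cc], per_cat)))
    ntorder <- c(sample(ntsel), sample(ntsel))

    position <- seq_len(spec$n_slots)
    is_target <- position %% 3 == 0
    stimulus_id <- character(spec$n_slots)
    stimulus_id[is_target] <- torder
    stimulus_id[!is_target] <- ntorder
    onset_s <- (position - 1) * spec$slot_dur

    eligible <- onset_s >= spec$fade &
      (onset_s + spec$slot_dur) <= (spec$duration - spec$fade)
    if (!spec$attention_on_targets) eligible <- eligible & !is_target
    if (sum(eligible) < spec$n_attention)
      stop("not enough eligible slots for ", spec$n_attention, " attention probes")
    is_attention <- logical(spec$n_slots)
    is_attention[sample(which(eligible), spec$n_attention)] <- TRUE

    slots <- data.frame(position = position, stimulus_id = stimulus_id,
                        category = cats[stimulus_id], onset_s = onset_s,
                        is_target = is_target, is_attention = is_attention,
                        row.names = NULL, stringsAsFactors = FALSE)
    structure(list(slots = slots, spec = spec), class = "stimulus_sequence")
  })
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> %d slots, target=%s, %.1f s\n",
              nrow(x$slots), x$spec$target_category, x$spec$duration))
  invisible(x)
}

#' Render a sequence's audio
#'
#' Concatenates the slotted stimuli with their inter-stimulus silences,
#' attenuates attention-probe slots by the spec's RMS factor, and applies
#' linear fade-in/fade-out gain ramps over the first and last `fade`
#' seconds. The same slot table can be rendered with the intact or the
#' scrambled stimulus set, giving identically ordered paired sequences.
#'
#' @param seq A `stimulus_sequence` from [build_sequence()].
#' @param stimuli Stimulus set supplying the audio (must contain every
#'   `stimulus_id` in the slot table, all at one sampling rate).
#' @return A [waveform] of duration `spec$duration`.
#' @export
render_audio <- function(seq, stimuli) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  need <- unique(seq$slots$stimulus_id)
  missing <- setdiff(need, names(stimuli))
  if (length(missing))
    stop("stimulus set is missing: ", paste(utils::head(missing, 5), collapse = ", "))
  rates <- unique(vapply(stimuli[need], function(w) w$rate, 0))
  if (length(rates) != 1L) stop("mixed sampling rates in stimulus set")
  rate <- rates
  n_total <- round(seq$spec$duration * rate)
  out <- numeric(n_total)
  for (i in seq_len(nrow(seq$slots))) {
    s <- seq$slots[i, ]
    x <- stimuli[[s$stimulus_id]]$samples
    if (s$is_attention) x <- x / seq$spec$attention_rms_factor
    start <- round(s$onset_s * rate)
    idx <- start + seq_along(x)
    idx <- idx[idx <= n_total]
    out[idx] <- out[idx] + x[seq_along(idx)]
  }
  n_fade <- round(seq$spec$fade * rate)
  if (n_fade > 0) {
    g <- seq(0, 1, length.out = n_fade)
    out[1:n_fade] <- out[1:n_fade] * g
    out[(n_total - n_fade + 1):n_total] <- out[(n_total - n_fade + 1):n_total] * rev(g)
  }
  waveform(out, rate,
           label = sprintf("seq_%s_seed%d", seq$spec$target_category, seq$spec$seed))
}

#' Write a sequence slot table as CSV
#'
#' @param seq A `stimulus_sequence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_slot_table <- function(seq, path) {
  utils::write.csv(seq$slots, path, row.names = FALSE)
  invisible(path)
}
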