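#' Multichannel EEG recording container
#'
#' @param data Channels x samples numeric matrix in microvolts.
#' @param rate Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param positions Channels x 2 matrix of 2-D scalp coordinates (may be
#'   `NULL` if unknown; channel interpolation then refuses to run).
#' @param events Data frame with columns `sample` (1-based index) and
#'   `code`; may be empty.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names,
                          positions = NULL,
                          events = data.frame(sample = integer(),
                                              code = character()),
                          meta = list()) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match rows of data")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == nrow(data), ncol(positions) == 2)
    rownames(positions) <- channel_names
  }
  rownames(data) <- channel_names
  structure(list(data = data, rate = rate,
                 channel_names = as.character(channel_names),
                 positions = positions, events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d event(s)\n",
              nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate, nrow(x$events)))
  invisible(x)
}

#' Standard 128+2 channel layout for synthetic recordings
#'
#' A deterministic 128-channel scalp layout in the style of a high-density
#' Biosemi cap (labels `A1`-`A32` ... `D1`-`D32`) plus two mastoid channels
#' `M1`/`M2`. Scalp positions are laid out on the unit disk with a sunflower
#' (golden-angle) pattern, giving smooth, distinct 2-D coordinates suitable
#' for nearest-neighbour interpolation; mastoids sit outside the disk.
#'
#' @return A list with `names` (130 labels), `positions` (130 x 2 matrix)
#'   and `scalp` (logical, `TRUE` for the 128 scalp channels).
#' @export
biosemi128_layout <- function() {
  n <- 128
  labels <- paste0(rep(c("A", "B", "C", "D"), each = 32), rep(1:32, 4))
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n)
  th <- i * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  names_all <- c(labels, "M1", "M2")
  pos <- rbind(pos, c(-1.15, -0.35), c(1.15, -0.35))
  rownames(pos) <- names_all
  list(names = names_all, positions = pos,
       scalp = c(rep(TRUE, n), FALSE, FALSE))
}

#' Scalp (non-mastoid) channel names of a recording
#' @param rec An [eeg_recording()].
#' @param mastoids Mastoid channel names (default `c("M1", "M2")`).
#' @return Character vector of scalp channel names.
#' @export
scalp_channels <- function(rec, mastoids = c("M1", "M2")) {
  setdiff(rec$channel_names, mastoids)
}
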