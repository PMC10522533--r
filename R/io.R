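#' Write an EEG recording as raw binary + JSON sidecar
#'
#' The package's internal array container: samples as little-endian
#' float64 (channel index varying fastest) in `<path>`, and rate, channel
#' names, positions, events and metadata in `<path>.json`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path (conventionally `.feeg`).
#' @return `path`, invisibly.
#' @export
write_eeg_raw <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  side <- list(
    n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    rate = rec$rate, channel_names = rec$channel_names,
    positions = if (!is.null(rec$positions)) unname(as.matrix(rec$positions)),
    events = rec$events, meta = rec$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raw + sidecar EEG recording
#'
#' @param path Path written by [write_eeg_raw()].
#' @return An [eeg_recording()].
#' @export
read_eeg_raw <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  n <- side$n_channels * side$n_samples
  con <- file(path, "rb")
  x <- readBin(con, "double", n, size = 8, endian = "little")
  close(con)
  if (length(x) != n)
    stop("malformed raw file ", path, ": expected ", n, " doubles, got ",
         length(x), " (offset ", length(x) * 8, ")")
  data <- matrix(x, side$n_channels, side$n_samples)
  events <- if (is.data.frame(side$events) && nrow(side$events))
    side$events else data.frame(sample = integer(), code = character())
  pos <- side$positions
  if (!is.null(pos)) pos <- matrix(unlist(pos), ncol = 2, byrow = FALSE)
  eeg_recording(data, side$rate, side$channel_names, pos, events,
                as.list(side$meta))
}

# Fixed-width ASCII field helper for EDF headers.
edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write an EEG recording as a minimal EDF file
#'
#' 16-bit EDF with a single data record spanning the whole recording.
#' Events are encoded in the recording-identification header field
#' (`EV <sample> <code>; ...`); channel positions are not representable in
#' EDF and are dropped (a recording read back from EDF therefore refuses
#' channel interpolation until positions are supplied).
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  phys_max <- max(1e-6, max(abs(rec$data)))
  pmax_s <- signif(phys_max * 1.0001, 6)
  ev <- if (nrow(rec$events))
    paste(sprintf("EV %d %s", rec$events$sample, rec$events$code),
          collapse = ";") else "none"
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_field(x, width), con, eos = NULL)
  wr("0", 8)
  wr("synthetic", 80)
  wr(ev, 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(1, 8)                                  # one data record
  wr(format(n_samp / rec$rate, digits = 10), 8)
  wr(ns, 4)
  for (nm in rec$channel_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pmax_s, digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_s, digits = 6), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(n_samp, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- 32767 / pmax_s
  for (i in seq_len(ns))
    writeBin(as.integer(round(rec$data[i, ] * scale)), con, size = 2,
             endian = "little")
  invisible(path)
}

#' Read a minimal EDF file
#'
#' Reads 16-bit EDF written by [write_edf()] (and any single- or
#' multi-record EDF with uniform sampling). Physical scaling is applied;
#' events are recovered from the recording-identification field when
#' present. Positions are absent by construction.
#'
#' @param path Path to an `.edf` file.
#' @return An [eeg_recording()] without positions.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (nchar(s, type = "bytes") < width)
      stop("malformed EDF ", path, ": truncated header at offset ",
           seek(con, NA))
    trimws(s)
  }
  rd(8)                                     # version
  rd(80)                                    # patient id
  rec_id <- rd(80)
  rd(8); rd(8)                              # date, time
  as.numeric(rd(8))                         # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)             # transducer
  for (i in seq_len(ns)) rd(8)              # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)             # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  chunks <- vector("list", n_rec)           # uniform samples-per-record assumed
  for (r in seq_len(n_rec)) {
    rec_chunk <- matrix(NA_real_, ns, max(spr))
    for (i in seq_len(ns)) {
      raw16 <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                       endian = "little")
      if (length(raw16) != spr[i])
        stop("malformed EDF ", path, ": truncated data record ", r)
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      rec_chunk[i, seq_len(spr[i])] <- phys_min[i] + (raw16 - dig_min[i]) * gain
    }
    chunks[[r]] <- rec_chunk[, seq_len(spr[1]), drop = FALSE]
  }
  data <- do.call(cbind, chunks)
  rate <- spr[1] / rec_dur
  events <- data.frame(sample = integer(), code = character(),
                       stringsAsFactors = FALSE)
  if (grepl("^EV ", rec_id)) {
    parts <- strsplit(strsplit(rec_id, ";")[[1]], " +")
    events <- do.call(rbind, lapply(parts, function(p)
      data.frame(sample = as.integer(p[2]), code = p[3],
                 stringsAsFactors = FALSE)))
  }
  eeg_recording(data, rate, labels, positions = NULL, events = events)
}

#' Load an EEG recording, dispatching on file format
#'
#' `.edf` files go through [read_edf()]; anything else is treated as the
#' internal raw + sidecar container ([read_eeg_raw()]).
#'
#' @param path Path to a recording.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else read_eeg_raw(path)
}

#' Read and validate a dataset manifest
#'
#' @param path Path to a `manifest.csv` (columns `file`, `participant`,
#'   `condition`, `type`, `trial`, `seed`).
#' @param check_files Verify the listed files exist next to the manifest
#'   (default `TRUE`).
#' @return The manifest `data.frame` with an attribute `dir`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "participant", "condition", "type", "trial")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  key <- do.call(paste, man[c("participant", "condition", "type", "trial")])
  if (anyDuplicated(key))
    stop("duplicate (participant, condition, type, trial) rows in manifest")
  dir <- dirname(path)
  if (check_files) {
    absent <- !file.exists(file.path(dir, man$file))
    if (any(absent))
      stop("manifest lists missing file(s): ",
           paste(utils::head(man$file[absent], 5), collapse = ", "))
  }
  attr(man, "dir") <- dir
  man
}
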