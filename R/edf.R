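# Minimal EDF (European Data Format) writer/reader for EEG/EMG traces.
# Implements the 16-bit integer EDF layout: a 256-byte fixed header, 256
# bytes per signal, then data records of little-endian int16 samples scaled
# between the per-signal physical and digital ranges. Sufficient for
# round-tripping continuous polysomnography channels; EDF+ annotations are
# not supported.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write traces to an EDF file
#'
#' @param path output file.
#' @param channels named list of numeric traces (e.g. `eeg_R`, `eeg_L`,
#'   `emg_1`, `emg_2`).
#' @param fs sampling rate in Hz, one value or one per channel. Record
#'   duration is 1 s, so each rate must be a whole number of samples per
#'   second and all traces must span the same whole number of seconds.
#' @param units physical dimension label per channel (default "V").
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, channels, fs, units = "V") {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  ns <- length(channels)
  fs <- rep_len(fs, ns); units <- rep_len(units, ns)
  secs <- unique(vapply(seq_len(ns), function(i)
    length(channels[[i]]) / fs[i], numeric(1)))
  if (length(secs) != 1 || secs %% 1 != 0)
    abort("all channels must span the same whole number of seconds")
  n_rec <- as.integer(secs)
  pmin_ <- vapply(channels, function(x) min(x, -1e-9), numeric(1))
  pmax_ <- vapply(channels, function(x) max(x, 1e-9), numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("synthetic", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    pad = c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32),
    val = list(names(channels), rep("", ns), units,
               formatC(pmin_, format = "g", digits = 7),
               formatC(pmax_, format = "g", digits = 7),
               rep("-32768", ns), rep("32767", ns), rep("", ns),
               as.character(as.integer(fs)), rep("", ns))
  )
  for (k in seq_along(fields$pad))
    writeChar(paste0(vapply(fields$val[[k]], pad_field, "",
                            width = fields$pad[k]), collapse = ""),
              con, eos = NULL)
  dig <- purrr::map(seq_len(ns), function(i) {
    x <- channels[[i]]
    as.integer(round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs[i] + 1):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads continuous 16-bit EDF signals written by [write_edf()] or another
#' standard EDF source.
#'
#' @param path EDF file path.
#' @return a named list of channels, each a list with `trace` (numeric,
#'   physical units), `fs` (Hz) and `units`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  get_fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- get_fields(16); get_fields(80)
  units <- get_fields(8)
  pmin_ <- as.numeric(get_fields(8)); pmax_ <- as.numeric(get_fields(8))
  dmin <- as.numeric(get_fields(8)); dmax <- as.numeric(get_fields(8))
  get_fields(80)
  spr <- as.integer(get_fields(8))  # samples per record
  get_fields(32)
  raw <- purrr::map(seq_len(ns), function(i) integer(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]] <- c(raw[[i]], readBin(con, "integer", n = spr[i], size = 2,
                                      signed = TRUE, endian = "little"))
    }
  }
  out <- purrr::map(seq_len(ns), function(i) {
    phys <- pmin_[i] + (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i])
    list(trace = phys, fs = spr[i] / rec_dur, units = units[i])
  })
  setNames(out, labels)
}

#' Write a synthetic session to disk
#'
#' EEG and EMG channels as EDF, photometry as CSV (`time_s`, `signal`,
#' `reference`), ground truth as JSON, and the configuration as a plain
#' key-value text file.
#'
#' @param session a `synth_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synth_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- session$recording
  # store in microvolts: the 8-char EDF physical-range fields keep ~6
  # significant figures, which volt-scale values would waste on the exponent
  write_edf(file.path(dir, "eeg_emg.edf"),
            channels = list(eeg_R = rec$eeg$eeg_R * 1e6,
                            eeg_L = rec$eeg$eeg_L * 1e6,
                            emg_1 = rec$emg$emg_1 * 1e6,
                            emg_2 = rec$emg$emg_2 * 1e6),
            fs = c(rec$rates$eeg, rec$rates$eeg, rec$rates$emg, rec$rates$emg),
            units = "uV")
  utils::write.csv(
    data.frame(time_s = rec$photo$t, signal = rec$photo$signal,
               reference = rec$photo$reference),
    file.path(dir, "photometry.csv"), row.names = FALSE)
  truth <- session$truth
  jsonlite::write_json(
    list(hypnogram = as.character(truth$hypnogram$state),
         spindle_intervals = truth$spindle_intervals[c("start", "end")],
         movement_intervals = truth$movement_intervals,
         stim_pulses = truth$stim_pulses,
         latent_response_latency = truth$latent_response_latency),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- session$config
  scal <- vapply(cfg, function(v) paste(format(v), collapse = ","), "")
  writeLines(paste0(names(cfg), " = ", scal), file.path(dir, "config.txt"))
  invisible(dir)
}
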