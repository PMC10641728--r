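#' Write a recording to an EDF file
#'
#' Plain EDF (European Data Format): 256-byte ASCII header, one
#' 256-byte signal header per channel, then 1-second data records of
#' little-endian 16-bit integers. The physical range is set from the data
#' minimum and maximum with 5% headroom, so the quantization step is about
#' `range / 65535` uV. A trailing partial second is dropped with a
#' warning.
#'
#' @param recording An [eeg_recording()] with finite samples.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edf <- function(recording, path) {
  assert_that(n_samples(recording) > 0, "cannot write a zero-length recording")
  assert_that(all(is.finite(recording$samples)),
              "recording contains non-finite samples; EDF requires finite values")
  fs <- recording$fs
  assert_that(abs(fs - round(fs)) < 1e-9, "EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(recording$samples)
  n_rec <- floor(n_samples(recording) / fs)
  assert_that(n_rec >= 1, "recording shorter than one 1-second EDF record")
  if (n_rec * fs < n_samples(recording)) {
    warning(sprintf("dropping trailing partial second (%d samples)",
                    n_samples(recording) - n_rec * fs))
  }
  x <- recording$samples[, seq_len(n_rec * fs), drop = FALSE]

  rng <- range(x)
  span <- diff(rng)
  if (span == 0) span <- 1
  pmin_ <- rng[1] - 0.05 * span
  pmax_ <- rng[2] + 0.05 * span
  dmin <- -32768L; dmax <- 32767L

  pad <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    formatC(s, width = width, flag = "-")
  }
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(
    pad("0", 8),
    pad(if (is.na(recording$subject_id)) "X" else recording$subject_id, 80),
    pad("Startdate 01-JAN-2000", 80),
    pad("01.01.00", 8),
    pad("00.00.00", 8),
    pad(256 * (1 + ns), 8),
    pad("", 44),
    pad(n_rec, 8),
    pad("1", 8),
    pad(ns, 4)
  ), con, eos = NULL)
  fmt_num <- function(v) pad(formatC(v, format = "g", digits = 7), 8)
  writeChar(paste0(
    paste(vapply(recording$channel_labels, pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(fmt_num(pmin_), ns), collapse = ""),
    paste(rep(fmt_num(pmax_), ns), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("BP:0.5-40Hz", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[ch, idx] - pmin_) * scale + dmin))
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Parses the EDF header and data records and rescales the 16-bit digital
#' values to physical units. When signals carry different sampling rates,
#' all channels are linearly resampled to the highest rate with a warning.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), sprintf("EDF file not found: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) {
    out <- readChar(con, width, useBytes = TRUE)
    assert_that(nchar(out, type = "bytes") == width,
                sprintf("corrupt EDF header in %s", path))
    trimws(out)
  }
  rd(8)                         # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)          # recording id, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  assert_that(!is.na(ns) && ns >= 1 && !is.na(n_rec) && n_rec >= 1 &&
                !is.na(rec_dur) && rec_dur > 0,
              sprintf("corrupt EDF header in %s", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  assert_that(isTRUE(header_bytes == 256 * (1 + ns)),
              sprintf("corrupt EDF header in %s (header size mismatch)", path))
  # drop EDF+ annotation channels if present
  keep <- !grepl("Annotations", labels)
  raw <- purrr::map(seq_len(ns), ~vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little",
                      signed = TRUE)
      assert_that(length(vals) == spr[ch],
                  sprintf("truncated EDF data in %s", path))
      raw[[ch]][[r]] <- vals
    }
  }
  signals <- purrr::map(seq_len(ns), function(ch) {
    dig <- unlist(raw[[ch]])
    pmin_[ch] + (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
  })
  signals <- signals[keep]; labels <- labels[keep]; spr_k <- spr[keep]
  fs_all <- spr_k / rec_dur
  fs <- max(fs_all)
  if (length(unique(fs_all)) > 1) {
    warning("signals carry mixed sampling rates; resampling all channels to the highest rate")
    n_target <- round(n_rec * rec_dur * fs)
    signals <- purrr::map(seq_along(signals), function(ch) {
      if (fs_all[ch] == fs) return(signals[[ch]])
      t_src <- (seq_along(signals[[ch]]) - 1) / fs_all[ch]
      t_dst <- (seq_len(n_target) - 1) / fs
      stats::approx(t_src, signals[[ch]], xout = t_dst, rule = 2)$y
    })
  }
  eeg_recording(do.call(rbind, signals), fs = fs, channel_labels = labels,
                subject_id = if (nzchar(patient)) patient else NA_character_)
}
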