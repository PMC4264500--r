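#' Write a recording to an EDF file
#'
#' Writes the European Data Format (16-bit little-endian integers with a
#' plain-ASCII header).  Signals are quantized to the physical range
#' (default +/-200 microvolts); one data record per second.  EDF requires
#' an integer number of records, so a trailing partial record is
#' zero-padded and the true sample count is noted in the reserved header
#' field (`NSAMP=`), which [read_edf()] honours.  Events are *not* written
#' as EDF+ annotations; use [write_events()] for the companion CSV.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @param physical_range symmetric physical range in microvolts; samples
#'   outside it are clipped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  sig <- recording$signal
  ns <- ncol(sig)
  nchan <- nrow(sig)
  fs <- recording$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  spr <- as.integer(fs)                     # samples per 1-s record
  n_rec <- ceiling(ns / spr)
  pad <- n_rec * spr - ns
  if (pad > 0) sig <- cbind(sig, matrix(0, nchan, pad))

  pmin_ <- -physical_range; pmax_ <- physical_range
  dmin <- -32768L; dmax <- 32767L
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((pmin(pmax(sig, pmin_), pmax_) - pmin_) * scale) + dmin
  storage.mode(dig) <- "integer"

  pad_str <- function(x, n) {
    x <- substr(as.character(x), 1, n)
    formatC(x, width = -n, flag = " ")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8),                         # version
    pad_str("X X X X", 80),                  # patient id (anonymous)
    pad_str("Startdate X X X X", 80),        # recording id
    pad_str("01.01.00", 8), pad_str("00.00.00", 8),
    pad_str(256 + nchan * 256, 8),           # header bytes
    pad_str(sprintf("NSAMP=%d", ns), 44),    # reserved: true sample count
    pad_str(n_rec, 8), pad_str("1", 8),      # n records, record duration s
    pad_str(nchan, 4))
  filt <- sprintf("HP:%sHz LP:%sHz N:%sHz",
                  recording$meta$highpass, recording$meta$lowpass,
                  recording$meta$notch)
  hdr <- paste0(hdr,
    paste(vapply(recording$labels, pad_str, "", n = 16), collapse = ""),
    paste(rep(pad_str("AgAgCl electrode", 80), nchan), collapse = ""),
    paste(rep(pad_str("uV", 8), nchan), collapse = ""),
    paste(rep(pad_str(pmin_, 8), nchan), collapse = ""),
    paste(rep(pad_str(pmax_, 8), nchan), collapse = ""),
    paste(rep(pad_str(dmin, 8), nchan), collapse = ""),
    paste(rep(pad_str(dmax, 8), nchan), collapse = ""),
    paste(rep(pad_str(filt, 80), nchan), collapse = ""),
    paste(rep(pad_str(spr, 8), nchan), collapse = ""),
    paste(rep(pad_str("", 32), nchan), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Minimal EDF/EDF+ reader for equal-rate signals: all channels must share
#' one sampling rate.  Physical values are reconstructed from the
#' digital/physical calibration in the header.
#'
#' @param path an EDF file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  if (is.na(nchan) || nchan < 1) stopf("not an EDF file: %s", path)
  fld <- function(w) vapply(seq_len(nchan), function(i) rd(w), "")
  labels <- fld(16); fld(80); units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  filt <- fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (anyDuplicated(labels)) stopf("duplicate channel labels in %s", path)
  if (length(unique(spr)) != 1)
    stopf("channels disagree on samples per record; mixed-rate EDF unsupported")
  if (any(is.na(spr)) || rec_dur <= 0) stopf("missing sampling rate in %s", path)
  fs <- spr[1] / rec_dur
  raw_ <- readBin(con, "integer", n = n_rec * nchan * spr[1], size = 2,
                  signed = TRUE, endian = "little")
  if (length(raw_) < n_rec * nchan * spr[1])
    stopf("truncated EDF data in %s", path)
  sig <- matrix(NA_real_, nchan, n_rec * spr[1])
  dim(raw_) <- c(spr[1], nchan, n_rec)
  for (c in seq_len(nchan))
    sig[c, ] <- as.numeric(raw_[, c, ])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- sweep(sweep(sig, 1, dmin), 1, gain, `*`) + pmin_
  ns_true <- sub(".*NSAMP=([0-9]+).*", "\\1", reserved)
  if (grepl("NSAMP=", reserved, fixed = TRUE)) {
    ns_true <- as.integer(ns_true)
    if (ns_true <= ncol(sig)) sig <- sig[, seq_len(ns_true), drop = FALSE]
  }
  hp <- lp <- nt <- NA_real_
  m <- regmatches(filt[1], regexec("HP:([0-9.]+)Hz LP:([0-9.]+)Hz N:([0-9.]+)Hz",
                                   filt[1]))[[1]]
  if (length(m) == 4) { hp <- as.numeric(m[2]); lp <- as.numeric(m[3]); nt <- as.numeric(m[4]) }
  eeg_recording(sig, fs = fs, labels = labels,
                highpass = hp, lowpass = lp, notch = nt)
}

#' Write / read the cue event table
#'
#' Plain CSV with columns `onset_sample` (0-based), `onset_s`, `label`,
#' `run`.
#'
#' @param events an [event_list()].
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   an [event_list()].
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param fs sampling rate used to recompute `onset_s` (the stored column
#'   is cross-checked).
#' @export
read_events <- function(path, fs) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev <- event_list(df$onset_sample, fs = fs, label = df$label, run = df$run)
  if (max(abs(ev$onset_s - df$onset_s)) > 1 / fs)
    stopf("onset_s column inconsistent with fs = %g", fs)
  ev
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth a `ground_truth` object from [generate_session()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(gt$artifacts) && nrow(gt$artifacts) == 0)
    gt$artifacts <- empty_artifact_annotations()
  structure(gt, class = "ground_truth")
}
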