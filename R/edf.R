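# Minimal European Data Format (EDF) reader/writer.
# Layout: 256-byte ASCII main header, 256 bytes of ASCII header per signal,
# then data records of 16-bit little-endian integers (one block per signal
# per record), linearly mapped between the digital and physical ranges.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a multichannel signal matrix as an EDF file
#'
#' Each channel is scaled to the full 16-bit digital range against its own
#' physical extremes, so the round-trip error is bounded by one quantization
#' step of the per-channel range. Data are written as 1-second records when
#' the sample count is a multiple of `fs`, otherwise as a single record.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling frequency in Hz.
#' @param channel_labels character vector, one unique label per channel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, fs, channel_labels, path) {
  stopifnot(is.matrix(signal), fs > 0,
            length(channel_labels) == nrow(signal),
            !anyDuplicated(channel_labels))
  nc <- nrow(signal); ns <- ncol(signal)
  if (ns %% fs == 0) {
    spr <- as.integer(fs); nrec <- ns %/% fs; dur <- 1
  } else {
    spr <- ns; nrec <- 1L; dur <- ns / fs
  }
  pmin <- apply(signal, 1, min); pmax <- apply(signal, 1, max)
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1  # avoid zero physical span
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (nc + 1), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_num(dur, 8), edf_pad(nc, 4),
    paste(vapply(channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad("uV", 8), nc), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), nc), collapse = ""),
    paste(rep(edf_pad(dmax, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad(spr, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 32), nc), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nc)) {
      dig <- round((signal[ch, idx] - pmin[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    if (length(raw) < w) stop("truncated EDF header")
    trimws(rawToChar(raw))
  }
  h <- list(version = rd(8), patient = rd(80), recording = rd(80),
            startdate = rd(8), starttime = rd(8),
            header_bytes = as.integer(rd(8)), reserved = rd(44),
            n_records = as.integer(rd(8)),
            record_duration = as.numeric(rd(8)), n_signals = as.integer(rd(4)))
  if (is.na(h$n_signals) || h$n_signals < 1) stop("malformed EDF header")
  ns <- h$n_signals
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  h$labels <- fld(16); fld(80)
  h$dim <- fld(8)
  h$pmin <- as.numeric(fld(8)); h$pmax <- as.numeric(fld(8))
  h$dmin <- as.numeric(fld(8)); h$dmax <- as.numeric(fld(8))
  fld(80)
  h$spr <- as.integer(fld(8)); fld(32)
  h
}

#' Read an EDF recording
#'
#' Parses the fixed-layout EDF headers and data records into an
#' [eeg_record]. Seizure intervals are populated from a sidecar annotation
#' CSV (`start_s,end_s,label` in seconds) when one is supplied or found next
#' to the file (same path with a `.csv` extension); otherwise they are empty.
#' A sampling frequency other than 256 Hz triggers a warning, not an error.
#'
#' @param path EDF file path.
#' @param annotations optional path to the annotation CSV. `NULL` (default)
#'   looks for the sibling file; `NA` skips annotations entirely.
#' @return an [eeg_record].
#' @export
read_edf <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (anyDuplicated(h$labels))
    h$labels <- make.unique(h$labels)
  ns <- h$n_signals
  if (length(unique(h$spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  spr <- h$spr[1]
  fs <- spr / h$record_duration
  if (!isTRUE(all.equal(fs, 256)))
    warning("sampling frequency is ", fs, " Hz, expected 256 Hz")
  nrec <- h$n_records
  dat <- readBin(con, "integer", n = nrec * ns * spr, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(dat) < nrec * ns * spr) stop("truncated EDF data section")
  # records x (signal-major blocks) -> channels x samples
  arr <- array(dat, dim = c(spr, ns, nrec))
  sig <- matrix(0, nrow = ns, ncol = spr * nrec)
  gain <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  for (ch in seq_len(ns)) {
    sig[ch, ] <- (as.vector(arr[, ch, ]) - h$dmin[ch]) * gain[ch] + h$pmin[ch]
  }
  iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (!isTRUE(is.na(annotations))) {
    ann_path <- if (is.null(annotations))
      sub("\\.edf$", ".csv", path, ignore.case = TRUE) else annotations
    if (!is.null(ann_path) && file.exists(ann_path) && ann_path != path) {
      a <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
      if (all(c("start_s", "end_s") %in% names(a)))
        iv <- a[, c("start_s", "end_s"), drop = FALSE]
    }
  }
  eeg_record(sig, fs = fs, channel_labels = h$labels, seizure_intervals = iv)
}
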