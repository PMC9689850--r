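#' Multichannel EEG recording container
#'
#' Bundles a channels x samples signal matrix (microvolts) with its sampling
#' rate, channel labels and annotated seizure intervals. Intervals are
#' half-open `[start_s, end_s)` in 0-based seconds and must lie inside the
#' recording.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling frequency in Hz (> 0; scalp EEG corpora typically 256).
#' @param channel_labels unique channel labels, one per row of `signal`.
#' @param seizure_intervals data.frame with columns `start_s`, `end_s`
#'   (seconds), possibly empty.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, channel_labels,
                       seizure_intervals = data.frame(start_s = numeric(0),
                                                      end_s = numeric(0))) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (length(channel_labels) != nrow(signal))
    stop("one channel label per signal row required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  dur <- ncol(signal) / fs
  iv <- as.data.frame(seizure_intervals)
  if (nrow(iv) > 0) {
    stopifnot(all(c("start_s", "end_s") %in% names(iv)))
    if (any(iv$start_s < 0) || any(iv$end_s > dur) ||
        any(iv$end_s <= iv$start_s))
      stop("seizure intervals must be nonempty and lie within [0, duration)")
  }
  structure(list(signal = signal, fs = fs,
                 channel_labels = as.character(channel_labels),
                 seizure_intervals = iv),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels, %.1f s at %g Hz, %d seizure interval(s)\n",
              nrow(x$signal), ncol(x$signal) / x$fs, x$fs,
              nrow(x$seizure_intervals)))
  invisible(x)
}

#' One windowed EEG segment
#'
#' @param signal channels x samples matrix.
#' @param label `"seizure"` or `"seizure_free"`.
#' @param band band name (`"broadband"`, `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`).
#' @param start_s window start in seconds within the source recording.
#' @param fs sampling frequency in Hz.
#' @param segment_id optional identifier carried into feature tables.
#' @return an object of class `eeg_segment`.
#' @export
eeg_segment <- function(signal, label, band = "broadband", start_s = 0,
                        fs = 256, segment_id = NULL) {
  signal <- as.matrix(signal)
  label <- match.arg(label, c("seizure", "seizure_free"))
  band <- match.arg(band, c("broadband", names(eeg_bands())))
  structure(list(signal = signal, label = label, band = band,
                 start_s = start_s, fs = fs, segment_id = segment_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment [%s, %s]: %d x %d at %g Hz, start %g s\n",
              x$label, x$band, nrow(x$signal), ncol(x$signal), x$fs,
              x$start_s))
  invisible(x)
}

#' The four clinical EEG sub-bands
#'
#' Fixed frequency edges (Hz) of the delta, theta, alpha and beta bands used
#' for decomposition: delta (0, 4], theta (4, 8], alpha (8, 15],
#' beta (15, 30].
#'
#' @return named list of `c(low_hz, high_hz)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 15), beta = c(15, 30))
}

#' The 23-channel bipolar scalp montage
#'
#' Channel labels of the longitudinal bipolar montage commonly used with
#' pediatric scalp EEG corpora recorded at 256 Hz.
#'
#' @return character vector of 23 labels.
#' @export
standard_montage <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3",
    "P3-O1", "FZ-CZ", "CZ-PZ", "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2", "T8-O2", "P7-T7", "T7-FT9",
    "FT9-FT10", "FT10-T8")
}

#' Select and reorder channels of a recording
#'
#' @param record an [eeg_record].
#' @param wanted character vector of labels; the output channels follow this
#'   order, all other channels are dropped.
#' @return an [eeg_record] restricted to `wanted`.
#' @export
select_montage <- function(record, wanted) {
  stopifnot(inherits(record, "eeg_record"))
  idx <- match(wanted, record$channel_labels)
  if (anyNA(idx))
    stop("channel ", wanted[which(is.na(idx))[1]], " not found")
  eeg_record(record$signal[idx, , drop = FALSE], record$fs,
             record$channel_labels[idx], record$seizure_intervals)
}

#' Cut a recording into overlapping labeled windows
#'
#' Sliding windows of `window_s` seconds advance by
#' `stride = window_s - overlap_s` from time 0 while fully inside the
#' recording, so a duration-D recording yields
#' `floor((D - window_s)/stride) + 1` windows. A window is labeled
#' `"seizure"` only if it lies entirely inside one annotated interval;
#' windows that straddle an interval boundary are discarded, the rest are
#' `"seizure_free"`.
#'
#' @param record an [eeg_record].
#' @param window_s window length in seconds (default 20).
#' @param overlap_s overlap between consecutive windows in seconds
#'   (default 15; `0 <= overlap_s < window_s`).
#' @return list of broadband [eeg_segment] objects.
#' @export
segment_record <- function(record, window_s = 20, overlap_s = 15) {
  stopifnot(inherits(record, "eeg_record"))
  if (!(overlap_s >= 0 && overlap_s < window_s))
    stop("need 0 <= overlap_s < window_s")
  fs <- record$fs
  dur <- ncol(record$signal) / fs
  if (dur < window_s)
    stop("recording shorter (", dur, " s) than one window (", window_s, " s)")
  stride <- window_s - overlap_s
  starts <- seq(0, dur - window_s, by = stride)
  iv <- record$seizure_intervals
  out <- list()
  for (s0 in starts) {
    s1 <- s0 + window_s
    if (nrow(iv) > 0) {
      inside   <- any(iv$start_s <= s0 & s1 <= iv$end_s)
      touching <- any(iv$start_s < s1 & s0 < iv$end_s)
    } else inside <- touching <- FALSE
    if (touching && !inside) next  # mixed window: discard
    i0 <- round(s0 * fs) + 1L
    seg <- eeg_segment(record$signal[, i0:(i0 + round(window_s * fs) - 1L),
                                     drop = FALSE],
                       label = if (inside) "seizure" else "seizure_free",
                       band = "broadband", start_s = s0, fs = fs,
                       segment_id = sprintf("t%07.1f", s0))
    out[[length(out) + 1L]] <- seg
  }
  out
}

fir_band_taps <- function(band_name, fs, order = 512) {
  edges <- eeg_bands()[[band_name]]
  if (is.null(edges)) stop("unknown band: ", band_name)
  if (edges[2] >= fs / 2)
    stop("band edge ", edges[2], " Hz at or above Nyquist (", fs / 2, " Hz)")
  # Pad the design cutoffs by ~1/4 of the Hamming transition width so that,
  # after the forward-backward (squared-response) pass, adjacent bands cross
  # near half power and the four bands partition broadband power up to 30 Hz.
  pad <- 0.23 * 3.3 * fs / (order + 1)
  lo <- max(edges[1] - pad, 0)
  hi <- min(edges[2] + pad, fs / 2 * 0.999)
  if (edges[1] <= 0) {
    signal::fir1(order, hi / (fs / 2), type = "low")
  } else {
    signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  }
}

# Zero-phase FIR application to a channels x samples matrix.
# Forward-backward filtering with a symmetric FIR equals convolution with the
# autocorrelation of the taps, centered; done here via FFT with mirror
# padding to suppress edge transients, on all channels at once.
apply_zero_phase <- function(mat, taps) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  L <- length(taps)
  # g = taps * taps (self-convolution; taps are symmetric so this equals the
  # forward-backward response), computed by FFT with proper lag ordering
  ng <- 2L * L - 1L
  g <- Re(stats::fft(stats::fft(c(taps, rep(0, ng - L)))^2,
                     inverse = TRUE)) / ng
  half <- (length(g) - 1L) / 2L
  pad <- min(half, n - 1L)
  # even (mirror) padding at both ends
  left  <- mat[, pad:1, drop = FALSE]
  right <- mat[, n:(n - pad + 1L), drop = FALSE]
  xp <- cbind(left, mat, right)
  np <- ncol(xp)
  nfft <- stats::nextn(np + length(g) - 1L, 2)
  G <- stats::fft(c(g, rep(0, nfft - length(g))))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(mat), nfft - np))))
  Y <- Re(stats::mvfft(X * G, inverse = TRUE)) / nfft
  out <- t(Y)[, (half + pad + 1L):(half + pad + n), drop = FALSE]
  out
}

#' Decompose a broadband segment into one sub-band
#'
#' Applies a linear-phase windowed-sinc (Hamming) FIR filter of order 512
#' forward and backward, giving zero net phase so the SODP geometry of the
#' filtered trace is not skewed by group delay. The delta band is realized
#' as a 4 Hz low-pass; the other bands as band-passes at the edges of
#' [eeg_bands()].
#'
#' @param seg a broadband [eeg_segment].
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param order FIR order (default 512 at 256 Hz).
#' @return an [eeg_segment] of the same shape with `band` set.
#' @export
band_decompose <- function(seg, band, order = 512) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (seg$band != "broadband")
    stop("segment is already band-filtered (", seg$band, ")")
  band <- match.arg(band, names(eeg_bands()))
  taps <- fir_band_taps(band, seg$fs, order)
  out <- seg
  out$signal <- apply_zero_phase(seg$signal, taps)
  out$band <- band
  out
}

#' Reject segments with excessive peak amplitude
#'
#' A coarse stand-in for manual artifact screening: drops any segment whose
#' peak absolute amplitude exceeds `factor` times the median absolute
#' amplitude of the source recording. Off by default in the pipeline.
#'
#' @param segments list of [eeg_segment] objects.
#' @param median_abs median absolute amplitude of the parent recording.
#' @param factor rejection multiple (default 8).
#' @return the retained subset of `segments`.
#' @export
amplitude_reject <- function(segments, median_abs, factor = 8) {
  keep <- vapply(segments, function(s) max(abs(s$signal)) <= factor * median_abs,
                 logical(1))
  segments[keep]
}
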