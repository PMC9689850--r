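# Synthetic multichannel EEG with the statistical structure the analysis
# assumes: 1/f background with band-limited oscillations, and seizure
# segments carrying intermittent high-amplitude spike-wave trains.

#' Configuration of the synthetic EEG generator
#'
#' @param fs sampling frequency (Hz, default 256).
#' @param n_channels channels per segment (default 23).
#' @param n_seizure,n_free segment counts for [gen_dataset()]
#'   (defaults 100/100).
#' @param segment_s segment length in seconds (default 20).
#' @param background_rms nominal background RMS in microvolts (default 20).
#' @param amplitude_ratio mean seizure/background RMS ratio (default 4).
#' @param spike_rate spike-wave complexes per second during a burst
#'   (default 2.5; the clinical spike-wave range is roughly 1.5-4 Hz).
#' @param burst_duty fraction of seizure time occupied by bursts
#'   (default 0.6).
#' @param band_powers named relative powers of the band-limited background
#'   oscillations over the unit-power 1/f base.
#' @param amp_jitter_sd log-scale SD of the per-segment RMS jitter applied
#'   to both classes (default 0.5), emulating inter-segment amplitude
#'   variability of real recordings.
#' @param channel_mix mixing coefficient of the shared source into each
#'   channel (default 0.7).
#' @param interictal_rate mean rate (per second) of isolated interictal
#'   spike-wave discharges in seizure-free segments (default 0.4; drawn
#'   per segment from U(0, 2 x rate), 0 disables them). These keep the
#'   seizure-free class heterogeneous, as interictal EEG of epileptic
#'   patients is.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(fs = 256, n_channels = 23,
                         n_seizure = 100, n_free = 100,
                         segment_s = 20, background_rms = 20,
                         amplitude_ratio = 4, spike_rate = 2.5,
                         burst_duty = 0.6,
                         band_powers = c(delta = 0.4, theta = 0.2,
                                         alpha = 0.3, beta = 0.1),
                         amp_jitter_sd = 0.5, channel_mix = 0.7,
                         interictal_rate = 0.4) {
  stopifnot(fs > 0, n_channels >= 1, segment_s > 0,
            amplitude_ratio >= 1, spike_rate >= 0,
            burst_duty > 0, burst_duty <= 1,
            channel_mix >= 0, channel_mix <= 1)
  structure(list(fs = fs, n_channels = n_channels,
                 n_seizure = n_seizure, n_free = n_free,
                 segment_s = segment_s, background_rms = background_rms,
                 amplitude_ratio = amplitude_ratio, spike_rate = spike_rate,
                 burst_duty = burst_duty, band_powers = band_powers,
                 amp_jitter_sd = amp_jitter_sd, channel_mix = channel_mix,
                 interictal_rate = interictal_rate),
            class = "synth_config")
}

# amplitude spectrum (rfft bins) of the background: unit-power 1/f base
# plus band-limited plateaus with the configured relative powers
background_spectrum <- function(n, fs, band_powers) {
  nb <- n %/% 2 + 1L
  f <- (0:(nb - 1L)) * fs / n
  p1f <- 1 / pmax(f, 0.5)          # power ~ 1/f, floored below 0.5 Hz
  p1f[1] <- 0                       # no DC
  p1f <- p1f / sum(p1f)
  ptot <- p1f
  bands <- eeg_bands()
  for (b in names(band_powers)) {
    if (band_powers[[b]] <= 0) next
    e <- bands[[b]]
    inb <- f > e[1] & f <= e[2]
    pb <- as.numeric(inb)
    pb <- pb / sum(pb) * band_powers[[b]]
    ptot <- ptot + pb
  }
  sqrt(ptot)
}

# k independent shaped-noise traces of length n (rows = traces), unit RMS
shaped_noise <- function(k, n, amp_spec) {
  nb <- length(amp_spec)
  # hermitian spectrum via random phases
  re <- matrix(stats::rnorm(k * nb), nb, k) * amp_spec
  im <- matrix(stats::rnorm(k * nb), nb, k) * amp_spec
  im[1, ] <- 0
  if (n %% 2 == 0) im[nb, ] <- 0
  half <- complex(real = re, imaginary = im)
  dim(half) <- c(nb, k)
  full <- rbind(half,
                Conj(half[rev(seq(2, nb - ifelse(n %% 2 == 0, 1, 0))), ,
                          drop = FALSE]))
  x <- Re(stats::mvfft(full, inverse = TRUE))
  x <- t(x)
  sweep(x, 1, sqrt(rowMeans(x^2)), "/")
}

# channels x n correlated background at unit RMS per channel
background_matrix <- function(config, n) {
  amp <- background_spectrum(n, config$fs, config$band_powers)
  src <- shaped_noise(config$n_channels + 1L, n, amp)
  common <- src[1, ]
  priv <- src[-1, , drop = FALSE]
  m <- config$channel_mix
  x <- m * matrix(common, config$n_channels, n, byrow = TRUE) +
    sqrt(1 - m^2) * priv
  sweep(x, 1, sqrt(rowMeans(x^2)), "/")
}

# isolated interictal discharges for seizure-free segments: sparse
# spike-wave complexes at a per-segment Poisson rate
interictal_activity <- function(config, n) {
  out <- numeric(n)
  if (config$interictal_rate <= 0) return(out)
  fs <- config$fs
  rate <- stats::runif(1, 0, 2 * config$interictal_rate)
  k <- stats::rpois(1, rate * n / fs)
  if (k < 1) return(out)
  kernel <- spike_wave_kernel(fs)
  at <- sort(stats::runif(k, 0, n / fs - length(kernel) / fs))
  for (tt in at) {
    i0 <- floor(tt * fs) + 1L
    i1 <- min(n, i0 + length(kernel) - 1L)
    amp <- stats::runif(1, 2, 5)
    out[i0:i1] <- out[i0:i1] + amp * kernel[seq_len(i1 - i0 + 1L)]
  }
  out
}

# one spike-wave complex sampled at fs: sharp biphasic transient followed
# by a slow half-sine wave
spike_wave_kernel <- function(fs) {
  t_spike <- seq(0, 0.07, by = 1 / fs)          # ~70 ms transient
  s <- 0.012                                     # ~12 ms rise scale
  spike <- -(t_spike - 0.035) / s * exp(-((t_spike - 0.035)^2) / (2 * s^2))
  t_wave <- seq(0, 0.25, by = 1 / fs)            # ~250 ms slow wave
  wave <- 0.6 * sin(pi * t_wave / 0.25)
  k <- c(spike / max(abs(spike)), wave)
  k - mean(k)
}

# burst gate and common spike train of length n, unit-normalized later;
# the duty cycle is jittered per segment around the configured value
spike_train <- function(config, n) {
  fs <- config$fs
  gate <- logical(n)
  t <- 0
  mean_on <- 2
  duty <- min(0.95, config$burst_duty * stats::runif(1, 0.5, 1.3))
  mean_off <- mean_on * (1 - duty) / duty
  while (t < n / fs) {
    on <- stats::runif(1, 0.5 * mean_on, 1.5 * mean_on)
    i0 <- floor(t * fs) + 1L
    i1 <- min(n, floor((t + on) * fs))
    if (i0 <= n) gate[i0:i1] <- TRUE
    t <- t + on + stats::runif(1, 0.5 * mean_off, 1.5 * mean_off)
  }
  train <- numeric(n)
  if (config$spike_rate > 0 && any(gate)) {
    period <- 1 / config$spike_rate
    kernel <- spike_wave_kernel(fs)
    # waxing-waning envelope: mild slow modulation of burst amplitude
    env <- 0.75 + 0.25 * abs(sin(2 * pi * stats::runif(1) +
                                 2 * pi * 0.1 * seq_len(n) / fs))
    tt <- 0
    while (tt < n / fs) {
      i0 <- floor(tt * fs) + 1L
      if (i0 <= n && gate[i0]) {
        amp <- stats::runif(1, 0.8, 1.2) * env[i0]
        i1 <- min(n, i0 + length(kernel) - 1L)
        train[i0:i1] <- train[i0:i1] + amp * kernel[seq_len(i1 - i0 + 1L)]
      }
      tt <- tt + period * stats::runif(1, 0.9, 1.1)
    }
  }
  list(train = train, gate = gate)
}

#' Generate one seizure-free background segment
#'
#' 1/f-shaped noise plus band-limited oscillations at the configured
#' relative powers, with all channels sharing a common source (mixing
#' coefficient `channel_mix`). The segment RMS is the configured background
#' RMS times a per-segment log-normal jitter.
#'
#' @param config a [synth_config].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return a broadband [eeg_segment] labeled `"seizure_free"`.
#' @export
gen_background <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$segment_s * config$fs)
  x <- background_matrix(config, n)
  ii <- interictal_activity(config, n)
  if (any(ii != 0)) {
    gains <- stats::runif(config$n_channels, 0.7, 1)
    x <- x + outer(gains, ii)
    x <- sweep(x, 1, sqrt(rowMeans(x^2)), "/")
  }
  rms <- config$background_rms * stats::rlnorm(1, 0, config$amp_jitter_sd)
  eeg_segment(x * rms, label = "seizure_free", band = "broadband",
              fs = config$fs)
}

#' Generate one seizure segment
#'
#' Background activity plus intermittent spike-wave trains: bursts gated by
#' an on/off process with duty `burst_duty`, spike-wave complexes repeating
#' at `spike_rate` with waxing-waning amplitude, shared across channels with
#' per-channel gains. The overall segment RMS is `amplitude_ratio` times the
#' (jittered) background RMS; with `amplitude_ratio = 1` and
#' `spike_rate = 0` the output reduces to a background segment.
#'
#' @inheritParams gen_background
#' @return a broadband [eeg_segment] labeled `"seizure"`.
#' @export
gen_seizure <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$segment_s * config$fs)
  bg <- background_matrix(config, n)
  st <- spike_train(config, n)
  extra <- config$amplitude_ratio^2 - 1
  if (extra > 0 && any(st$train != 0)) {
    gains <- stats::runif(config$n_channels, 0.7, 1)
    tr <- st$train / sqrt(mean(st$train^2))
    x <- bg + sqrt(extra) * outer(gains / sqrt(mean(gains^2)), tr)
  } else {
    x <- bg
  }
  x <- sweep(x, 1, sqrt(rowMeans(x^2)), "/")  # unit RMS per channel
  rms <- config$background_rms * stats::rlnorm(1, 0, config$amp_jitter_sd)
  eeg_segment(x * config$amplitude_ratio * rms, label = "seizure",
              band = "broadband", fs = config$fs)
}

#' Generate a labeled synthetic dataset
#'
#' `n_seizure + n_free` broadband segments in shuffled order with a manifest.
#' Deterministic for a given seed.
#'
#' @param config a [synth_config].
#' @param seed integer seed (default 1).
#' @return list with `segments` (list of [eeg_segment]) and `manifest`
#'   (data.frame `segment_id`, `label`).
#' @export
gen_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_seizure < 1 || config$n_free < 1)
    stop("need at least one segment per class")
  set.seed(seed)
  labels <- c(rep("seizure", config$n_seizure),
              rep("seizure_free", config$n_free))
  labels <- labels[sample.int(length(labels))]
  segments <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    seg <- if (labels[i] == "seizure") gen_seizure(config)
           else gen_background(config)
    seg$segment_id <- sprintf("syn%04d", i)
    segments[[i]] <- seg
  }
  manifest <- data.frame(segment_id = vapply(segments,
                                             function(s) s$segment_id, ""),
                         label = labels, stringsAsFactors = FALSE)
  list(segments = segments, manifest = manifest)
}
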