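# Shared fixture builders. Everything is generated in code at test time.

make_record <- function(duration_s = 30, fs = 256, n_ch = 2,
                        intervals = data.frame(start_s = numeric(0),
                                               end_s = numeric(0)),
                        seed = 1) {
  set.seed(seed)
  sig <- matrix(rnorm(n_ch * duration_s * fs, sd = 10), n_ch)
  eeg_record(sig, fs = fs,
             channel_labels = paste0("CH", seq_len(n_ch)),
             seizure_intervals = intervals)
}

# feature table with a planted perfectly-predictive feature among noise
make_planted_table <- function(n_per_class = 100, planted = 3,
                               band = "delta", seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * 10), n, 10)
  label <- rep(c("seizure", "seizure_free"), each = n_per_class)
  if (!is.na(planted))
    X[, planted] <- ifelse(label == "seizure", 1, -1) + rnorm(n, sd = 0.05)
  colnames(X) <- geo_feature_names()
  data.frame(segment_id = sprintf("s%04d", seq_len(n)),
             band = band, label = label, X, stringsAsFactors = FALSE)
}

make_noise_table <- function(n_per_class = 100, band = "delta", seed = 11) {
  make_planted_table(n_per_class, planted = NA, band = band, seed = seed)
}

small_swarm_config <- function(dim = 10, mode = "AsyLnCPSO-GA", trials = 5,
                               ...) {
  swarm_config(dim = dim, lower = -1, upper = 1, pop_size = 20,
               iterations = 40, trials = trials, mode = mode, ...)
}
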