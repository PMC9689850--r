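# Descriptive statistics over extracted features and selection results.

#' One-way ANOVA for two groups
#'
#' Classical between/within mean-square ratio with (k-1, N-k) degrees of
#' freedom, computed from raw sums of squares; the p-value comes from the F
#' distribution. When the within-group variance is zero and the group means
#' are equal, F is defined as 0 (p = 1); zero within-group variance with
#' unequal means gives F = Inf (p = 0).
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return named vector `c(F, p)`.
#' @export
anova_oneway <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  grand <- (sum(a) + sum(b)) / N
  ssb <- n1 * (mean(a) - grand)^2 + n2 * (mean(b) - grand)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  df1 <- 1; df2 <- N - 2
  if (ssw == 0) {
    if (ssb == 0) return(c(F = 0, p = 1))
    return(c(F = Inf, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  c(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Min-max normalization to the unit interval
#'
#' `(v - min)/(max - min)`; a constant input maps to all zeros (display
#' convention).
#'
#' @param values numeric vector.
#' @return numeric vector in \[0, 1\].
#' @export
normalize01 <- function(values) {
  v <- as.numeric(values)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Occurrence frequency of features across selection trials
#'
#' For each feature bit, the fraction of trials whose best mask includes it,
#' plus the top-k features per band.
#'
#' @param result a `selection_result` (from [select_features()]), or a list
#'   of per-trial masks with a `feature_names` attribute supplied via
#'   `feature_names`.
#' @param top_k how many top features to report per band (default 4).
#' @param feature_names band-qualified feature names (taken from `result`
#'   when it is a `selection_result`).
#' @return list with `frequency` (data.frame `band`, `feature`, `fraction`)
#'   and `top` (per band, the `top_k` most frequent features).
#' @export
key_feature_frequency <- function(result, top_k = 4, feature_names = NULL) {
  if (inherits(result, "selection_result")) {
    masks <- result$trial_masks
    feature_names <- result$feature_names
  } else {
    masks <- result
  }
  if (length(masks) == 0) stop("no trials in the selection result")
  if (is.null(feature_names)) stop("feature names are required")
  counts <- Reduce(`+`, masks)
  frac <- counts / length(masks)
  parts <- strsplit(feature_names, ".", fixed = TRUE)
  band <- vapply(parts, `[`, "", 1)
  feat <- vapply(parts, `[`, "", 2)
  freq <- data.frame(band = band, feature = feat, fraction = frac,
                     stringsAsFactors = FALSE, row.names = NULL)
  top <- lapply(split(freq, factor(freq$band, levels = unique(band))),
                function(d) d[order(-d$fraction), ][seq_len(min(top_k, nrow(d))), ])
  list(frequency = freq, top = top)
}

#' Per-band share of selected feature bits
#'
#' Across all trials of a multi-band selection, the percentage of selected
#' bits falling in each band; the shares sum to 100.
#'
#' @param result a `selection_result` for a multi-band combination.
#' @return named numeric vector of percentages, one per band.
#' @export
band_contribution <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  counts <- Reduce(`+`, result$trial_masks)
  band <- vapply(strsplit(result$feature_names, ".", fixed = TRUE),
                 `[`, "", 1)
  tot <- tapply(counts, factor(band, levels = result$bands), sum)
  if (sum(tot) == 0) stop("no bits selected in any trial")
  pct <- 100 * as.numeric(tot) / sum(tot)
  names(pct) <- result$bands
  pct
}
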