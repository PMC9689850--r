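#' Second-order difference plot of a signal
#'
#' Builds the second-order difference plot (SODP): the scatter of successive
#' first differences `x(i) = s(i+1) - s(i)` against their one-step lag
#' `y(i) = s(i+2) - s(i+1)`. The SODP is a Poincare-style representation of
#' signal variability; its geometry (spread, angles, areas, central density)
#' distinguishes ictal from interictal EEG.
#'
#' @param signal numeric vector, length >= 3.
#' @return an object of class `sodp`: list with `x`, `y` (equal-length numeric
#'   vectors) and `n_points = length(signal) - 2`.
#' @export
#' @examples
#' p <- compute_sodp(c(0, 1, 3, 6, 10))
#' p$x  # 1 2 3
#' p$y  # 2 3 4
compute_sodp <- function(signal) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 3) stop("signal must have at least 3 samples to form an SODP")
  d <- diff(signal)
  structure(
    list(x = d[-(n - 1L)], y = d[-1L], n_points = n - 2L),
    class = "sodp"
  )
}

#' @export
print.sodp <- function(x, ...) {
  cat("SODP with", x$n_points, "points; radial extent",
      format(max(sqrt(x$x^2 + x$y^2)), digits = 4), "\n")
  invisible(x)
}

as_sodp <- function(p) {
  if (inherits(p, "sodp")) return(p)
  stopifnot(is.list(p), length(p$x) == length(p$y))
  structure(list(x = as.numeric(p$x), y = as.numeric(p$y),
                 n_points = length(p$x)), class = "sodp")
}

# population variance (descriptor convention, not an estimator)
pop_var <- function(v) mean((v - mean(v))^2)

#' Ellipse standard descriptors of an SODP
#'
#' Dispersion of the SODP point cloud along the 45-degree and 135-degree
#' directions, i.e. the Poincare ellipse axes, and the ellipse area:
#' `STD1 = sqrt(Var((x - y)/sqrt(2)))`, `STD2 = sqrt(Var((x + y)/sqrt(2)))`,
#' `STD = pi * STD1 * STD2`. Population (1/n) variance is used throughout.
#'
#' @param p an [sodp] object (or list with `x`, `y`).
#' @return named numeric vector `c(STD1, STD2, STD)`.
#' @export
std_descriptors <- function(p) {
  p <- as_sodp(p)
  if (p$n_points < 2) stop("need at least 2 SODP points for the ellipse descriptors")
  std1 <- sqrt(pop_var((p$x - p$y) / sqrt(2)))
  std2 <- sqrt(pop_var((p$x + p$y) / sqrt(2)))
  c(STD1 = std1, STD2 = std2, STD = pi * std1 * std2)
}

#' Sum of angles between consecutive SODP vectors
#'
#' For each pair of consecutive points treated as vectors from the origin,
#' the cosine of the angle between them is accumulated:
#' `sum_i dot(v_i, v_{i+1}) / (||v_i|| * ||v_{i+1}||)`. A pair involving a
#' zero-length vector contributes 0. `denominator = "sum"` replaces the
#' product of norms with the root of the summed squared components, an
#' alternative reading of the defining formula kept for comparison.
#'
#' @param p an [sodp] object.
#' @param denominator `"product"` (cosine of the angle, default) or `"sum"`.
#' @return scalar; with the default denominator each term lies in \[-1, 1\].
#' @export
sav <- function(p, denominator = c("product", "sum")) {
  p <- as_sodp(p)
  denominator <- match.arg(denominator)
  if (p$n_points < 2) stop("need at least 2 SODP points for SAV")
  n <- p$n_points
  i <- seq_len(n - 1L)
  dots <- p$x[i] * p$x[i + 1L] + p$y[i] * p$y[i + 1L]
  r <- sqrt(p$x^2 + p$y^2)
  den <- if (denominator == "product") r[i] * r[i + 1L] else sqrt(r[i]^2 + r[i + 1L]^2)
  terms <- ifelse(den > 0, dots / den, 0)
  sum(terms)
}

#' Sum of shortest distances to the 45-degree line
#'
#' `sum_i |x_i - y_i| / sqrt(2)`: total scattering of the SODP points away
#' from the identity line y = x.
#'
#' @param p an [sodp] object.
#' @return nonnegative scalar in signal units.
#' @export
sshd <- function(p) {
  p <- as_sodp(p)
  if (p$n_points < 1) stop("empty SODP")
  sum(abs(p$x - p$y)) / sqrt(2)
}

#' Sum of triangle areas of consecutive SODP point triples
#'
#' Each run of three consecutive points forms a triangle; the absolute areas
#' (half the absolute determinant of the homogeneous-coordinate matrix) are
#' summed.
#'
#' @param p an [sodp] object with at least 3 points.
#' @return nonnegative scalar in squared signal units.
#' @export
sta <- function(p) {
  p <- as_sodp(p)
  n <- p$n_points
  if (n < 3) stop("need at least 3 SODP points for STA")
  i <- seq_len(n - 2L)
  # shoelace form of the 3x3 homogeneous determinant
  det2 <- (p$x[i + 1L] - p$x[i]) * (p$y[i + 2L] - p$y[i]) -
          (p$x[i + 2L] - p$x[i]) * (p$y[i + 1L] - p$y[i])
  0.5 * sum(abs(det2))
}

#' Central tendency measure of an SODP
#'
#' Fraction of SODP points inside the disk of radius
#' `r = rho * max_i sqrt(x_i^2 + y_i^2)` centered at the origin. The radius is
#' a proportion of this SODP's own radial extent, so the measure is invariant
#' to amplitude scaling; a low value means the plot spreads widely relative to
#' its extremes. An all-zero SODP yields 1 (every point satisfies `<= 0`).
#'
#' @param p an [sodp] object.
#' @param rho radius as a fraction of the radial extent, typically 0.3-0.5.
#' @return fraction in \[0, 1\].
#' @export
ctm <- function(p, rho) {
  p <- as_sodp(p)
  if (p$n_points < 1) stop("empty SODP")
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0)
  r2 <- p$x^2 + p$y^2
  mean(r2 <= rho^2 * max(r2))
}

#' Sum of distances to the coordinate origin
#'
#' `sum_i sqrt(x_i^2 + y_i^2)`: overall radial scattering of the SODP.
#'
#' @param p an [sodp] object.
#' @return nonnegative scalar in signal units.
#' @export
sdc <- function(p) {
  p <- as_sodp(p)
  if (p$n_points < 1) stop("empty SODP")
  sum(sqrt(p$x^2 + p$y^2))
}

#' Sum of successive vector lengths (SODP trajectory length)
#'
#' Polyline length of the SODP traversed in time order:
#' `sum_i sqrt((x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2)`.
#'
#' @param p an [sodp] object.
#' @return nonnegative scalar in signal units.
#' @export
ssvl <- function(p) {
  p <- as_sodp(p)
  if (p$n_points < 2) stop("need at least 2 SODP points for SSVL")
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

#' Sum of centroid-to-centroid distances of successive triangles
#'
#' Centroid `C_i` is the mean of points i, i+1, i+2; the distances between
#' consecutive centroids are summed, quantifying self-similarity of the plot.
#'
#' @param p an [sodp] object with at least 4 points.
#' @return nonnegative scalar in signal units.
#' @export
scc <- function(p) {
  p <- as_sodp(p)
  n <- p$n_points
  if (n < 4) stop("need at least 4 SODP points for SCC")
  i <- seq_len(n - 2L)
  cx <- (p$x[i] + p$x[i + 1L] + p$x[i + 2L]) / 3
  cy <- (p$y[i] + p$y[i + 1L] + p$y[i + 2L]) / 3
  sum(sqrt(diff(cx)^2 + diff(cy)^2))
}

#' Canonical order of the ten geometric SODP features
#'
#' The fixed ordering used throughout the package for feature vectors,
#' tables and particle encodings.
#' @return character vector of length 10.
#' @export
geo_feature_names <- function() {
  c("STD", "SAV", "SDC", "STA", "SSHD", "SCC", "SSVL",
    "CTM03", "CTM04", "CTM05")
}

#' All ten geometric SODP features of one signal
#'
#' Convenience wrapper: builds the SODP of `signal` and evaluates the ten
#' descriptors in the canonical order of [geo_feature_names()].
#'
#' @param signal numeric vector (one channel of a band-filtered segment).
#' @inheritParams sav
#' @return named numeric vector of length 10.
#' @export
geo_features <- function(signal, denominator = c("product", "sum")) {
  p <- compute_sodp(signal)
  denominator <- match.arg(denominator)
  c(STD   = unname(std_descriptors(p)["STD"]),
    SAV   = sav(p, denominator),
    SDC   = sdc(p),
    STA   = sta(p),
    SSHD  = sshd(p),
    SCC   = scc(p),
    SSVL  = ssvl(p),
    CTM03 = ctm(p, 0.3),
    CTM04 = ctm(p, 0.4),
    CTM05 = ctm(p, 0.5))
}

#' Extract a per-segment geometric feature table
#'
#' Computes the ten SODP descriptors for every channel of every segment and
#' averages them across channels, yielding one 10-dimensional vector per
#' segment. All segments must share the same band and window length. The
#' channel mean is used (rather than per-channel vectors) so that a band
#' contributes exactly ten features to the selection particle.
#'
#' @param segments list of band-filtered [eeg_segment] objects.
#' @inheritParams sav
#' @return a `data.frame` (feature table) with columns `segment_id`, `band`,
#'   `label`, then the ten features of [geo_feature_names()].
#' @export
extract_features <- function(segments, denominator = c("product", "sum")) {
  if (length(segments) == 0) stop("no segments supplied")
  denominator <- match.arg(denominator)
  bands <- vapply(segments, function(s) s$band, character(1))
  lens  <- vapply(segments, function(s) ncol(s$signal), integer(1))
  if (length(unique(bands)) != 1L)
    stop("all segments must share the same band")
  if (length(unique(lens)) != 1L)
    stop("all segments must share the same window length")
  feats <- t(vapply(segments, function(s) {
    per_ch <- apply(s$signal, 1L, geo_features, denominator = denominator)
    rowMeans(per_ch)
  }, numeric(10)))
  colnames(feats) <- geo_feature_names()
  ids <- vapply(seq_along(segments), function(i) {
    id <- segments[[i]]$segment_id
    if (is.null(id)) sprintf("seg%04d", i) else as.character(id)
  }, character(1))
  data.frame(
    segment_id = ids,
    band  = bands,
    label = vapply(segments, function(s) s$label, character(1)),
    feats,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Conventional time-domain summary features
#'
#' Eight simple descriptors used as a comparison baseline for the geometric
#' features: root mean square, peak-to-peak range, sample skewness and
#' kurtosis, and the shape, crest, impulse and clearance indicators. An
#' all-zero signal leaves the four indicator ratios undefined; they are
#' returned as 0 with a warning.
#'
#' @param signal numeric vector.
#' @return named numeric vector of length 8.
#' @export
time_domain_features <- function(signal) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  rms <- sqrt(mean(x^2))
  pk  <- max(x) - min(x)
  s   <- stats::sd(x)
  skw <- if (s > 0) mean((x - mean(x))^3) / (sqrt(mean((x - mean(x))^2)))^3 else 0
  krt <- if (s > 0) mean((x - mean(x))^4) / (mean((x - mean(x))^2))^2 else 0
  ma  <- mean(abs(x))
  mx  <- max(abs(x))
  msr <- mean(sqrt(abs(x)))^2
  if (ma == 0) {
    warning("all-zero signal: indicator ratios undefined, returning 0")
    shape <- crest <- impulse <- clearance <- 0
  } else {
    shape     <- rms / ma
    crest     <- mx / rms
    impulse   <- mx / ma
    clearance <- mx / msr
  }
  c(rms = rms, peak_peak = pk, skewness = skw, kurtosis = krt,
    shape_indicator = shape, crest_indicator = crest,
    impulse_indicator = impulse, clearance_indicator = clearance)
}
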