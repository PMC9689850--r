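# Independent brute-force oracles: term-by-term loops, no vectorization.
# These deliberately mirror the defining formulas one index at a time so the
# package implementations are checked against a separate code path.

bf_std <- function(x, y) {
  n <- length(x)
  u <- numeric(n); v <- numeric(n)
  for (i in seq_len(n)) {
    u[i] <- (x[i] - y[i]) / sqrt(2)
    v[i] <- (x[i] + y[i]) / sqrt(2)
  }
  pv <- function(z) {
    m <- sum(z) / length(z)
    s <- 0
    for (zz in z) s <- s + (zz - m)^2
    s / length(z)
  }
  s1 <- sqrt(pv(u)); s2 <- sqrt(pv(v))
  c(STD1 = s1, STD2 = s2, STD = pi * s1 * s2)
}

bf_sav <- function(x, y) {
  out <- 0
  for (i in seq_len(length(x) - 1)) {
    num <- x[i] * x[i + 1] + y[i] * y[i + 1]
    den <- sqrt(x[i]^2 + y[i]^2) * sqrt(x[i + 1]^2 + y[i + 1]^2)
    if (den > 0) out <- out + num / den
  }
  out
}

bf_sshd <- function(x, y) {
  out <- 0
  for (i in seq_along(x)) out <- out + abs(x[i] - y[i]) / sqrt(2)
  out
}

bf_sta <- function(x, y) {
  out <- 0
  for (i in seq_len(length(x) - 2)) {
    m <- matrix(c(x[i], x[i + 1], x[i + 2],
                  y[i], y[i + 1], y[i + 2],
                  1, 1, 1), 3, 3, byrow = TRUE)
    out <- out + 0.5 * abs(det(m))
  }
  out
}

bf_ctm <- function(x, y, rho) {
  rmax <- 0
  for (i in seq_along(x)) rmax <- max(rmax, sqrt(x[i]^2 + y[i]^2))
  r <- rho * rmax
  cnt <- 0
  for (i in seq_along(x)) if (sqrt(x[i]^2 + y[i]^2) <= r) cnt <- cnt + 1
  cnt / length(x)
}

bf_sdc <- function(x, y) {
  out <- 0
  for (i in seq_along(x)) out <- out + sqrt(x[i]^2 + y[i]^2)
  out
}

bf_ssvl <- function(x, y) {
  out <- 0
  for (i in seq_len(length(x) - 1))
    out <- out + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  out
}

bf_scc <- function(x, y) {
  n <- length(x)
  cx <- numeric(n - 2); cy <- numeric(n - 2)
  for (i in seq_len(n - 2)) {
    cx[i] <- (x[i] + x[i + 1] + x[i + 2]) / 3
    cy[i] <- (y[i] + y[i + 1] + y[i + 2]) / 3
  }
  out <- 0
  for (i in seq_len(n - 3))
    out <- out + sqrt((cx[i + 1] - cx[i])^2 + (cy[i + 1] - cy[i])^2)
  out
}

bf_anova <- function(a, b) {
  all <- c(a, b)
  grand <- mean(all)
  ssb <- length(a) * (mean(a) - grand)^2 + length(b) * (mean(b) - grand)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  (ssb / 1) / (ssw / (length(all) - 2))
}

random_sodp <- function(n = 60) {
  list(x = stats::rnorm(n), y = stats::rnorm(n))
}

# compare a package feature against its brute-force oracle on random SODPs
expect_matches_oracle <- function(fun, oracle, n_cases = 200, tol = 1e-10,
                                  seed = 404) {
  set.seed(seed)
  for (k in seq_len(n_cases)) {
    p <- random_sodp(sample(10:80, 1))
    got <- fun(p)
    want <- oracle(p$x, p$y)
    expect_equal(got, want, tolerance = tol)
  }
}
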