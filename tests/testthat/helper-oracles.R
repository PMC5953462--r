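# Independent oracles used across the suite. Each re-derives its target
# quantity by a direct method (explicit DFT sums, tridiagonal solves,
# exhaustive loops) that shares no code with the implementation under test.

make_uniform <- function(t, x, kind = "rr", fs = 4) {
  tfhrv:::new_uniform_series(t, x, fs, kind)
}

# Direct evaluation of the discrete SPWVD: instantaneous autocorrelation,
# explicit DFT matrices for the doppler transform and its inverse, kernel
# weighting, and an explicit lag -> frequency sum. Mirrors the published
# discretisation (zero padding of twice the lag support, lag truncation at
# the 1e-4 kernel level) without FFTs or wrap-around index tricks.
oracle_spwvd <- function(x, fs, kernel, freq) {
  n <- length(x)
  # analytic extension, spelled out
  xf <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  z <- fft(xf * h, inverse = TRUE) / n

  tau_max <- (log(1e4) / pi)^(1 / (4 * kernel$lambda)) / kernel$tau0
  m_max <- max(1L, floor(tau_max * fs / 2))
  pad <- 2L * m_max
  zp <- c(rep(0, pad), z, rep(0, pad))
  p <- length(zp)
  ms <- seq(-m_max, m_max)

  r <- matrix(0 + 0i, p, length(ms))
  for (j in seq_along(ms)) {
    for (i in seq_len(p)) {
      i1 <- i + ms[j]; i2 <- i - ms[j]
      if (i1 >= 1 && i1 <= p && i2 >= 1 && i2 <= p) {
        r[i, j] <- zp[i1] * Conj(zp[i2])
      }
    }
  }
  dop <- (seq_len(p) - 1) / p * fs
  dop[dop > fs / 2] <- dop[dop > fs / 2] - fs
  nn <- seq_len(p) - 1
  fwd <- exp(-2i * pi * outer(nn, nn) / p)     # doppler DFT
  a <- fwd %*% r
  psi <- outer(dop, 2 * ms / fs,
               function(nu, tau) {
                 exp(-pi * ((nu / kernel$nu0)^2 +
                            (tau * kernel$tau0)^2)^(2 * kernel$lambda))
               })
  r_s <- (Conj(fwd) %*% (a * psi)) / p
  r_s <- r_s[seq(pad + 1L, pad + n), , drop = FALSE]
  # explicit lag -> frequency sum at the requested frequencies
  ek <- exp(-2i * pi * outer(2 * ms / fs, freq))
  Re(r_s %*% ek) * (2 / fs)
}

# Natural cubic spline by direct tridiagonal solve of the second-derivative
# system (m_1 = m_n = 0), evaluated at arbitrary points.
oracle_natural_spline <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  a <- matrix(0, n, n)
  b <- numeric(n)
  a[1, 1] <- 1; a[n, n] <- 1
  for (i in 2:(n - 1)) {
    a[i, i - 1] <- h[i - 1]
    a[i, i] <- 2 * (h[i - 1] + h[i])
    a[i, i + 1] <- h[i]
    b[i] <- 6 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1])
  }
  m <- solve(a, b)
  vapply(xout, function(x) {
    i <- max(1, min(n - 1, findInterval(x, xk)))
    dx <- x - xk[i]
    yk[i] + dx * ((yk[i + 1] - yk[i]) / h[i] -
                  h[i] / 6 * (2 * m[i] + m[i + 1])) +
      dx^2 * m[i] / 2 + dx^3 * (m[i + 1] - m[i]) / (6 * h[i])
  }, numeric(1))
}

# Exhaustive ReliefF on a small matrix: per-centre loops over every
# instance to find hits and misses.
oracle_relieff <- function(x, y, k) {
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(v) max(v) - min(v))
  rng[rng == 0] <- 1
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    d[i] <- Inf
    hits <- order(ifelse(y == y[i], d, Inf))[1:k]
    miss <- order(ifelse(y != y[i], d, Inf))[1:k]
    for (j in seq_len(p)) {
      w[j] <- w[j] +
        (sum(abs(x[miss, j] - x[i, j]) / rng[j]) -
         sum(abs(x[hits, j] - x[i, j]) / rng[j])) / (n * k)
    }
  }
  w
}

# periodogram argmax frequency of a uniformly sampled sequence
periodogram_peak <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  pw <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) / n * fs
  half <- freqs > 0 & freqs <= fs / 2
  freqs[half][which.max(pw[half])]
}

# empirical AUC by exhaustive pairwise concordance
concordance_auc <- function(scores_pos, scores_neg) {
  s <- 0
  for (a in scores_pos) for (b in scores_neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(scores_pos) * length(scores_neg))
}
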