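#' Ambiguity-domain smoothing kernel
#'
#' The smoothed pseudo Wigner-Ville distribution used here filters the
#' ambiguity function with the radially-compressed exponential kernel
#' \deqn{\Psi(\tau, \nu) = \exp\{-\pi[(\nu/\nu_0)^2 +
#'   (\tau\,\tau_0)^2]^{2\lambda}\},}
#' where \eqn{\nu} is doppler in Hz and \eqn{\tau} is lag in seconds. Both
#' parameters are expressed in Hz: `nu0` is the doppler half-width (its
#' reciprocal sets the temporal smoothing scale, 1/0.06 = 16.7 s at the
#' default) and `tau0` is the reciprocal of the lag-window scale, so it
#' directly sets the spectral resolution (about 0.03 Hz at the default).
#' `lambda` controls how sharply the kernel rolls off.
#'
#' @param nu0 Doppler width in Hz.
#' @param tau0 Reciprocal lag width in Hz.
#' @param lambda Positive roll-off exponent.
#' @return An object of class `spwvd_kernel`.
#' @export
spwvd_kernel <- function(nu0 = 0.06, tau0 = 0.03, lambda = 0.3) {
  if (any(c(nu0, tau0, lambda) <= 0)) {
    abort("kernel parameters nu0, tau0 and lambda must be positive")
  }
  structure(list(nu0 = nu0, tau0 = tau0, lambda = lambda),
            class = "spwvd_kernel")
}

kernel_value <- function(kernel, tau_s, nu_hz) {
  u <- (nu_hz / kernel$nu0)^2 + (tau_s * kernel$tau0)^2
  exp(-pi * u^(2 * kernel$lambda))
}

# lag index truncation: largest m with kernel tau-factor >= 1e-4
kernel_lag_support <- function(kernel, fs) {
  tau_max <- (log(1e4) / pi)^(1 / (4 * kernel$lambda)) / kernel$tau0
  max(1L, floor(tau_max * fs / 2))
}

#' Effective time and frequency resolution of a kernel
#'
#' Diagnostic: equivalent widths (integral of the window divided by its
#' peak) of the lag and doppler sections of the kernel, converted to the
#' implied spectral and temporal resolutions.
#'
#' @param kernel An [spwvd_kernel()].
#' @return A tibble with `time_resolution_s` and `freq_resolution_hz`.
#' @export
kernel_resolution <- function(kernel) {
  dx <- 1e-3
  nu <- seq(0, 20 * kernel$nu0, by = dx * kernel$nu0)
  w_nu <- 2 * sum(kernel_value(kernel, 0, nu)) * dx * kernel$nu0
  tau <- seq(0, 20 / kernel$tau0, by = dx / kernel$tau0)
  w_tau <- 2 * sum(kernel_value(kernel, tau, 0)) * dx / kernel$tau0
  tibble(time_resolution_s = 1 / w_nu, freq_resolution_hz = 1 / w_tau)
}

# analytic extension via the FFT method (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Smoothed pseudo Wigner-Ville distribution
#'
#' Computes the discrete SPWVD of the analytic extension of a uniformly
#' sampled signal: the ambiguity function is formed from the instantaneous
#' autocorrelation, multiplied by the smoothing kernel, and transformed
#' back to the time-frequency plane. The signal is zero-padded at the
#' recording boundaries; time samples closer to either edge than the lag
#' half-support are flagged in the margin mask, and downstream window
#' averages ignore them.
#'
#' @param series A `uniform_series` (4 Hz pipeline signals).
#' @param kernel An [spwvd_kernel()].
#' @param freq_max Upper edge of the returned frequency grid (Hz).
#' @param freq_step Frequency grid resolution (Hz); must divide `fs/2`.
#' @return An object of class `tfr`: list with `time_s`, `freq_hz`, the
#'   real power matrix `power` (time x frequency), the logical `margin`
#'   mask, the sampling rate `fs` and the `kernel`. The largest imaginary
#'   residue relative to the real part is stored as attribute
#'   `"imag_residue"`.
#' @export
spwvd <- function(series, kernel = spwvd_kernel(), freq_max = 1,
                  freq_step = 0.005) {
  fs <- attr(series, "fs") %||% 4
  x <- series$value
  n <- length(x)
  if (n < 2 * 60 * fs) abort("signal must be at least 2 minutes long")
  if (any(!is.finite(x))) abort("signal contains non-finite values")

  m_max <- kernel_lag_support(kernel, fs)
  pad <- 2L * m_max
  z <- c(rep(0, pad), analytic_signal(x), rep(0, pad))
  p <- length(z)

  # instantaneous autocorrelation r[n, m] = z[n+m] conj(z[n-m]), zero
  # outside the padded support; columns ordered m = -m_max..m_max
  ms <- seq(-m_max, m_max)
  r <- matrix(0 + 0i, p, length(ms))
  for (j in seq_along(ms)) {
    m <- ms[j]
    idx <- seq_len(p)
    i1 <- idx + m
    i2 <- idx - m
    ok <- i1 >= 1L & i1 <= p & i2 >= 1L & i2 <= p
    r[idx[ok], j] <- z[i1[ok]] * Conj(z[i2[ok]])
  }

  # doppler-domain filtering (FFT over time per lag column)
  nu <- (seq_len(p) - 1) / p * fs
  nu[nu > fs / 2] <- nu[nu > fs / 2] - fs
  a <- stats::mvfft(r)
  psi <- kernel_value(kernel, outer(rep(1, p), 2 * ms / fs),
                      outer(nu, rep(1, length(ms))))
  r_s <- stats::mvfft(a * psi, inverse = TRUE) / p
  r_s <- r_s[seq(pad + 1L, pad + n), , drop = FALSE]

  # lag -> frequency transform; f_k = k * fs / (2K)
  k_fft <- as.integer(round(fs / (2 * freq_step)))
  if (abs(k_fft * freq_step - fs / 2) > 1e-9) {
    abort("freq_step must divide fs/2")
  }
  if (k_fft < length(ms)) abort("freq_step too coarse for the lag support")
  q <- matrix(0 + 0i, k_fft, n)
  q[1L, ] <- r_s[, m_max + 1L]
  for (m in seq_len(m_max)) {
    q[1L + m, ] <- r_s[, m_max + 1L + m]
    q[k_fft + 1L - m, ] <- r_s[, m_max + 1L - m]
  }
  cmat <- stats::mvfft(q) * (2 / fs)
  freq <- (seq_len(k_fft) - 1) * freq_step
  keep <- freq <= freq_max + 1e-12
  cmat <- t(cmat[keep, , drop = FALSE])
  resid <- max(abs(Im(cmat))) / max(abs(Re(cmat)), .Machine$double.eps)

  margin <- rep(FALSE, n)
  margin[seq_len(min(m_max, n))] <- TRUE
  margin[seq(max(1L, n - m_max + 1L), n)] <- TRUE

  structure(
    list(time_s = series$time_s, freq_hz = freq[keep],
         power = Re(cmat), margin = margin, fs = fs, kernel = kernel),
    class = "tfr", imag_residue = resid
  )
}

#' @export
print.tfr <- function(x, ...) {
  res <- kernel_resolution(x$kernel)
  cat(sprintf(
    paste0("<tfr> %d time samples x %d frequency bins ",
           "(%.3f-%.3f Hz)\n  effective resolution: %.1f s, %.4f Hz; ",
           "%d margin samples masked\n"),
    length(x$time_s), length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
    res$time_resolution_s, res$freq_resolution_hz, sum(x$margin)
  ))
  invisible(x)
}

# trapezoidal integral of one spectral row over [lo, hi] with linear
# interpolation at the band edges
row_band_trapz <- function(freq, vals, lo, hi) {
  if (lo >= hi) abort("band lower edge must be below the upper edge")
  inside <- which(freq > lo & freq < hi)
  f <- c(lo, freq[inside], hi)
  v <- c(approx(freq, vals, xout = lo, rule = 2)$y,
         vals[inside],
         approx(freq, vals, xout = hi, rule = 2)$y)
  sum(diff(f) * (v[-1] + v[-length(v)]) / 2)
}

#' Integrate band power from a time-frequency distribution
#'
#' Per-time trapezoidal integral of the distribution over a frequency
#' band. The band may be fixed (two numbers) or time-varying (a
#' `band_definition` tibble with per-time edges, as produced by
#' [hf_band_from_fr()]). Negative excursions of the distribution are kept,
#' not clipped.
#'
#' @param tfd A `tfr` object.
#' @param band Either `c(lower, upper)` in Hz or a tibble with columns
#'   `lower_hz` and `upper_hz` of length `nrow` equal to the time grid.
#' @return A tibble (`time_s`, `power`, `masked`) where `masked` carries
#'   the kernel margin mask.
#' @export
band_power <- function(tfd, band = c(0.04, 0.15)) {
  stopifnot(inherits(tfd, "tfr"))
  n <- length(tfd$time_s)
  if (is.data.frame(band)) {
    if (nrow(band) != n) {
      abort("time-varying band must have one row per time sample")
    }
    lo <- band$lower_hz
    hi <- band$upper_hz
  } else {
    lo <- rep(band[1], n)
    hi <- rep(band[2], n)
  }
  rng <- range(tfd$freq_hz)
  if (any(lo < rng[1] - 1e-9) || any(hi > rng[2] + 1e-9)) {
    abort("band lies outside the frequency grid of the distribution")
  }
  pw <- vapply(
    seq_len(n),
    function(i) row_band_trapz(tfd$freq_hz, tfd$power[i, ], lo[i], hi[i]),
    numeric(1)
  )
  tibble(time_s = tfd$time_s, power = pw, masked = tfd$margin)
}

#' @describeIn spwvd Heatmap of a time-frequency distribution.
#' @param object A `tfr` object.
#' @param ... Unused.
#' @export
autoplot.tfr <- function(object, ...) {
  df <- expand.grid(time_s = object$time_s, freq_hz = object$freq_hz)
  df$power <- as.vector(object$power)
  ggplot(df, aes(.data$time_s, .data$freq_hz, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency (Hz)", fill = "power") +
    theme_minimal()
}
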