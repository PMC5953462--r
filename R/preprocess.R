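#' Automatic RR artifact correction
#'
#' Replaces RR intervals that deviate from the median of their 11-beat
#' neighbourhood by more than a fractional tolerance with that local
#' median. This is an automatic, reproducible surrogate for manual beat
#' editing; it is off by default in the extraction pipeline.
#'
#' @param series A `beat_series`.
#' @param tolerance Fractional deviation from the local median above which
#'   an RR value is replaced; must lie in (0, 1).
#' @return The corrected `beat_series`; the number of replaced intervals is
#'   attached as attribute `"n_replaced"`. Series shorter than the 11-beat
#'   neighbourhood are returned unchanged with attribute
#'   `"too_short" = TRUE` and a warning.
#' @export
correct_rr_artifacts <- function(series, tolerance = 0.3) {
  if (tolerance <= 0 || tolerance >= 1) abort("tolerance must lie in (0, 1)")
  rr <- series$rr_ms[-1]
  if (length(rr) < 11L) {
    warn("series shorter than the 11-beat neighbourhood; returned unchanged")
    attr(series, "n_replaced") <- 0L
    attr(series, "too_short") <- TRUE
    return(series)
  }
  med <- runmed(rr, 11L, endrule = "median")
  bad <- abs(rr - med) > tolerance * med
  rr[bad] <- med[bad]
  out <- series
  out$rr_ms <- c(series$rr_ms[1], rr)
  attr(out, "n_replaced") <- sum(bad)
  out
}

new_uniform_series <- function(time_s, value, fs, kind) {
  structure(
    tibble(time_s = time_s, value = value),
    class = c("uniform_series", "tbl_df", "tbl", "data.frame"),
    fs = fs, kind = kind
  )
}

#' Resample a beat channel to a uniform grid
#'
#' Interpolates the chosen per-beat channel with a natural cubic spline and
#' evaluates it on a uniform grid (default 4 Hz, i.e. 0.25 s spacing)
#' spanning the beat times. RR values are anchored at the time of the beat
#' ending the interval; no extrapolation is performed beyond the first and
#' last available beat.
#'
#' @param series A `beat_series`.
#' @param channel `"rr"` (ms) or `"amplitude"`.
#' @param rate Sampling rate of the output grid in Hz.
#' @return A `uniform_series` tibble (`time_s`, `value`) with attributes
#'   `fs` and `kind`.
#' @export
resample_uniform <- function(series, channel = c("rr", "amplitude"),
                             rate = 4) {
  channel <- match.arg(channel)
  if (nrow(series) < 4L) {
    abort("at least 4 beats are required for spline resampling")
  }
  if (channel == "rr") {
    tt <- series$time_s[-1]
    vv <- series$rr_ms[-1]
    kind <- "rr"
  } else {
    tt <- series$time_s
    vv <- series$r_amp
    if (any(is.na(vv))) abort("amplitude channel contains missing values")
    kind <- "amp"
  }
  dt <- 1 / rate
  grid <- seq(ceiling(tt[1] / dt) * dt, floor(tt[length(tt)] / dt) * dt,
              by = dt)
  vals <- spline(tt, vv, xout = grid, method = "natural")$y
  new_uniform_series(grid, vals, fs = rate, kind = kind)
}

# direct-form II transposed IIR filter with explicit initial state
lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- zi %||% rep(0, nf - 1L)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (nf > 2L) {
      for (j in seq_len(nf - 2L)) {
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
      }
    }
    z[nf - 1L] <- b[nf] * x[i] - a[nf] * y[i]
  }
  y
}

# steady-state filter state for a unit step (removes start-up transients)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  comp <- rbind(-a[2:nf],
                cbind(diag(1, nf - 2L), rep(0, nf - 2L)))
  rhs <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(1, nf - 1L) - t(comp), rhs)
}

# zero-phase filtering: forward-backward passes with odd-reflective
# padding of 3x the filter length and steady-state initial conditions;
# both pass orders are averaged so the operator is exactly symmetric
# under time reversal
filtfilt_once <- function(b, a, x) {
  np <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= np) abort("series too short for zero-phase filtering")
  front <- 2 * x[1] - x[seq(np + 1L, 2L)]
  back <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - np)]
  xe <- c(front, x, back)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, xe, zi * xe[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[seq(np + 1L, np + length(x))]
}

filtfilt_reflect <- function(b, a, x) {
  (filtfilt_once(b, a, x) + rev(filtfilt_once(b, a, rev(x)))) / 2
}

#' High-pass filter an RR series
#'
#' Removes the very-low-frequency trend with a 4th-order Butterworth
#' high-pass filter (cutoff 0.03 Hz by default) applied in both forward and
#' backward directions, so the filter is zero-phase.
#'
#' @param series A `uniform_series` of kind `rr`.
#' @param cutoff_hz High-pass cutoff in Hz.
#' @param order Butterworth order of each pass.
#' @return A `uniform_series` of kind `rr`, approximately zero-mean.
#' @export
highpass_rr <- function(series, cutoff_hz = 0.03, order = 4L) {
  fs <- attr(series, "fs")
  if (!identical(attr(series, "kind"), "rr")) {
    abort("highpass_rr expects a uniform series of kind 'rr'")
  }
  if (nrow(series) <= 3L * (2L * order + 1L)) {
    abort("series too short for the high-pass filter")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  new_uniform_series(series$time_s,
                     filtfilt_reflect(bf$b, bf$a, series$value),
                     fs = fs, kind = "rr")
}

#' ECG-derived respiration from R-amplitude modulation
#'
#' Builds the surrogate respiratory signal: the R-peak amplitude channel is
#' resampled to a uniform grid (natural cubic spline, 4 Hz) and band-pass
#' filtered to the respiratory range with a zero-phase 4th-order
#' Butterworth filter (0.15-0.7 Hz by default).
#'
#' @param series A `beat_series` with an amplitude channel.
#' @param band Two-element pass band in Hz.
#' @param rate Output sampling rate in Hz.
#' @return A `uniform_series` of kind `edr`.
#' @export
edr_series <- function(series, band = c(0.15, 0.7), rate = 4) {
  us <- resample_uniform(series, "amplitude", rate = rate)
  bf <- signal::butter(4L, band / (rate / 2), type = "pass")
  new_uniform_series(us$time_s, filtfilt_reflect(bf$b, bf$a, us$value),
                     fs = rate, kind = "edr")
}
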