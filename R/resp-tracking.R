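#' Track the instantaneous respiratory frequency
#'
#' Follows the spectral peak of the EDR's time-frequency distribution
#' through time. At the first sample the peak is picked inside the standard
#' HF band (0.15-0.4 Hz). At every later sample the search is restricted
#' to a narrow interval of half-width `delta` centred on a reference
#' frequency updated as an exponential average of previous picks,
#' `f_r(k) = beta * f_r(k-1) + (1 - beta) * fhat(k-1)`, which rejects
#' transient spurious peaks. Discrete argmax picks are refined below bin
#' resolution by parabolic interpolation.
#'
#' @param tfd A `tfr` computed from an EDR series.
#' @param beta Forgetting factor in (0, 1).
#' @param delta Search half-width in Hz.
#' @param init_band Initial search band in Hz.
#' @return A tibble of class `resp_track` with columns `time_s`, `fhat_hz`
#'   (raw constrained peak picks), `fr_hz` (reference series) and
#'   `at_edge` (pick landed on a search-window edge). A diagnostic
#'   attribute `"edge_run"` gives the longest run of edge-limited picks;
#'   runs longer than 10 samples raise a warning (tracker may be lost).
#' @export
track_resp_frequency <- function(tfd, beta = 0.7, delta = 0.01,
                                 init_band = c(0.15, 0.4)) {
  stopifnot(inherits(tfd, "tfr"))
  if (beta <= 0 || beta >= 1) abort("beta must lie in (0, 1)")
  if (delta <= 0) abort("delta must be positive")
  freq <- tfd$freq_hz
  n <- length(tfd$time_s)

  pick_peak <- function(row, lo, hi) {
    idx <- which(freq >= lo & freq <= hi)
    if (!length(idx)) abort("empty search interval after clipping to grid")
    j <- idx[which.max(row[idx])]
    f0 <- freq[j]
    # parabolic refinement on the log-free power values
    if (j > 1L && j < length(freq)) {
      y1 <- row[j - 1L]; y2 <- row[j]; y3 <- row[j + 1L]
      den <- y1 - 2 * y2 + y3
      if (is.finite(den) && abs(den) > .Machine$double.eps) {
        off <- 0.5 * (y1 - y3) / den
        f0 <- f0 + max(-0.5, min(0.5, off)) * (freq[2] - freq[1])
      }
    }
    list(f = min(max(f0, lo), hi),
         at_edge = j == idx[1] || j == idx[length(idx)])
  }

  if (all(tfd$power[1, ] <= 0)) {
    abort("all-zero spectrum at the first time sample; cannot initialise")
  }
  fhat <- numeric(n)
  fr <- numeric(n)
  at_edge <- logical(n)
  p0 <- pick_peak(tfd$power[1, ], init_band[1], init_band[2])
  fhat[1] <- p0$f
  fr[1] <- p0$f
  at_edge[1] <- FALSE
  for (k in seq(2L, n)) {
    fr[k] <- beta * fr[k - 1L] + (1 - beta) * fhat[k - 1L]
    fr[k] <- min(max(fr[k], 0.15), 0.7)
    p <- pick_peak(tfd$power[k, ], fr[k] - delta, fr[k] + delta)
    fhat[k] <- p$f
    at_edge[k] <- p$at_edge
  }
  runs <- rle(at_edge)
  edge_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (edge_run > 10L) {
    warn(sprintf(
      "peak pick stuck on the search-window edge for %d consecutive samples; the tracker may be lost",
      edge_run
    ))
  }
  structure(
    tibble(time_s = tfd$time_s, fhat_hz = fhat, fr_hz = fr,
           at_edge = at_edge),
    class = c("resp_track", "tbl_df", "tbl", "data.frame"),
    beta = beta, delta = delta, edge_run = edge_run
  )
}

#' Respiration-centred HF band
#'
#' Builds the time-varying HF band of half-width 0.125 Hz centred on the
#' tracked respiratory frequency. By default the band is not clipped;
#' when the respiratory frequency drops below 0.275 Hz the band overlaps
#' the upper edge of the LF band (0.15 Hz), which is reported through the
#' `overlaps_lf` attribute rather than silently corrected. Setting
#' `clip_lf = TRUE` clips the lower edge at 0.15 Hz.
#'
#' @param fr A `resp_track` (or tibble with `time_s`, `fr_hz`).
#' @param half_width Band half-width in Hz.
#' @param clip_lf Clip the lower edge at 0.15 Hz?
#' @return A tibble of class `band_definition` with columns `time_s`,
#'   `lower_hz`, `upper_hz`.
#' @export
hf_band_from_fr <- function(fr, half_width = 0.125, clip_lf = FALSE) {
  lower <- fr$fr_hz - half_width
  if (clip_lf) lower <- pmax(lower, 0.15)
  out <- tibble(time_s = fr$time_s, lower_hz = lower,
                upper_hz = fr$fr_hz + half_width)
  overlaps <- any(out$lower_hz < 0.15)
  if (overlaps && !clip_lf) {
    inform("HF band overlaps the LF band (lower edge below 0.15 Hz)")
  }
  structure(out,
    class = c("band_definition", "tbl_df", "tbl", "data.frame"),
    overlaps_lf = overlaps
  )
}

#' @describeIn track_resp_frequency Plot the tracked respiratory frequency.
#' @param object A `resp_track`.
#' @param ... Unused.
#' @export
autoplot.resp_track <- function(object, ...) {
  ggplot(object, aes(.data$time_s)) +
    geom_line(aes(y = .data$fhat_hz), colour = "grey60", linewidth = 0.3) +
    geom_line(aes(y = .data$fr_hz), colour = "firebrick") +
    labs(x = "time (s)", y = "respiratory frequency (Hz)") +
    theme_minimal()
}
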