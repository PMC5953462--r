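#' Exercise-test protocol profile for synthetic recordings
#'
#' Describes a cyclo-ergometer stress test as a deterministic RR-interval
#' trend plus two spectral components: a low-frequency (LF) oscillation at a
#' fixed frequency and a high-frequency (HF) respiratory oscillation whose
#' instantaneous frequency follows a piecewise-linear trajectory. Defaults
#' emulate a standard triangular protocol: 2 min warm-up at a baseline RR,
#' 8 min incremental exercise with a monotone RR decrease, then 3 min active
#' and 3 min passive recovery with an exponential RR rebound.
#'
#' @param warmup_s,exercise_s,active_rec_s,passive_rec_s Phase durations in
#'   seconds; all must be positive.
#' @param baseline_rr_ms Resting RR interval in ms, within \[300, 2000\].
#' @param rr_slope_ms_min RR decrease per minute of incremental exercise (ms).
#' @param recovery_tau_s Time constant of the exponential RR rebound (s).
#' @param lf_freq_hz,lf_amp_ms Frequency (Hz) and amplitude (ms) of the LF
#'   oscillation.
#' @param hf_amp_ms Amplitude (ms) of the respiratory (HF) RR oscillation.
#' @param resp_nodes Two-column data frame (`time_s`, `fr_hz`) of
#'   piecewise-linear respiratory-frequency nodes; all frequencies must lie
#'   in \[0.15, 0.7\] Hz.
#' @param am_depth Fractional depth of the R-amplitude respiratory
#'   modulation.
#' @param noise_sd_ms SD of white Gaussian noise added per beat to RR (ms).
#' @param amp_noise_sd SD of white noise on the R-amplitude channel.
#' @param seed Integer seed; the generated recording is a deterministic
#'   function of the profile, including this seed.
#'
#' @return An object of class `exercise_profile`.
#' @export
exercise_profile <- function(warmup_s = 120, exercise_s = 480,
                             active_rec_s = 180, passive_rec_s = 180,
                             baseline_rr_ms = 800, rr_slope_ms_min = 40,
                             recovery_tau_s = 90,
                             lf_freq_hz = 0.1, lf_amp_ms = 25,
                             hf_amp_ms = 20,
                             resp_nodes = NULL,
                             am_depth = 0.2,
                             noise_sd_ms = 5, amp_noise_sd = 0.02,
                             seed = 1L) {
  durs <- c(warmup_s, exercise_s, active_rec_s, passive_rec_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort("all phase durations must be positive")
  }
  if (baseline_rr_ms < 300 || baseline_rr_ms > 2000) {
    abort("baseline RR must lie in [300, 2000] ms")
  }
  total <- sum(durs)
  if (is.null(resp_nodes)) {
    resp_nodes <- tibble(
      time_s = c(0, warmup_s, warmup_s + exercise_s,
                 warmup_s + exercise_s + active_rec_s, total),
      fr_hz = c(0.25, 0.25, 0.55, 0.35, 0.30)
    )
  }
  resp_nodes <- as_tibble(resp_nodes)
  if (!all(c("time_s", "fr_hz") %in% names(resp_nodes))) {
    abort("resp_nodes needs columns time_s and fr_hz")
  }
  if (any(resp_nodes$fr_hz < 0.15 | resp_nodes$fr_hz > 0.7)) {
    abort("respiratory trajectory nodes must lie within [0.15, 0.7] Hz")
  }
  structure(
    list(
      warmup_s = warmup_s, exercise_s = exercise_s,
      active_rec_s = active_rec_s, passive_rec_s = passive_rec_s,
      baseline_rr_ms = baseline_rr_ms, rr_slope_ms_min = rr_slope_ms_min,
      recovery_tau_s = recovery_tau_s,
      lf_freq_hz = lf_freq_hz, lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
      resp_nodes = resp_nodes, am_depth = am_depth,
      noise_sd_ms = noise_sd_ms, amp_noise_sd = amp_noise_sd,
      seed = as.integer(seed)
    ),
    class = "exercise_profile"
  )
}

# RR trend in ms at time t (vectorised): warm-up plateau, linear decrease
# during exercise, exponential rebound during recovery
rr_trend <- function(profile, t) {
  t_ex <- profile$warmup_s
  t_pk <- profile$warmup_s + profile$exercise_s
  drop <- profile$rr_slope_ms_min / 60
  rr_pk <- profile$baseline_rr_ms - drop * profile$exercise_s
  out <- numeric(length(t))
  wu <- t < t_ex
  ex <- t >= t_ex & t < t_pk
  rec <- t >= t_pk
  out[wu] <- profile$baseline_rr_ms
  out[ex] <- profile$baseline_rr_ms - drop * (t[ex] - t_ex)
  out[rec] <- rr_pk + (profile$baseline_rr_ms - rr_pk) *
    (1 - exp(-(t[rec] - t_pk) / profile$recovery_tau_s))
  out
}

# cumulative respiratory phase: phi(t) = 2*pi * integral of fr(u) du, with
# fr piecewise linear through the profile nodes
resp_phase_fun <- function(resp_nodes, total_s, dt = 0.05) {
  tg <- seq(0, total_s, by = dt)
  fr <- approx(resp_nodes$time_s, resp_nodes$fr_hz, xout = tg, rule = 2)$y
  phi <- 2 * pi * c(0, cumsum((fr[-1] + fr[-length(fr)]) / 2 * dt))
  list(
    phase = function(t) approx(tg, phi, xout = t, rule = 2)$y,
    fr = function(t) approx(tg, fr, xout = t, rule = 2)$y
  )
}

#' Simulate a protocol-structured exercise recording
#'
#' Generates a beat-by-beat recording whose RR series is
#' `trend(t) + A_LF sin(2 pi f_LF t) + A_HF sin(phi_r(t)) + noise`, where
#' `phi_r` is the integral of the programmed respiratory-frequency
#' trajectory, so the instantaneous HF frequency equals that trajectory
#' exactly. Beats are placed by cumulative-RR accumulation (the next beat
#' falls one RR interval after the previous one). R-peak amplitudes carry a
#' respiratory amplitude modulation `1 + depth * sin(phi_r(t))`.
#'
#' @param profile An [exercise_profile()].
#' @return An object of class `synthetic_recording`: a list with elements
#'   `beats` (tibble `time_s`, `rr_ms`, `r_amp`), `segmentation` (one-row
#'   tibble of protocol timestamps), and `truth` (ground truth: respiratory
#'   trajectory on a 0.25 s grid, component amplitudes, and the normalized
#'   HF fraction implied by the programmed tone amplitudes).
#' @export
simulate_recording <- function(profile = exercise_profile()) {
  stopifnot(inherits(profile, "exercise_profile"))
  total <- profile$warmup_s + profile$exercise_s + profile$active_rec_s +
    profile$passive_rec_s
  rp <- resp_phase_fun(profile$resp_nodes, total)

  withr::local_seed(profile$seed)
  # beats by cumulative-RR placement; generous preallocation
  n_max <- ceiling(total / 0.25) + 16L
  times <- numeric(n_max)
  k <- 1L
  t_k <- 0
  repeat {
    rr_k <- rr_trend(profile, t_k) +
      profile$lf_amp_ms * sin(2 * pi * profile$lf_freq_hz * t_k) +
      profile$hf_amp_ms * sin(rp$phase(t_k)) +
      rnorm(1L, 0, profile$noise_sd_ms)
    rr_k <- max(rr_k, 250)              # physiological floor
    t_next <- t_k + rr_k / 1000
    if (t_next > total) break
    k <- k + 1L
    times[k] <- t_next
    t_k <- t_next
  }
  times <- times[seq_len(k)]
  amps <- 1 + profile$am_depth * sin(rp$phase(times)) +
    rnorm(k, 0, profile$amp_noise_sd)

  beats <- tibble(
    time_s = times,
    rr_ms = c(NA_real_, diff(times) * 1000),
    r_amp = amps
  )
  seg <- tibble(
    warmup_start_s = 0,
    exercise_start_s = profile$warmup_s,
    peak_effort_s = profile$warmup_s + profile$exercise_s,
    active_rec_end_s = profile$warmup_s + profile$exercise_s +
      profile$active_rec_s,
    passive_rec_end_s = total
  )
  grid <- seq(0, total, by = 0.25)
  p_lf <- profile$lf_amp_ms^2 / 2
  p_hf <- profile$hf_amp_ms^2 / 2
  truth <- list(
    fr = tibble(time_s = grid, fr_hz = rp$fr(grid)),
    lf_amp_ms = profile$lf_amp_ms,
    hf_amp_ms = profile$hf_amp_ms,
    hfnu_true = if (p_lf + p_hf > 0) 100 * p_hf / (p_lf + p_hf) else NA_real_
  )
  structure(
    list(beats = beats, segmentation = seg, truth = truth, profile = profile),
    class = "synthetic_recording"
  )
}

#' Write a synthetic recording to disk
#'
#' Writes the beat file (`<stem>_beats.csv`, columns `time_s,rr_ms,r_amp`),
#' the segmentation file (`<stem>_segmentation.csv`) and the ground truth
#' (`<stem>_truth.json`) next to each other.
#'
#' @param recording A `synthetic_recording`.
#' @param stem Path stem (directory + basename without extension).
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "synthetic_recording"))
  paths <- c(
    beats = paste0(stem, "_beats.csv"),
    segmentation = paste0(stem, "_segmentation.csv"),
    truth = paste0(stem, "_truth.json")
  )
  readr::write_csv(recording$beats, paths[["beats"]])
  readr::write_csv(recording$segmentation, paths[["segmentation"]])
  jsonlite::write_json(
    list(
      fr = recording$truth$fr,
      lf_amp_ms = recording$truth$lf_amp_ms,
      hf_amp_ms = recording$truth$hf_amp_ms,
      hfnu_true = recording$truth$hfnu_true
    ),
    paths[["truth"]],
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}
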