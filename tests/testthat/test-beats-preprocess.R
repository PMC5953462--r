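test_that("beat files define RR from consecutive times and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "b.csv")
  writeLines(c("time_s,r_amp", "0,1", "0.8,1.1", "1.7,0.9"), f)
  b <- read_beats(f)
  expect_equal(b$rr_ms, c(NA, 800, 900))

  rec <- simulate_recording(exercise_profile(seed = 4))
  f2 <- file.path(dir, "b2.csv")
  write_beats(rec$beats, f2)
  again <- read_beats(f2)
  expect_equal(again$time_s, rec$beats$time_s)
  expect_equal(again$r_amp, rec$beats$r_amp)
})

test_that("non-monotone beat times raise an error naming the row", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("time_s,r_amp", "0,1", "0.8,1", "1.6,1", "2.4,1", "2.0,1"), f)
  expect_error(read_beats(f), "row 5")
  f2 <- file.path(dir, "cols.csv")
  writeLines(c("time_s,rr_ms", "0,NA"), f2)
  expect_error(read_beats(f2), "r_amp")
})

test_that("artifact correction replaces outliers with the local median", {
  set.seed(1)
  n <- 60
  beats <- tibble::tibble(
    time_s = cumsum(c(0, rep(0.8, n - 1))),
    rr_ms = c(NA, rep(800, n - 1)),
    r_amp = rep(1, n)
  )
  clean <- tfhrv:::new_beat_series(beats)
  out <- correct_rr_artifacts(clean, 0.3)
  expect_equal(attr(out, "n_replaced"), 0L)

  spoiled <- beats
  spoiled$rr_ms[30] <- 1600       # simulated missed beat
  # oracle: the 11-beat local median around the spoiled position
  med <- median(spoiled$rr_ms[c(25:29, 30, 31:35)][-6])
  out2 <- correct_rr_artifacts(tfhrv:::new_beat_series(spoiled), 0.3)
  expect_equal(attr(out2, "n_replaced"), 1L)
  expect_equal(out2$rr_ms[30], med)

  dip <- beats
  dip$rr_ms[20] <- 400
  out3 <- correct_rr_artifacts(tfhrv:::new_beat_series(dip), 0.2)
  expect_equal(out3$rr_ms[20], 800)
})

test_that("artifact correction is idempotent and guards short series", {
  set.seed(7)
  beats <- tibble::tibble(
    time_s = cumsum(c(0, runif(99, 0.7, 0.9))),
    r_amp = rep(1, 100)
  )
  beats$rr_ms <- c(NA, diff(beats$time_s) * 1000)
  beats$rr_ms[c(20, 50)] <- beats$rr_ms[c(20, 50)] * 2
  b <- tfhrv:::new_beat_series(beats)
  once <- correct_rr_artifacts(b, 0.3)
  twice <- correct_rr_artifacts(once, 0.3)
  expect_equal(attr(twice, "n_replaced"), 0L)
  expect_equal(twice$rr_ms, once$rr_ms)

  short <- tfhrv:::new_beat_series(beats[1:8, ])
  expect_warning(out <- correct_rr_artifacts(short, 0.3), "unchanged")
  expect_equal(out$rr_ms, short$rr_ms)
})

test_that("uniform resampling runs on a 0.25 s grid and keeps constants", {
  beats <- tibble::tibble(
    time_s = cumsum(c(0, rep(1, 59))),
    rr_ms = c(NA, rep(1000, 59)),
    r_amp = rep(1, 60)
  )
  us <- resample_uniform(tfhrv:::new_beat_series(beats), "rr")
  expect_equal(unique(diff(us$time_s)), 0.25, tolerance = 1e-12)
  expect_true(all(abs(us$value - 1000) < 1e-9))
  expect_gte(min(us$time_s), beats$time_s[2])
  expect_lte(max(us$time_s), max(beats$time_s))
  expect_error(resample_uniform(tfhrv:::new_beat_series(beats[1:3, ]), "rr"),
               "4 beats")
})

test_that("spline resampling matches an independent natural-spline solve", {
  set.seed(11)
  tt <- cumsum(runif(40, 0.6, 1.1))
  vv <- sin(2 * pi * 0.05 * tt)
  beats <- tibble::tibble(time_s = tt, rr_ms = c(NA, diff(tt) * 1000),
                          r_amp = vv)
  us <- resample_uniform(tfhrv:::new_beat_series(beats), "amplitude")
  expected <- oracle_natural_spline(tt, vv, us$time_s)
  expect_lt(max(abs(us$value - expected)) / max(abs(expected)), 1e-9)
})

test_that("natural-spline resampling is exact on low-degree polynomials", {
  tt <- seq(0, 40, by = 0.9)
  lin <- 3 + 0.5 * tt
  beats <- tibble::tibble(time_s = tt, rr_ms = c(NA, diff(tt) * 1000),
                          r_amp = lin)
  us <- resample_uniform(tfhrv:::new_beat_series(beats), "amplitude")
  expect_lt(max(abs(us$value - (3 + 0.5 * us$time_s))), 1e-9)
  # cubics are reproduced away from the free boundary only
  cub <- tt^3 - 5 * tt^2
  beats$r_amp <- cub
  us2 <- resample_uniform(tfhrv:::new_beat_series(beats), "amplitude")
  interior <- us2$time_s > 10 & us2$time_s < 30
  expect_lt(max(abs(us2$value[interior] -
                    (us2$time_s[interior]^3 - 5 * us2$time_s[interior]^2))),
            1e-3 * max(abs(cub)))
})

test_that("high-pass filter removes DC and preserves in-band tones", {
  t <- seq(0, 600, by = 0.25)
  const <- make_uniform(t, rep(5, length(t)))
  out <- highpass_rr(const)
  expect_lt(max(abs(out$value)), 1e-6 * 5)

  tone <- make_uniform(t, sin(2 * pi * 0.1 * t))
  filt <- highpass_rr(tone)
  mid <- t > 100 & t < 500
  # oracle: squared magnitude response of the cascaded Butterworth at 0.1 Hz
  bf <- signal::butter(4, 0.03 / 2, type = "high")
  zw <- exp(-1i * 2 * pi * 0.1 / 4 * (seq_along(bf$b) - 1))
  h <- Mod(sum(bf$b * zw) / sum(bf$a * zw))^2
  gain <- max(abs(filt$value[mid]))
  expect_lt(abs(gain - h), 0.02)
})

test_that("forward-backward filtering is zero-phase", {
  set.seed(3)
  t <- seq(0, 300, by = 0.25)
  x <- sin(2 * pi * 0.08 * t) + rnorm(length(t), 0, 0.1)
  a <- highpass_rr(make_uniform(t, x))$value
  b <- rev(highpass_rr(make_uniform(t, rev(x)))$value)
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("EDR isolates the respiratory band of the amplitude channel", {
  tt <- cumsum(c(0, rep(0.8, 749)))
  mk <- function(f) tibble::tibble(
    time_s = tt, rr_ms = c(NA, diff(tt) * 1000),
    r_amp = 1 + 0.2 * sin(2 * pi * f * tt)
  )
  flat <- mk(0)
  out0 <- edr_series(tfhrv:::new_beat_series(flat))
  expect_lt(max(abs(out0$value)), 1e-6)

  inband <- edr_series(tfhrv:::new_beat_series(mk(0.3)))
  expect_lt(abs(periodogram_peak(inband$value, 4) - 0.3),
            4 / length(inband$value) + 1e-9)

  below <- edr_series(tfhrv:::new_beat_series(mk(0.05)))
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(below$value), 0.1 * rms(inband$value))
})
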