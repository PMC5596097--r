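# Synthetic fPCG generator: timelines, beat templates, rendering, noise.

test_that("SSID law gives the printed inter-sound distances and decreases with rate", {
  expect_equal(ssid_ms(140), 140)
  expect_equal(ssid_ms(110), 155)
  expect_equal(ssid_ms(180), 120)
  rates <- seq(80, 200, by = 5)
  expect_true(all(diff(ssid_ms(rates)) < 0))
})

test_that("timelines hold the expected cycle counts for each preset", {
  # brute-force oracle: first S1 at t0, cycle spacing 60/fhr, a beat is
  # emitted only when it fits fully before the record end
  count_oracle <- function(fhr, duration, t0, s1_dur, s2_dur) {
    s1 <- 0L; s2 <- 0L; t <- t0
    while (t + s1_dur <= duration) {
      s1 <- s1 + 1L
      if (t + ssid_ms(fhr) / 1000 + s2_dur <= duration) s2 <- s2 + 1L
      t <- t + 60 / fhr
    }
    c(s1 = s1, s2 = s2)
  }
  p <- beat_waveform_params()
  for (case in list(list("normal", 140), list("bradycardia", 110),
                    list("tachycardia", 180))) {
    tl <- build_beat_timeline(case[[1]], 10, 1000, seed = 1)
    exp_counts <- count_oracle(case[[2]], 10, 0.1, p$s1_duration, p$s2_duration)
    expect_equal(sum(tl$events$label == "S1"), unname(exp_counts["s1"]),
                 info = case[[1]])
    expect_equal(sum(tl$events$label == "S2"), unname(exp_counts["s2"]),
                 info = case[[1]])
  }
  # 140 bpm: 23 cycles -> 46 sounds; 180 bpm: 30 cycles -> 60 sounds
  expect_equal(nrow(build_beat_timeline("normal", 10, 1000)$events), 46)
  expect_equal(nrow(build_beat_timeline("tachycardia", 10, 1000)$events), 60)
})

test_that("timeline events are ordered, non-overlapping, alternating, SSID-spaced", {
  for (cond in c("normal", "bradycardia", "tachycardia", "arrhythmia")) {
    tl <- build_beat_timeline(cond, 10, 1000, seed = 7)
    ev <- tl$events
    expect_true(all(diff(ev$onset) > 0), info = cond)
    expect_true(all(ev$onset[-1] >= (ev$onset + ev$duration)[-nrow(ev)]),
                info = cond)
    expect_equal(ev$label, rep_len(c("S1", "S2"), nrow(ev)), info = cond)
    n1 <- sum(ev$label == "S1"); n2 <- sum(ev$label == "S2")
    expect_true((n1 - n2) %in% c(0L, 1L), info = cond)
    # per-cycle S1 -> S2 spacing matches the SSID of that cycle's rate
    s1_on <- ev$onset[ev$label == "S1"]
    s2_on <- ev$onset[ev$label == "S2"]
    k <- seq_along(s2_on)
    expect_equal(s2_on - s1_on[k], ssid_ms(tl$fhr_series[k]) / 1000,
                 tolerance = 1e-9, info = cond)
  }
})

test_that("arrhythmia draws per-cycle rates inside 80-200 bpm, seeded", {
  tl1 <- build_beat_timeline("arrhythmia", 10, 1000, seed = 5)
  tl2 <- build_beat_timeline("arrhythmia", 10, 1000, seed = 5)
  tl3 <- build_beat_timeline("arrhythmia", 10, 1000, seed = 6)
  expect_identical(tl1$events, tl2$events)
  expect_false(identical(tl1$events, tl3$events))
  expect_true(all(tl1$fhr_series >= 80 & tl1$fhr_series <= 200))
  expect_gt(stats::sd(tl1$fhr_series), 0)
})

test_that("too-short records raise the empty-timeline error", {
  expect_error(build_beat_timeline("normal", 0.05, 1000), "empty timeline")
})

test_that("beat templates have the configured duration, amplitude ratio and zero mean", {
  s1 <- synthesize_beat("S1", 1000)
  s2 <- synthesize_beat("S2", 1000)
  expect_length(s1, 60)
  expect_length(s2, 45)
  expect_equal(max(abs(s1)), 1.0)
  expect_equal(max(abs(s2)), 0.7)
  expect_lt(abs(sum(s1)), 0.01 * max(abs(s1)))
  expect_lt(abs(sum(s2)), 0.01 * max(abs(s2)))
  expect_error(synthesize_beat("S1", 50), "Nyquist")
  expect_error(beat_waveform_params(s2_duration = 0.08), "duration")
})

test_that("rendered clean signal is silent between beats and unit-peak", {
  tl <- build_beat_timeline("normal", 10, 1000)
  x <- render_clean_signal(tl, 1000)
  expect_length(x, 10000)
  expect_equal(max(abs(x)), 1.0)
  # zero at every sample at least 30 ms away from every beat support
  tt <- (seq_along(x) - 1) / 1000
  iv <- beat_intervals(tl)
  near <- rep(FALSE, length(x))
  for (r in seq_len(nrow(iv))) {
    near <- near | (tt >= iv$onset_s[r] - 0.03 & tt <= iv$offset_s[r] + 0.03)
  }
  expect_true(all(x[!near] == 0))
  # one burst per sound (a burst may contain exact zero crossings on the
  # sample grid, so merge sub-runs closer than 10 samples)
  runs <- wtfd:::true_runs(abs(x) > 0)
  n_bursts <- 1L + sum(runs[-1L, "start"] - runs[-nrow(runs), "end"] > 10L)
  expect_equal(n_bursts, nrow(iv))
})

test_that("clean normal-rate signal autocorrelates at the cycle lag", {
  tl <- build_beat_timeline("normal", 10, 1000)
  x <- render_clean_signal(tl, 1000)
  lag_expect <- 60 / 140 * 1000                      # 428.57 samples
  ac <- stats::acf(x, lag.max = 500, plot = FALSE)$acf[-1]
  peak_lag <- 350 + which.max(ac[351:500])
  expect_lte(abs(peak_lag - lag_expect), 1)
})

test_that("additive noise hits the requested SNR and is seed-reproducible", {
  tl <- build_beat_timeline("normal", 10, 1000)
  x <- render_clean_signal(tl, 1000)
  p_s <- mean(x^2)
  for (snr in c(8, 5, 3)) {
    nz <- add_awgn(x, snr, seed = 11)
    expect_equal(stats::var(nz$noise), p_s / 10^(snr / 10), tolerance = 0.05)
    emp <- 10 * log10(p_s / mean(nz$noise^2))
    expect_lt(abs(emp - snr), 0.3)
  }
  expect_identical(add_awgn(x, 8, seed = 3)$noise,
                   add_awgn(x, 8, seed = 3)$noise)
  expect_error(add_awgn(numeric(100), 8), "degenerate SNR")
})

test_that("simulated records are unit-peak and store a checkable SNR split", {
  for (snr in c(8, 5, 3)) {
    rec <- simulate_fpcg("normal", snr_db = snr, duration = 10, fs = 1000,
                         seed = 2)
    expect_equal(max(abs(rec$samples)), 1.0)
    expect_equal(length(rec$samples), 10000L)
    expect_equal(rec$samples, rec$clean + rec$noise)
    expect_lt(abs(empirical_snr(rec) - snr), 0.5)
  }
  clean_rec <- simulate_fpcg("normal", snr_db = NULL, seed = 2)
  expect_true(is.na(clean_rec$snr_db))
  expect_equal(clean_rec$samples, clean_rec$clean)
})
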