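# Synthetic fPCG generator: beat timelines, beat waveforms, clean rendering,
# additive white Gaussian noise at a prescribed SNR.

#' Beat waveform parameters
#'
#' Parameters of the synthetic S1/S2 beat templates. Each beat is a
#' Gaussian-windowed sinusoidal burst: S1 is the louder, sharper
#' (higher-frequency) valve sound; S2 is quieter and smoother, which is what
#' makes it the harder of the two to detect. Centre frequencies sit inside the
#' typical 20-110 Hz fetal heart-sound band.
#'
#' @param s1_duration,s2_duration Burst durations in seconds. S2 must not be
#'   longer than S1.
#' @param s1_freq,s2_freq Centre frequencies in Hz.
#' @param s1_amp,s2_amp Peak amplitudes (dimensionless). The default 0.7 ratio
#'   follows the reported mean relative amplitude of the two fetal sounds.
#' @param env_width Gaussian envelope width as a fraction of the burst
#'   duration (the envelope SD is `duration * env_width`).
#' @return A list of class `"beat_waveform_params"`.
#' @export
beat_waveform_params <- function(s1_duration = 0.060, s2_duration = 0.045,
                                 s1_freq = 45, s2_freq = 35,
                                 s1_amp = 1.0, s2_amp = 0.7,
                                 env_width = 1 / 6) {
  stopifnot(s1_duration > 0, s2_duration > 0, s1_freq > 0, s2_freq > 0,
            s1_amp > 0, s2_amp > 0, env_width > 0)
  if (s2_duration > s1_duration)
    stop("S2 duration must not exceed S1 duration", call. = FALSE)
  structure(list(s1_duration = s1_duration, s2_duration = s2_duration,
                 s1_freq = s1_freq, s2_freq = s2_freq,
                 s1_amp = s1_amp, s2_amp = s2_amp, env_width = env_width),
            class = "beat_waveform_params")
}

fhr_for_condition <- function(condition) {
  switch(condition, normal = 140, bradycardia = 110, tachycardia = 180,
         arrhythmia = NA_real_)
}

#' Inter-sound distance law
#'
#' Distance from S1 onset to S2 onset as a function of the fetal heart rate:
#' `SSID = 210 - 0.5 * fhr` milliseconds.
#'
#' @param fhr Fetal heart rate in beats per minute.
#' @return SSID in milliseconds.
#' @examples
#' ssid_ms(140)  # 140 ms
#' @export
ssid_ms <- function(fhr) 210 - 0.5 * fhr

# Timeline construction without RNG management; `draw_fhr` supplies the
# per-cycle rate (constant for the fixed presets).
build_timeline_impl <- function(condition, duration, fs, params, t0) {
  fixed <- fhr_for_condition(condition)
  events <- list()
  fhr_series <- numeric(0)
  t <- t0
  repeat {
    fhr <- if (condition == "arrhythmia") stats::runif(1, 80, 200) else fixed
    if (t + params$s1_duration > duration) break
    events[[length(events) + 1L]] <-
      data.frame(onset = t, duration = params$s1_duration, label = "S1",
                 stringsAsFactors = FALSE)
    fhr_series <- c(fhr_series, fhr)
    s2_on <- t + ssid_ms(fhr) / 1000
    if (s2_on + params$s2_duration <= duration) {
      events[[length(events) + 1L]] <-
        data.frame(onset = s2_on, duration = params$s2_duration, label = "S2",
                   stringsAsFactors = FALSE)
    }
    t <- t + 60 / fhr
  }
  if (!length(events))
    stop("empty timeline: duration too short to hold one full cycle",
         call. = FALSE)
  ev <- do.call(rbind, events)
  structure(list(events = ev, fhr_series = fhr_series,
                 total_duration = duration, fs = fs, condition = condition),
            class = "beat_timeline")
}

#' Build a ground-truth beat timeline
#'
#' Lays out S1/S2 onsets for one simulated record. Fixed presets use
#' 140 bpm (normal), 110 bpm (bradycardia) and 180 bpm (tachycardia);
#' `"arrhythmia"` redraws the instantaneous rate uniformly in 80-200 bpm for
#' every cycle. Within a cycle the S2 onset follows the S1 onset by
#' [ssid_ms()] milliseconds. The first S1 starts at `t0` (default 0.1 s) so
#' the first beat lies fully inside the record; a beat is emitted only if it
#' fits completely before `duration`.
#'
#' @param condition `"normal"`, `"bradycardia"`, `"tachycardia"` or
#'   `"arrhythmia"`.
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz (carried as metadata).
#' @param seed Integer seed for the arrhythmia rate draws.
#' @param params [beat_waveform_params()].
#' @param t0 Onset of the first S1 in seconds.
#' @return A `"beat_timeline"`: list with `events` (data.frame
#'   `onset`/`duration`/`label`), `fhr_series` (per-cycle bpm),
#'   `total_duration`, `fs`, `condition`.
#' @examples
#' tl <- build_beat_timeline("normal", 10, 1000, seed = 1)
#' table(tl$events$label)
#' @export
build_beat_timeline <- function(condition = c("normal", "bradycardia",
                                              "tachycardia", "arrhythmia"),
                                duration, fs, seed = 1L,
                                params = beat_waveform_params(), t0 = 0.1) {
  condition <- match.arg(condition)
  stopifnot(duration > 0, fs > 0)
  with_seed(seed, build_timeline_impl(condition, duration, fs, params, t0))
}

#' @export
print.beat_timeline <- function(x, ...) {
  cat("<beat_timeline> ", x$condition, ", ", x$total_duration, " s, ",
      nrow(x$events), " sounds (",
      sum(x$events$label == "S1"), " S1 / ",
      sum(x$events$label == "S2"), " S2)\n", sep = "")
  invisible(x)
}

#' Ground-truth sound intervals of a timeline
#'
#' @param timeline A `"beat_timeline"`.
#' @return A data.frame with columns `onset_s`, `offset_s`, `label`, one row
#'   per sound, suitable for [match_detections()] and [write_annotations()].
#' @export
beat_intervals <- function(timeline) {
  stopifnot(inherits(timeline, "beat_timeline"))
  ev <- timeline$events
  data.frame(onset_s = ev$onset, offset_s = ev$onset + ev$duration,
             label = ev$label, stringsAsFactors = FALSE)
}

#' Synthesize one heart-sound burst
#'
#' Returns a Gaussian-windowed sinusoid of the configured duration, centred in
#' its support, anti-symmetric about its centre (hence zero-mean), with peak
#' absolute amplitude equal to the configured S1 or S2 amplitude.
#'
#' @param label `"S1"` or `"S2"`.
#' @param fs Sampling rate in Hz.
#' @param params [beat_waveform_params()].
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
synthesize_beat <- function(label = c("S1", "S2"), fs,
                            params = beat_waveform_params()) {
  label <- match.arg(label)
  dur <- if (label == "S1") params$s1_duration else params$s2_duration
  f0 <- if (label == "S1") params$s1_freq else params$s2_freq
  amp <- if (label == "S1") params$s1_amp else params$s2_amp
  if (f0 >= fs / 2)
    stop("sampling rate too low for the beat centre frequency (Nyquist)",
         call. = FALSE)
  n <- max(3L, as.integer(round(dur * fs)))
  tt <- (seq_len(n) - 1) / fs
  tc <- (n - 1) / (2 * fs)
  env <- exp(-0.5 * ((tt - tc) / (dur * params$env_width))^2)
  y <- env * sin(2 * pi * f0 * (tt - tc))
  amp * y / max(abs(y))
}

#' Render a clean fPCG signal from a timeline
#'
#' Places one synthetic burst per timeline event at its onset over silence and
#' normalizes the result to unit peak amplitude. Overlapping beats (possible
#' only under pathological waveform parameters) are summed with a warning.
#'
#' @param timeline A `"beat_timeline"`.
#' @param fs Sampling rate in Hz.
#' @param params [beat_waveform_params()].
#' @return Numeric vector of `round(total_duration * fs)` samples with
#'   `max(abs(.)) == 1`.
#' @export
render_clean_signal <- function(timeline, fs,
                                params = beat_waveform_params()) {
  stopifnot(inherits(timeline, "beat_timeline"))
  ev <- timeline$events
  if (!nrow(ev)) stop("empty timeline", call. = FALSE)
  n <- as.integer(round(timeline$total_duration * fs))
  x <- numeric(n)
  occupied <- logical(n)
  overlap <- FALSE
  waves <- list(S1 = synthesize_beat("S1", fs, params),
                S2 = synthesize_beat("S2", fs, params))
  for (r in seq_len(nrow(ev))) {
    w <- waves[[ev$label[r]]]
    i0 <- as.integer(round(ev$onset[r] * fs)) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    keep <- idx >= 1L & idx <= n
    if (any(occupied[idx[keep]])) overlap <- TRUE
    x[idx[keep]] <- x[idx[keep]] + w[keep]
    occupied[idx[keep]] <- TRUE
  }
  if (overlap) warning("overlapping beats were summed")
  x / max(abs(x))
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' The noise variance is `P_s / 10^(snr_db / 10)` where `P_s` is the mean
#' squared amplitude of `clean`, so that the expected signal-to-noise ratio of
#' the sum is `snr_db` decibels.
#'
#' @param clean Clean signal (nonzero power).
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed; the same seed yields bit-identical noise.
#' @return List with elements `noisy` (`clean + noise`) and `noise`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, by = 1e-3))
#' nz <- add_awgn(x, snr_db = 8, seed = 42)
#' 10 * log10(mean(x^2) / mean(nz$noise^2))  # close to 8
#' @export
add_awgn <- function(clean, snr_db, seed = 1L) {
  p_s <- mean(clean^2)
  if (p_s == 0) stop("degenerate SNR: clean signal has zero power",
                     call. = FALSE)
  sigma <- sqrt(p_s / 10^(snr_db / 10))
  noise <- with_seed(seed, sigma * stats::rnorm(length(clean)))
  list(noisy = clean + noise, noise = noise)
}

#' Simulate a complete fPCG record
#'
#' Builds a ground-truth timeline, renders the clean signal, optionally adds
#' white Gaussian noise at `snr_db`, and normalizes the mixture to unit peak
#' amplitude. The clean and noise parts are stored (under the same
#' normalization) so the empirical SNR of the record remains checkable.
#' All randomness (arrhythmia rate draws, noise) flows from `seed`.
#'
#' @param condition Heart-rate condition, see [build_beat_timeline()].
#' @param snr_db Target SNR in dB, or `NULL` for a noise-free record.
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param params [beat_waveform_params()].
#' @param t0 Onset of the first S1 in seconds.
#' @return An `"fpcg_record"`: list with `samples` (unit-peak mixture),
#'   `clean`, `noise`, `fs`, `truth` (the `"beat_timeline"`), `snr_db`,
#'   `condition`, `seed`.
#' @examples
#' rec <- simulate_fpcg("normal", snr_db = 8, duration = 10, fs = 1000, seed = 1)
#' rec
#' @export
simulate_fpcg <- function(condition = c("normal", "bradycardia",
                                        "tachycardia", "arrhythmia"),
                          snr_db = 8, duration = 10, fs = 1000, seed = 1L,
                          params = beat_waveform_params(), t0 = 0.1) {
  condition <- match.arg(condition)
  stopifnot(duration > 0, fs > 0)
  out <- with_seed(seed, {
    tl <- build_timeline_impl(condition, duration, fs, params, t0)
    clean <- render_clean_signal(tl, fs, params)
    if (is.null(snr_db)) {
      list(tl = tl, clean = clean, noise = numeric(length(clean)),
           noisy = clean)
    } else {
      p_s <- mean(clean^2)
      sigma <- sqrt(p_s / 10^(snr_db / 10))
      noise <- sigma * stats::rnorm(length(clean))
      list(tl = tl, clean = clean, noise = noise, noisy = clean + noise)
    }
  })
  m <- max(abs(out$noisy))
  structure(list(samples = out$noisy / m, clean = out$clean / m,
                 noise = out$noise / m, fs = fs, truth = out$tl,
                 snr_db = if (is.null(snr_db)) NA_real_ else snr_db,
                 condition = condition, seed = as.integer(seed)),
            class = "fpcg_record")
}

#' @export
print.fpcg_record <- function(x, ...) {
  cat("<fpcg_record> ", length(x$samples), " samples @ ", x$fs, " Hz (",
      round(length(x$samples) / x$fs, 3), " s)", sep = "")
  if (!is.null(x$condition)) cat(", condition:", x$condition)
  if (!is.na(x$snr_db)) cat(", SNR:", x$snr_db, "dB")
  if (!is.null(x$truth)) cat(",", nrow(x$truth$events), "true sounds")
  cat("\n")
  invisible(x)
}

#' Empirical SNR of a simulated record
#'
#' @param record An `"fpcg_record"` with stored clean and noise parts.
#' @return `10 * log10(P_s / P_n)` in dB (`NA` for noise-free records).
#' @export
empirical_snr <- function(record) {
  stopifnot(inherits(record, "fpcg_record"))
  p_n <- mean(record$noise^2)
  if (p_n == 0) return(NA_real_)
  10 * log10(mean(record$clean^2) / p_n)
}
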