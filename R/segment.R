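# Segmentation: turn the per-level/per-iteration signal masks into sound
# intervals, label each interval S1 or S2 from the systolic/diastolic gap
# asymmetry plus amplitude and cycle-distance criteria, and estimate the
# fetal heart rate.

#' Extract sound intervals from the signal masks
#'
#' Takes the per-sample logical OR of the signal masks across all selected
#' levels and outer iterations, turns runs of 1 into intervals, and merges
#' runs separated by fewer than `int(merge_gap_coeff * fs)` samples (gaps far
#' shorter than any physiological systolic pause are mask fragmentation, not
#' separate sounds).
#'
#' @param masks A `"wtfd_result"`, or a list of 0/1 vectors / `"binary_masks"`
#'   (at least one).
#' @param fs Sampling rate in Hz (taken from the result when given).
#' @param merge_gap_coeff Gap-merging coefficient (default 0.015).
#' @return A data.frame of class `"s_vector"` with columns `start`, `end`
#'   (1-based sample indices, inclusive); zero rows when nothing was
#'   detected. The flat boundary vector of the source notation is
#'   `as.vector(t(as.matrix(df)))`.
#' @export
extract_intervals <- function(masks, fs = NULL, merge_gap_coeff = 0.015) {
  if (inherits(masks, "wtfd_result")) {
    fs <- fs %||% masks$fs
    flat <- list()
    for (it in masks$masks_per_iter) {
      for (mk in it) flat[[length(flat) + 1L]] <- mk
    }
    masks <- flat
  }
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  if (!length(masks))
    stop("at least one mask is required", call. = FALSE)
  vecs <- lapply(masks, function(m) {
    if (inherits(m, "binary_masks")) m <- m$sbth
    as.numeric(m)
  })
  n <- unique(lengths(vecs))
  if (length(n) != 1L) stop("mask length mismatch", call. = FALSE)
  union <- Reduce(`+`, vecs) > 0

  runs <- true_runs(union)
  out <- data.frame(start = integer(0), end = integer(0))
  if (nrow(runs)) {
    min_gap <- int_trunc(merge_gap_coeff * fs)
    merged <- list(c(runs[1L, "start"], runs[1L, "end"]))
    if (nrow(runs) > 1L) {
      for (r in 2L:nrow(runs)) {
        last <- merged[[length(merged)]]
        if (runs[r, "start"] - last[2L] - 1L < min_gap) {
          merged[[length(merged)]][2L] <- runs[r, "end"]
        } else {
          merged[[length(merged) + 1L]] <- c(runs[r, "start"], runs[r, "end"])
        }
      }
    }
    mm <- do.call(rbind, merged)
    out <- data.frame(start = as.integer(mm[, 1L]), end = as.integer(mm[, 2L]))
  }
  structure(out, class = c("s_vector", "data.frame"), fs = fs)
}

#' Label detected sounds as S1 or S2
#'
#' Labels each detected interval using the asymmetry of the cardiac cycle:
#' the systolic pause (S1 to S2) is shorter than the diastolic pause (S2 to
#' the next S1), so a sound whose preceding gap is strictly shorter than its
#' following gap is an S2, otherwise an S1. The first and last sounds, which
#' lack one of the two gaps, take the label complementary to their neighbour
#' (flagged when the neighbour decision itself came out S1-first-reversed).
#' Two auxiliary criteria refine the decision: an S1 must reach a peak
#' amplitude above `s1_min_amp` on the unit-normalized de-noised signal
#' (sounds failing it are relabelled S2 and flagged), and the pause from an
#' S2 to the following S1 must exceed `min_cycle_gap_ms`; pairs violating it
#' are swapped when the swap satisfies both rules, otherwise flagged
#' `"ambiguous"`. Gap ties fall through to the amplitude rule (flagged
#' `"tie"`).
#'
#' @param s An `"s_vector"` from [extract_intervals()] (or a data.frame with
#'   `start`/`end` sample columns).
#' @param x_rec The de-noised signal the intervals refer to; normalized to
#'   unit peak internally.
#' @param fs Sampling rate in Hz.
#' @param s1_min_amp Minimum S1 peak amplitude (default 0.5).
#' @param min_cycle_gap_ms Minimum S2-to-S1 pause in ms (default 130).
#' @return A data.frame of class `"labeled_sounds"` with columns `start`,
#'   `end`, `label`, `peak_sample`, `peak_amp`, `flag`.
#' @export
classify_s1_s2 <- function(s, x_rec, fs = NULL, s1_min_amp = 0.5,
                           min_cycle_gap_ms = 130) {
  fs <- fs %||% attr(s, "fs")
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  n <- nrow(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      label = character(0), peak_sample = integer(0),
                      peak_amp = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE)
  if (!n) return(structure(empty, class = c("labeled_sounds", "data.frame"),
                           fs = fs))
  peak <- max(abs(x_rec))
  if (peak > 0) x_rec <- x_rec / peak

  peak_sample <- integer(n)
  peak_amp <- numeric(n)
  for (i in seq_len(n)) {
    idx <- s$start[i]:s$end[i]
    peak_sample[i] <- idx[which.max(abs(x_rec[idx]))]
    peak_amp[i] <- max(abs(x_rec[idx]))
  }

  label <- rep(NA_character_, n)
  flag <- rep("", n)

  if (n < 3L) {
    label <- ifelse(peak_amp > s1_min_amp, "S1", "S2")
    flag <- rep("short_record", n)
  } else {
    gaps <- s$start[-1L] - s$end[-n]  # gap i: between sound i and i+1
    for (i in seq_len(n - 2L)) {      # labels sound i+1
      if (gaps[i] < gaps[i + 1L]) {
        label[i + 1L] <- "S2"
      } else if (gaps[i] > gaps[i + 1L]) {
        label[i + 1L] <- "S1"
      } else {
        label[i + 1L] <- if (peak_amp[i + 1L] > s1_min_amp) "S1" else "S2"
        flag[i + 1L] <- "tie"
      }
    }
    label[1L] <- if (label[2L] == "S2") "S1" else "S2"
    if (label[2L] == "S1") flag[1L] <- "first_by_complement"
    label[n] <- if (label[n - 1L] == "S2") "S1" else "S2"
    if (label[n - 1L] == "S1") flag[n] <- "last_by_complement"

    # Amplitude criterion: an S1 must surpass s1_min_amp.
    weak_s1 <- label == "S1" & peak_amp <= s1_min_amp
    label[weak_s1] <- "S2"
    flag[weak_s1] <- paste0(flag[weak_s1],
                            ifelse(nzchar(flag[weak_s1]), ";", ""),
                            "amp_relabel")

    # Cycle-distance criterion: S2 -> next S1 pause must exceed the
    # tachycardia floor. Violating pairs are swapped when the swap also
    # satisfies the amplitude rule, else flagged ambiguous.
    min_gap <- min_cycle_gap_ms / 1000 * fs
    for (i in seq_len(n - 1L)) {
      if (label[i] == "S2" && label[i + 1L] == "S1" && gaps[i] <= min_gap) {
        if (peak_amp[i] > s1_min_amp && peak_amp[i + 1L] <= s1_min_amp) {
          label[i] <- "S1"
          label[i + 1L] <- "S2"
          flag[i] <- paste0(flag[i], ifelse(nzchar(flag[i]), ";", ""),
                            "cycle_swap")
        } else {
          flag[i + 1L] <- paste0(flag[i + 1L],
                                 ifelse(nzchar(flag[i + 1L]), ";", ""),
                                 "ambiguous")
        }
      }
    }
  }

  structure(data.frame(start = s$start, end = s$end, label = label,
                       peak_sample = peak_sample, peak_amp = peak_amp,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("labeled_sounds", "data.frame"), fs = fs)
}

#' Estimate the fetal heart rate
#'
#' `60 / median(S1-onset-to-S1-onset spacing in seconds)` beats per minute.
#'
#' @param labeled A `"labeled_sounds"` data.frame.
#' @param fs Sampling rate in Hz.
#' @return Heart rate in bpm.
#' @export
estimate_fhr <- function(labeled, fs = NULL) {
  fs <- fs %||% attr(labeled, "fs")
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  onsets <- labeled$start[labeled$label == "S1"]
  if (length(onsets) < 2L)
    stop("at least 2 S1 sounds are required to estimate the heart rate",
         call. = FALSE)
  60 / stats::median(diff(onsets) / fs)
}

#' End-to-end detection on one record
#'
#' Convenience wrapper: de-noises the signal with [wtfd_denoise()], extracts
#' and labels the sound intervals, and estimates the heart rate.
#'
#' @param x An `"fpcg_record"` or a numeric signal.
#' @param fs Sampling rate in Hz (taken from the record when given).
#' @param config A [wtfd_config()].
#' @return An `"fhs_detection"`: list with `sounds` (a `"labeled_sounds"`
#'   data.frame), `fhr_bpm` (`NA` when fewer than two S1s were found),
#'   `denoised` (the `"wtfd_result"`), `fs`.
#' @examples
#' rec <- simulate_fpcg("normal", snr_db = 8, duration = 4, fs = 1000, seed = 1)
#' det <- detect_fhs(rec)
#' det$sounds[, c("start", "end", "label")]
#' @export
detect_fhs <- function(x, fs = NULL, config = wtfd_config()) {
  if (inherits(x, "fpcg_record")) fs <- x$fs
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  res <- wtfd_denoise(x, fs, config)
  s <- extract_intervals(res, merge_gap_coeff = config$segmentation$merge_gap_coeff)
  sounds <- classify_s1_s2(s, res$x_rec, fs,
                           s1_min_amp = config$segmentation$s1_min_amp,
                           min_cycle_gap_ms = config$segmentation$min_cycle_gap_ms)
  fhr <- if (sum(sounds$label == "S1") >= 2L) estimate_fhr(sounds, fs)
         else NA_real_
  structure(list(sounds = sounds, fhr_bpm = fhr, denoised = res, fs = fs),
            class = "fhs_detection")
}

#' @export
print.fhs_detection <- function(x, ...) {
  cat("<fhs_detection> ", nrow(x$sounds), " sounds (",
      sum(x$sounds$label == "S1"), " S1 / ",
      sum(x$sounds$label == "S2"), " S2)", sep = "")
  if (!is.na(x$fhr_bpm)) cat(", fHR ", round(x$fhr_bpm, 1), " bpm", sep = "")
  cat("\n")
  invisible(x)
}

#' Detected sounds as a time annotation table
#'
#' @param detection An `"fhs_detection"` or `"labeled_sounds"` object.
#' @param fs Sampling rate in Hz.
#' @return A data.frame `onset_s`, `offset_s`, `label` on the same schema as
#'   [beat_intervals()], enabling direct diffing against ground truth.
#' @export
detection_intervals <- function(detection, fs = NULL) {
  if (inherits(detection, "fhs_detection")) {
    fs <- detection$fs
    detection <- detection$sounds
  }
  fs <- fs %||% attr(detection, "fs")
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  data.frame(onset_s = (detection$start - 1L) / fs,
             offset_s = (detection$end - 1L) / fs,
             label = detection$label, stringsAsFactors = FALSE)
}
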