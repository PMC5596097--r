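# Detection scoring: match detected sounds to ground-truth intervals and
# compute the Q_P / D_R / S_F performance indices.

#' Detection counts
#'
#' @param s_o Number of true sounds.
#' @param s_p Number of detected sounds.
#' @param s_c Number of detected sounds matching a true sound
#'   (`0 <= s_c <= min(s_o, s_p)`).
#' @return A `"detection_counts"` list.
#' @export
detection_counts <- function(s_o, s_p, s_c) {
  stopifnot(s_o >= 0, s_p >= 0, s_c >= 0, s_c <= min(s_o, s_p))
  structure(list(s_o = as.integer(s_o), s_p = as.integer(s_p),
                 s_c = as.integer(s_c)), class = "detection_counts")
}

#' @export
print.detection_counts <- function(x, ...) {
  cat("<detection_counts> true:", x$s_o, " detected:", x$s_p,
      " correct:", x$s_c, "\n")
  invisible(x)
}

#' Match detections to ground truth
#'
#' A detection is counted correct when its peak time lies inside a true
#' sound's `[onset, offset]` interval (of the matching class when
#' `class_filter` is `"S1"` or `"S2"`). Each true sound can absorb at most
#' one detection; matching is greedy in time order, so a second detection
#' inside an already-matched interval counts as false.
#'
#' @param truth Ground truth: a `"beat_timeline"`, or a data.frame with
#'   `onset_s`, `offset_s`, `label` columns (see [beat_intervals()]).
#' @param detected Detections: an `"fhs_detection"`, a `"labeled_sounds"`
#'   data.frame (peak times are taken from `peak_sample`), or a data.frame
#'   with a `peak_s` column (and `label` when class filtering).
#' @param class_filter `"both"`, `"S1"` or `"S2"`; filters both sides.
#' @param fs Sampling rate in Hz (needed to convert `peak_sample` to
#'   seconds; taken from the detection object when available).
#' @return A `"detection_counts"`.
#' @export
match_detections <- function(truth, detected,
                             class_filter = c("both", "S1", "S2"),
                             fs = NULL) {
  class_filter <- match.arg(class_filter)
  if (inherits(truth, "beat_timeline")) truth <- beat_intervals(truth)
  if (inherits(detected, "fhs_detection")) {
    fs <- fs %||% detected$fs
    detected <- detected$sounds
  }
  fs <- fs %||% attr(detected, "fs")

  if (!"peak_s" %in% names(detected)) {
    if (is.null(fs))
      stop("fs is required to convert peak samples to seconds", call. = FALSE)
    detected$peak_s <- (detected$peak_sample - 1L) / fs
  }
  if (class_filter != "both") {
    truth <- truth[truth$label == class_filter, , drop = FALSE]
    detected <- detected[detected$label == class_filter, , drop = FALSE]
  }
  s_o <- nrow(truth)
  s_p <- nrow(detected)
  if (!s_o || !s_p) return(detection_counts(s_o, s_p, 0L))

  truth <- truth[order(truth$onset_s), , drop = FALSE]
  detected <- detected[order(detected$peak_s), , drop = FALSE]
  matched <- logical(s_o)
  s_c <- 0L
  for (i in seq_len(s_p)) {
    p <- detected$peak_s[i]
    hit <- which(!matched & truth$onset_s <= p & p <= truth$offset_s)
    if (length(hit)) {
      matched[hit[1L]] <- TRUE
      s_c <- s_c + 1L
    }
  }
  detection_counts(s_o, s_p, s_c)
}

#' Detection-performance indices
#'
#' * `compute_qp()`: overall accuracy
#'   `Q_P = 100 * S_C / sqrt(S_O * S_P)`, the geometric mean of precision and
#'   sensitivity — 100 iff every true sound was detected exactly once with no
#'   extras.
#' * `compute_dr()`: precision `D_R = 100 * S_C / S_P`, the share of
#'   detections that hit a real sound.
#' * `compute_sf()`: sensitivity `S_F = 100 * S_C / S_O`, the share of real
#'   sounds that were found.
#'
#' Zero denominators yield 0 with a warning (0 without a warning when
#' `s_c = 0`, where the limit is unambiguous).
#'
#' @param counts A `"detection_counts"` (or list with `s_o`, `s_p`, `s_c`).
#' @return Percentage in `[0, 100]`.
#' @examples
#' compute_qp(detection_counts(s_o = 15, s_p = 4, s_c = 3))   # 38.7
#' compute_qp(detection_counts(s_o = 15, s_p = 19, s_c = 9))  # 53.3
#' @export
compute_qp <- function(counts) {
  if (counts$s_c == 0) return(0)
  if (counts$s_o == 0 || counts$s_p == 0) {
    warning("zero denominator in Q_P")
    return(0)
  }
  100 * counts$s_c / sqrt(as.numeric(counts$s_o) * as.numeric(counts$s_p))
}

#' @rdname compute_qp
#' @export
compute_dr <- function(counts) {
  if (counts$s_p == 0) {
    if (counts$s_c > 0) warning("zero denominator in D_R")
    return(0)
  }
  100 * counts$s_c / counts$s_p
}

#' @rdname compute_qp
#' @export
compute_sf <- function(counts) {
  if (counts$s_o == 0) {
    if (counts$s_c > 0) warning("zero denominator in S_F")
    return(0)
  }
  100 * counts$s_c / counts$s_o
}

#' Benchmark the pipeline on simulated records
#'
#' Generates seeded records for every (condition, SNR) pair, runs the full
#' detection pipeline, and scores combined, S1-only and S2-only detection
#' against the generator's ground truth.
#'
#' @param conditions Character vector of conditions (see [simulate_fpcg()]).
#' @param snrs Numeric vector of SNRs in dB.
#' @param n_seeds Records per (condition, SNR) cell.
#' @param duration,fs Record length (s) and sampling rate (Hz).
#' @param config A [wtfd_config()].
#' @param base_seed Base of the per-record seed sequence.
#' @param params [beat_waveform_params()].
#' @return A data.frame with one row per (condition, snr, seed, class):
#'   columns `condition`, `snr_db`, `seed`, `class`, `s_o`, `s_p`, `s_c`,
#'   `qp`, `dr`, `sf`.
#' @seealso [benchmark_summary()] for the per-cell mean table.
#' @export
run_benchmark <- function(conditions = c("normal", "bradycardia",
                                         "tachycardia", "arrhythmia"),
                          snrs = c(8, 5, 3), n_seeds = 10,
                          duration = 10, fs = 1000,
                          config = wtfd_config(), base_seed = 1L,
                          params = beat_waveform_params()) {
  rows <- list()
  i <- 0L
  for (cond in conditions) {
    for (snr in snrs) {
      for (s in seq_len(n_seeds)) {
        i <- i + 1L
        seed <- as.integer(base_seed) + 1009L * i
        rec <- simulate_fpcg(cond, snr_db = snr, duration = duration,
                             fs = fs, seed = seed, params = params)
        det <- detect_fhs(rec, config = config)
        for (cls in c("both", "S1", "S2")) {
          cnt <- match_detections(rec$truth, det, class_filter = cls)
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, snr_db = snr, seed = seed, class = cls,
            s_o = cnt$s_o, s_p = cnt$s_p, s_c = cnt$s_c,
            qp = compute_qp(cnt), dr = compute_dr(cnt), sf = compute_sf(cnt),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark as a per-cell mean table
#'
#' Averages the indices over seeds and reshapes into one row per
#' (condition, SNR) with combined / S1 / S2 blocks of `Q_P`, `D_R`, `S_F`,
#' rounded to one decimal.
#'
#' @param bench Output of [run_benchmark()].
#' @return A data.frame with columns `condition`, `snr_db`, then
#'   `qp`/`dr`/`sf` for `both`, `s1`, `s2`.
#' @export
benchmark_summary <- function(bench) {
  cells <- unique(bench[, c("condition", "snr_db")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    cond <- cells$condition[r]
    snr <- cells$snr_db[r]
    row <- list(condition = cond, snr_db = snr)
    for (cls in c("both", "S1", "S2")) {
      sub <- bench[bench$condition == cond & bench$snr_db == snr &
                     bench$class == cls, , drop = FALSE]
      suff <- tolower(cls)
      row[[paste0("qp_", suff)]] <- round(mean(sub$qp), 1)
      row[[paste0("dr_", suff)]] <- round(mean(sub$dr), 1)
      row[[paste0("sf_", suff)]] <- round(mean(sub$sf), 1)
    }
    out[[r]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
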