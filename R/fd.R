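# Katz fractal dimension, its sliding-window trace, the iterative peak-peeling
# algorithm (FD-PPA) with epoching, small-peak pruning, and the complementary
# signal/noise binary masks.

#' Katz fractal dimension of a sampled curve
#'
#' Treats the input as the ordinates of a planar curve sampled at unit
#' abscissa spacing and evaluates Katz's estimator
#' `FD = log10(n_s) / (log10(d / L_c) + log10(n_s))`, where `L_c` is the
#' total path length (sum of successive point distances), `d` is the curve
#' diameter taken as the largest distance from the first point, and
#' `n_s = L_c / alpha` is the number of steps with `alpha` the mean step
#' length — so `n_s` equals the number of segments. A straight segment
#' (`d == L_c`) returns exactly 1, the estimator's lower bound; a constant
#' (zero-length) window returns 1 as its defined limit.
#'
#' Katz's estimator is not scale-invariant, so the abscissa convention (unit
#' sample spacing, amplitudes used as stored) is fixed and shared with
#' [sliding_fd()].
#'
#' @param y Numeric vector of at least 3 ordinates.
#' @return Scalar `FD >= 1`.
#' @examples
#' katz_fd(seq(0, 1, length.out = 50))   # straight line -> 1
#' katz_fd(c(0, 1, 0, 1, 0))             # zigzag -> ~1.333
#' @export
katz_fd <- function(y) {
  n <- length(y)
  if (n < 3L) stop("at least 3 points are required", call. = FALSE)
  dy <- diff(y)
  lc <- sum(sqrt(1 + dy * dy))
  if (lc == 0) return(1)
  dx <- seq_len(n - 1L)
  dev <- y[-1L] - y[1L]
  d <- max(sqrt(dx * dx + dev * dev))
  if (d >= lc) return(1)  # equality holds iff the segment is straight
  ns <- n - 1L
  log10(ns) / (log10(d / lc) + log10(ns))
}

#' Sliding-window fractal dimension trace
#'
#' Slides a `W = int(window_coeff * fs)`-sample window one sample at a time
#' along the input, evaluates [katz_fd()] in each window, and assigns the
#' value to the window midpoint. The `W - 1` missing edge values are filled
#' with the first and last estimates: the leading `ceiling((W-1)/2)` samples
#' take `FD(1)` and the trailing `floor((W-1)/2)` take `FD(N - W + 1)`, so
#' the trace has the full input length.
#'
#' @param level Numeric signal (one wavelet detail level).
#' @param fs Sampling rate in Hz.
#' @param window_coeff Window-length coefficient (default 0.05, i.e. 50
#'   samples at 1 kHz).
#' @return An `"fd_sequence"`: list with `values` (length `N` trace, all
#'   `>= 1`), `window`, `fs`.
#' @export
sliding_fd <- function(level, fs, window_coeff = 0.05) {
  n <- length(level)
  w <- int_trunc(window_coeff * fs)
  if (w < 3L) stop("window too short (need int(window_coeff * fs) >= 3)",
                   call. = FALSE)
  if (n <= w) stop("window exceeds signal", call. = FALSE)
  n_win <- n - w + 1L

  steps <- sqrt(1 + diff(level)^2)
  cs <- c(0, cumsum(steps))
  t0 <- seq_len(n_win)
  lc <- cs[t0 + w - 1L] - cs[t0]          # path length per window

  d <- numeric(n_win)                     # max distance from first point
  for (k in seq_len(w - 1L)) {
    dk <- sqrt(k * k + (level[t0 + k] - level[t0])^2)
    d <- pmax(d, dk)
  }

  ns <- w - 1L
  fd <- rep(1, n_win)
  curved <- d < lc & lc > 0
  fd[curved] <- log10(ns) / (log10(d[curved] / lc[curved]) + log10(ns))

  head_fill <- as.integer(ceiling((w - 1L) / 2))
  tail_fill <- (w - 1L) - head_fill
  values <- c(rep(fd[1L], head_fill), fd, rep(fd[n_win], tail_fill))
  structure(list(values = values, window = w, fs = fs),
            class = "fd_sequence")
}

# One epoch of the peak-peeling iteration. Returns the accumulated peeled
# trace (baseline exactly 1) and the number of inner iterations.
fd_ppa_epoch <- function(v, acc, max_inner) {
  l1 <- 0L
  acc_pfd <- numeric(length(v))
  e_prev <- 0
  cur <- v
  repeat {
    mu <- mean(cur)
    sdv <- stats::sd(cur)
    above <- cur > mu + sdv
    pfd <- rep(1, length(cur))
    pfd[above] <- cur[above]
    l1 <- l1 + 1L
    acc_pfd <- acc_pfd + pfd
    if (!any(above)) break  # peeling set is a fixed point: nothing to peel
    z <- cur - pfd + mu
    e_z <- mean(z * z)
    if (abs(e_z - e_prev) < acc) break
    if (l1 >= max_inner) {
      warning("FD-PPA did not converge within ", max_inner,
              " inner iterations; using the accumulated result")
      break
    }
    e_prev <- e_z
    cur <- z
  }
  list(fdpp = acc_pfd - (l1 - 1L), n_inner = l1)
}

#' Fractal-dimension peak peeling (FD-PPA)
#'
#' Splits the trace into consecutive epochs of roughly `epoch_ms`
#' milliseconds (the last epoch absorbs the remainder) and, independently in
#' each epoch, iteratively peels the trace: values above `mean + sd` are
#' gathered as peaks and replaced by the epoch mean, and the iteration stops
#' when the residual energy stabilizes to within `acc` (or when nothing
#' exceeds the threshold). The per-iteration peak layers are accumulated into
#' a peeled trace whose baseline is exactly 1 and which exceeds 1 exactly on
#' peak supports. Epoching keeps the thresholds local, so a faint peak (an S2
#' beat) in a quiet epoch is retained even when it sits far below the peaks
#' of a louder epoch; the default 430 ms matches one fetal cardiac cycle so
#' each epoch holds about one S1 and one S2.
#'
#' @param fd An `"fd_sequence"` from [sliding_fd()] (or a plain numeric
#'   trace).
#' @param fs Sampling rate in Hz (taken from `fd` when available).
#' @param epoch_ms Epoch length in milliseconds (>= 100).
#' @param acc Inner stopping accuracy (default 1e-5).
#' @param max_inner Iteration cap per epoch (default 50).
#' @return An `"fd_pp_result"`: list with `fdpp` (peeled trace, length `N`),
#'   `n_inner` (iterations per epoch), `epochs` (start/end sample matrix),
#'   `fs`.
#' @export
fd_ppa <- function(fd, fs = NULL, epoch_ms = 430, acc = 1e-5,
                   max_inner = 50L) {
  if (inherits(fd, "fd_sequence")) {
    fs <- fs %||% fd$fs
    v <- fd$values
  } else {
    v <- as.numeric(fd)
  }
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  if (epoch_ms < 100) stop("epoch_ms must be at least 100", call. = FALSE)
  n <- length(v)
  ep_len <- max(2L, as.integer(round(epoch_ms / 1000 * fs)))
  n_ep <- max(1L, n %/% ep_len)
  starts <- (seq_len(n_ep) - 1L) * ep_len + 1L
  ends <- c(starts[-1L] - 1L, n)   # last epoch absorbs the remainder

  fdpp <- numeric(n)
  n_inner <- integer(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- starts[e]:ends[e]
    res <- fd_ppa_epoch(v[idx], acc, max_inner)
    fdpp[idx] <- res$fdpp
    n_inner[e] <- res$n_inner
  }
  structure(list(fdpp = fdpp, n_inner = n_inner,
                 epochs = cbind(start = starts, end = ends), fs = fs),
            class = "fd_pp_result")
}

#' Prune small fractal peaks
#'
#' Removes (resets to the baseline 1) peeled-trace peaks that do not plausibly
#' correspond to a heart sound. A contiguous peak (run of `fdpp > 1`) is
#' tested against two clauses: duration shorter than `int(min_dur_coeff *
#' fs)` samples, and maximum absolute level amplitude under its support below
#' `min_amp` (relative to the unit-peak normalization of the record). With
#' `mode = "or"` (the default) a peak failing either clause is removed, i.e.
#' only peaks that are both long enough and strong enough survive; with
#' `mode = "and"` a peak is removed only when it fails both.
#'
#' @param fdpp An `"fd_pp_result"` from [fd_ppa()].
#' @param level The wavelet detail level the trace was computed from.
#' @param fs Sampling rate in Hz.
#' @param min_dur_coeff Duration coefficient (default 0.015, i.e. 15 samples
#'   at 1 kHz).
#' @param min_amp Amplitude threshold (default 0.25).
#' @param mode `"or"` or `"and"` (see above).
#' @return The pruned `"fd_pp_result"`.
#' @export
prune_small_peaks <- function(fdpp, level, fs = NULL,
                              min_dur_coeff = 0.015, min_amp = 0.25,
                              mode = c("or", "and")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fdpp, "fd_pp_result"))
  fs <- fs %||% fdpp$fs
  stopifnot(length(level) == length(fdpp$fdpp))
  min_dur <- int_trunc(min_dur_coeff * fs)
  runs <- true_runs(fdpp$fdpp > 1)
  if (!nrow(runs)) return(fdpp)
  out <- fdpp$fdpp
  for (r in seq_len(nrow(runs))) {
    idx <- runs[r, "start"]:runs[r, "end"]
    short <- length(idx) < min_dur
    weak <- max(abs(level[idx])) < min_amp
    drop <- if (mode == "and") short && weak else short || weak
    if (drop) out[idx] <- 1
  }
  fdpp$fdpp <- out
  fdpp
}

#' Complementary signal/noise binary masks
#'
#' The signal mask `sbth` is 1 exactly where the peeled trace departs from
#' its baseline (`fdpp != 1`), i.e. on detected sound supports, and the noise
#' mask is its complement `nbth = 1 - sbth`. Multiplying a detail level by
#' `sbth` keeps its transient (sound-bearing) content; multiplying by `nbth`
#' keeps the stationary background.
#'
#' @param fdpp An `"fd_pp_result"` (after pruning).
#' @return A `"binary_masks"`: list with 0/1 vectors `sbth` and `nbth`.
#' @export
build_masks <- function(fdpp) {
  stopifnot(inherits(fdpp, "fd_pp_result"))
  sbth <- as.numeric(fdpp$fdpp != 1)
  structure(list(sbth = sbth, nbth = 1 - sbth), class = "binary_masks")
}
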