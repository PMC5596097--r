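# The outer WT-FD separation loop: one pass splits the input into a
# transient (sound) part XS and a stationary residual XU; the residual is
# re-fed until the residual energy stabilizes, and the de-noised signal is
# the sum of the per-iteration XS parts.

#' One pass of the WT-FD separation
#'
#' Decomposes the input, discards the leading noise levels, selects the
#' informative band, builds the per-level signal masks from the peeled
#' fractal-dimension traces, and reconstructs the transient part `xs` as the
#' sum of the masked selected details. The residual is defined as
#' `xu = x - xs`, so the unselected levels, the smooth band and all
#' noise-masked content route to `xu` and conservation `xs + xu == x` holds
#' by construction.
#'
#' @param x Numeric signal, normalized to unit peak amplitude.
#' @param fs Sampling rate in Hz.
#' @param config A [wtfd_config()].
#' @return List with `xs`, `xu`, `d` (discarded levels), `m` (selected
#'   count), `selected` (original level indices), `masks` (named list of
#'   `"binary_masks"` keyed by level), `level_energies`, and `silent`
#'   (flag: zero-energy input).
#' @export
wtfd_once <- function(x, fs, config = wtfd_config()) {
  n <- length(x)
  if (all(x == 0)) {
    return(list(xs = numeric(n), xu = x, d = NA_integer_, m = NA_integer_,
                selected = integer(0), masks = list(),
                level_energies = NULL, silent = TRUE))
  }
  wl <- config$wavelet
  stack <- decompose_signal(x, n_levels = wl$levels, family = wl$family,
                            boundary = wl$boundary)
  prof_all <- energy_profile(stack)
  d <- discard_noisy_levels(prof_all, wl$c_discard)
  retained <- (d + 1L):stack$n_levels
  m <- if (length(retained) < 2L) 1L else
    select_levels(energy_profile(stack, levels = retained), wl$p_select)
  selected <- retained[seq_len(m)]

  masks <- list()
  xs <- numeric(n)
  for (j in selected) {
    fd <- sliding_fd(stack$details[[j]], fs, config$fd$window_coeff)
    pp <- fd_ppa(fd, fs, epoch_ms = config$fd$epoch_ms,
                 acc = config$fd$acc, max_inner = config$fd$max_inner)
    pp <- prune_small_peaks(pp, stack$details[[j]], fs,
                            min_dur_coeff = config$prune$min_dur_coeff,
                            min_amp = config$prune$min_amp,
                            mode = config$prune$mode)
    mk <- build_masks(pp)
    masks[[as.character(j)]] <- mk
    xs <- xs + mk$sbth * stack$details[[j]]
  }
  list(xs = xs, xu = x - xs, d = d, m = m, selected = selected,
       masks = masks, level_energies = stack$level_energies, silent = FALSE)
}

#' Iterative WT-FD de-noising
#'
#' Runs [wtfd_once()] repeatedly, feeding each iteration's stationary
#' residual `XU_k` to the next, and stops when the residual energy
#' stabilizes: `|E{XU_{k-1}^2} - E{XU_k^2}| < epsilon` (with `XU_0 = 0`), or
#' when `max_outer` is reached (with a warning). The de-noised signal is the
#' exact sum of the per-iteration transient parts, `x_rec = sum_k XS_k`.
#' The residual is never re-normalized between iterations, so the
#' amplitude-based thresholds keep their meaning relative to the original
#' unit-peak input.
#'
#' By default the discarded/selected level split is re-estimated at every
#' iteration (the input changes); set `filter$freeze_levels = TRUE` in the
#' config to reuse the first iteration's split.
#'
#' @param x Numeric signal or an `"fpcg_record"`; signals are normalized to
#'   unit peak amplitude.
#' @param fs Sampling rate in Hz (taken from the record when given).
#' @param config A [wtfd_config()].
#' @return A `"wtfd_result"`: list with `x_rec`, `xs_per_iter`,
#'   `xu_per_iter`, `masks_per_iter`, `n_outer`, `selected_per_iter`,
#'   `diagnostics` (data.frame per iteration: `d`, `m`, residual energy),
#'   `fs`, `config`.
#' @examples
#' rec <- simulate_fpcg("normal", snr_db = 8, duration = 4, fs = 1000, seed = 1)
#' res <- wtfd_denoise(rec)
#' res$n_outer
#' @export
wtfd_denoise <- function(x, fs = NULL, config = wtfd_config()) {
  if (inherits(x, "fpcg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak

  eps <- config$filter$epsilon
  max_outer <- config$filter$max_outer
  stopifnot(eps > 0)

  xs_list <- list()
  xu_list <- list()
  masks_list <- list()
  sel_list <- list()
  diag_rows <- list()
  frozen <- NULL

  cur <- x
  e_prev <- 0  # E{XU_0^2} = 0
  k <- 0L
  repeat {
    k <- k + 1L
    cfg_k <- config
    step <- wtfd_once(cur, fs, cfg_k)
    if (isTRUE(config$filter$freeze_levels)) {
      if (is.null(frozen)) {
        frozen <- list(d = step$d, selected = step$selected)
      } else if (!step$silent &&
                 !identical(step$selected, frozen$selected)) {
        # recompute masks on the frozen selection
        step <- wtfd_once_frozen(cur, fs, config, frozen$selected)
      }
    }
    xs_list[[k]] <- step$xs
    xu_list[[k]] <- step$xu
    masks_list[[k]] <- step$masks
    sel_list[[k]] <- step$selected
    e_k <- mean(step$xu^2)
    diag_rows[[k]] <- data.frame(iteration = k, d = step$d, m = step$m,
                                 residual_energy = e_k)
    if (abs(e_k - e_prev) < eps) break
    if (k >= max_outer) {
      warning("outer loop reached max_outer = ", max_outer,
              "; returning the accumulated result")
      break
    }
    e_prev <- e_k
    cur <- step$xu
  }

  structure(list(
    x_rec = Reduce(`+`, xs_list),
    xs_per_iter = xs_list, xu_per_iter = xu_list,
    masks_per_iter = masks_list, selected_per_iter = sel_list,
    n_outer = k, diagnostics = do.call(rbind, diag_rows),
    fs = fs, config = config
  ), class = "wtfd_result")
}

# One pass with a fixed selected-level set (freeze_levels = TRUE support).
wtfd_once_frozen <- function(x, fs, config, selected) {
  n <- length(x)
  wl <- config$wavelet
  stack <- decompose_signal(x, n_levels = wl$levels, family = wl$family,
                            boundary = wl$boundary)
  masks <- list()
  xs <- numeric(n)
  for (j in selected) {
    fd <- sliding_fd(stack$details[[j]], fs, config$fd$window_coeff)
    pp <- fd_ppa(fd, fs, epoch_ms = config$fd$epoch_ms,
                 acc = config$fd$acc, max_inner = config$fd$max_inner)
    pp <- prune_small_peaks(pp, stack$details[[j]], fs,
                            min_dur_coeff = config$prune$min_dur_coeff,
                            min_amp = config$prune$min_amp,
                            mode = config$prune$mode)
    mk <- build_masks(pp)
    masks[[as.character(j)]] <- mk
    xs <- xs + mk$sbth * stack$details[[j]]
  }
  list(xs = xs, xu = x - xs, d = min(selected) - 1L, m = length(selected),
       selected = selected, masks = masks,
       level_energies = stack$level_energies, silent = FALSE)
}

#' @export
print.wtfd_result <- function(x, ...) {
  cat("<wtfd_result> ", length(x$x_rec), " samples @ ", x$fs, " Hz, ",
      x$n_outer, " outer iteration(s)\n", sep = "")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
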