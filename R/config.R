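#' Pipeline configuration
#'
#' Builds the full set of tunable parameters of the WT-FD pipeline with the
#' method's reference defaults. Three profiles are provided: `"simulated"`
#' (the defaults; white-noise records sampled at ~1 kHz), `"physiobank"`
#' (shorter fractal-dimension epochs, 400 ms, matching the frame length of the
#' PhysioBank simulated fPCG database) and `"real"` (a much smaller discard
#' constant, 0.001, which drops more of the broadband maternal noise levels on
#' real abdominal recordings).
#'
#' Keys (grouped; override any of them via `...`, e.g.
#' `wtfd_config(fd = list(epoch_ms = 400))`):
#' \describe{
#'   \item{wavelet}{`family` ("db4"), `levels` (7), `c_discard` (0.4; 0.001 in
#'     the "real" profile), `p_select` (0.01), `boundary` ("symmetric" or
#'     "periodic" signal extension).}
#'   \item{fd}{`window_coeff` (0.05: the sliding window is
#'     `int(window_coeff * fs)` samples), `epoch_ms` (430; 400 in the
#'     "physiobank" profile), `acc` (1e-5, inner stopping accuracy),
#'     `max_inner` (50).}
#'   \item{prune}{`min_dur_coeff` (0.015), `min_amp` (0.25), `mode` ("or":
#'     a detected fractal peak is kept only if it is both long enough and
#'     lies over sufficient level amplitude; "and": removed only when it
#'     fails both clauses).}
#'   \item{filter}{`epsilon` (1e-4, outer stopping accuracy), `max_outer`
#'     (10), `freeze_levels` (FALSE: re-estimate the discarded/selected level
#'     split at every outer iteration).}
#'   \item{segmentation}{`merge_gap_coeff` (0.015: mask runs closer than
#'     `int(coeff * fs)` samples are merged), `s1_min_amp` (0.5),
#'     `min_cycle_gap_ms` (130).}
#' }
#'
#' @param profile One of `"simulated"`, `"physiobank"`, `"real"`.
#' @param ... Named lists overriding individual keys within the groups above.
#' @return A nested list of class `"wtfd_config"`.
#' @examples
#' cfg <- wtfd_config()
#' cfg$fd$epoch_ms
#' wtfd_config("physiobank")$fd$epoch_ms
#' @export
wtfd_config <- function(profile = c("simulated", "physiobank", "real"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    wavelet = list(family = "db4", levels = 7L, c_discard = 0.4,
                   p_select = 0.01, boundary = "symmetric"),
    fd = list(window_coeff = 0.05, epoch_ms = 430, acc = 1e-5,
              max_inner = 50L),
    prune = list(min_dur_coeff = 0.015, min_amp = 0.25, mode = "or"),
    filter = list(epsilon = 1e-4, max_outer = 10L, freeze_levels = FALSE),
    segmentation = list(merge_gap_coeff = 0.015, s1_min_amp = 0.5,
                        min_cycle_gap_ms = 130)
  )
  if (profile == "physiobank") cfg$fd$epoch_ms <- 400
  if (profile == "real") cfg$wavelet$c_discard <- 0.001

  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be named", call. = FALSE)
    for (nm in names(overrides)) {
      if (!nm %in% names(cfg))
        stop("unknown config group: ", nm, call. = FALSE)
      if (is.list(cfg[[nm]])) {
        bad <- setdiff(names(overrides[[nm]]), names(cfg[[nm]]))
        if (length(bad))
          stop("unknown config key(s) in '", nm, "': ",
               paste(bad, collapse = ", "), call. = FALSE)
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
      } else {
        cfg[[nm]] <- overrides[[nm]]
      }
    }
  }
  structure(cfg, class = "wtfd_config")
}

#' @export
print.wtfd_config <- function(x, ...) {
  cat("<wtfd_config> profile:", x$profile, "\n")
  for (grp in setdiff(names(x), "profile")) {
    vals <- vapply(x[[grp]], function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  ", grp, ": ", paste(names(vals), vals, sep = "=", collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' Round-trips a [wtfd_config()] object through a YAML file so that a run can
#' be reproduced from its recorded configuration. Requires the `yaml` package.
#'
#' @param path File path.
#' @param config A `"wtfd_config"` object.
#' @return `read_config()` returns a `"wtfd_config"` object;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "simulated"
  raw$profile <- NULL
  do.call(wtfd_config, c(list(profile = profile), raw))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write config files", call. = FALSE)
  stopifnot(inherits(config, "wtfd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
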