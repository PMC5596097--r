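# Shared fixtures built in code.

# Reference per-record index triples (Q_P, D_R, S_F) for the simulated and
# PhysioBank benchmark tables, used as a regression fixture for the index
# definitions (Q_P should be the geometric mean of D_R and S_F).
reference_index_triples <- function() {
  m <- rbind(
    c(100, 100, 100), c(97.3, 100, 94.7), c(94.6, 100, 89.5),
    c(98.7, 100, 97.3), c(97.5, 100, 95), c(98.3, 100, 96.7),
    c(96.6, 100, 93.3), c(95.6, 98.2, 93.3), c(96.7, 96.7, 96.7),
    c(94.9, 100, 90), c(92.8, 100, 86.4), c(97.7, 100, 95.5),
    c(87.9, 100, 77.3), c(94.1, 100, 88.6), c(90.5, 100, 81.8),
    c(92, 100, 84.1), c(85.3, 100, 72.7),
    c(94.9, 100, 90), c(89.4, 100, 80), c(96.6, 100, 93.3),
    c(93, 100, 86.7), c(87.8, 92.6, 83.3), c(82.8, 85.7, 80),
    c(88.1, 89.7, 86.7), c(83.9, 81.2, 86.7), c(68.9, 67.7, 70),
    c(53.3, 47.4, 60), c(66, 93.3, 46.7), c(85.6, 100, 73.3),
    c(38.7, 75, 20), c(62, 82.4, 46.7), c(77.5, 100, 60),
    c(45.6, 62.5, 33.3))
  data.frame(qp = m[, 1], dr = m[, 2], sf = m[, 3])
}

# Ground-truth intervals of a timeline converted to sample indices.
truth_s_vector <- function(timeline, fs) {
  tr <- beat_intervals(timeline)
  structure(data.frame(start = as.integer(round(tr$onset_s * fs)) + 1L,
                       end = as.integer(round(tr$offset_s * fs)) + 1L),
            class = c("s_vector", "data.frame"), fs = fs)
}

# Independent matcher oracle: ground-truth intervals are disjoint, so the
# number of correct detections under the single-match rule equals the number
# of truth intervals containing at least one detection peak.
oracle_match_count <- function(truth, peaks_s) {
  sum(vapply(seq_len(nrow(truth)), function(r) {
    any(peaks_s >= truth$onset_s[r] & peaks_s <= truth$offset_s[r])
  }, logical(1)))
}

# Hand-built fd_pp_result for pruning/mask tests.
make_fdpp <- function(fdpp, fs = 1000) {
  structure(list(fdpp = fdpp, n_inner = 1L,
                 epochs = cbind(start = 1L, end = length(fdpp)), fs = fs),
            class = "fd_pp_result")
}
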