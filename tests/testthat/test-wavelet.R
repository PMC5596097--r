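# Undecimated decomposition/reconstruction and the level-selection criteria.

test_that("decomposition is linear, full-length, and perfectly reconstructs", {
  expect_true(all(vapply(decompose_signal(numeric(512), 4)$details,
                         function(d) all(d == 0), logical(1))))
  x <- wtfd:::with_seed(1, stats::rnorm(10000))
  for (bd in c("symmetric", "periodic")) {
    st <- decompose_signal(x, 7, boundary = bd)
    expect_length(st$details, 7)
    expect_true(all(lengths(st$details) == 10000))
    rel <- sqrt(mean((reconstruct_signal(st) - x)^2) / mean(x^2))
    expect_lt(rel, 1e-8)
  }
})

test_that("transform-domain energy is conserved (periodic circle)", {
  x <- wtfd:::with_seed(2, stats::rnorm(4096))
  st <- decompose_signal(x, 6, boundary = "periodic")
  total <- sum(st$coeff_energies) + st$approx_coeff_energy
  expect_equal(total, mean(x^2), tolerance = 1e-6)
})

test_that("depth beyond the filter-bank maximum is clamped with a warning", {
  x <- stats::rnorm(64)
  expect_warning(st <- decompose_signal(x, 12), "clamped")
  expect_lt(st$n_levels, 12)
  expect_error(decompose_signal(stats::rnorm(4), 1), "shorter")
})

test_that("masked reconstruction is linear and routes only listed levels", {
  x <- wtfd:::with_seed(3, stats::rnorm(2000))
  st <- decompose_signal(x, 5)
  ones <- rep(1, 2000)
  # all-ones masks on every level reproduce the detail sum (no smooth)
  full_masks <- stats::setNames(rep(list(ones), 5), as.character(1:5))
  d_sum <- reconstruct_signal(st, full_masks)
  expect_equal(d_sum, reconstruct_signal(st, include_smooth = FALSE),
               tolerance = 1e-12)
  # all-zero masks give zero
  expect_true(all(reconstruct_signal(st, list("2" = numeric(2000))) == 0))
  # complementary masks on the selected levels sum to the unmasked band
  m <- wtfd:::with_seed(4, as.numeric(stats::runif(2000) > 0.5))
  a <- reconstruct_signal(st, list("2" = m, "3" = m))
  b <- reconstruct_signal(st, list("2" = 1 - m, "3" = 1 - m))
  band <- st$details[[2]] + st$details[[3]]
  expect_equal(a + b, band, tolerance = 1e-12)
  expect_error(reconstruct_signal(st, list("2" = m[-1])), "length mismatch")
  expect_error(reconstruct_signal(st, list(m)), "named")
})

test_that("energy profile matches an independent cumulative-sum oracle", {
  e <- c(4, 3, 2, 1) / 10
  pr <- energy_profile(e)
  expect_equal(pr$eta, 1 - cumsum(e) / sum(e), tolerance = 1e-12)
  # equal energies: eta = (0.75, 0.5, 0.25, 0)
  expect_equal(energy_profile(rep(2, 4))$eta, c(0.75, 0.5, 0.25, 0))
  # random energies against the oracle
  re <- wtfd:::with_seed(5, stats::runif(7))
  pr2 <- energy_profile(re)
  f <- re / sum(re)
  expect_equal(pr2$eta, 1 - cumsum(f), tolerance = 1e-12)
  expect_equal(pr2$eta1, f, tolerance = 1e-12)
  expect_equal(pr2$eta2, f - c(f[-1], 0), tolerance = 1e-12)
  expect_true(all(diff(pr2$eta) <= 0))
  expect_equal(pr2$eta[7], 0)
  expect_error(energy_profile(numeric(1) + 1), "2 levels")
  expect_error(energy_profile(rep(0, 4)), "silent")
})

test_that("discard criterion follows the signed-difference rule and always drops level 1", {
  # independent enumeration of D = min{lambda >= 1: eta'_1 - eta'_{lambda+1} <= c}
  oracle_d <- function(e, cc) {
    f <- e / sum(e)
    d1 <- diff(1 - cumsum(f))
    for (lam in seq_len(length(e) - 2)) {
      if (d1[1] - d1[lam + 1] <= cc) return(lam)
    }
    length(e) - 1L
  }
  cases <- list(rep(1, 5),                       # flat profile
                c(0.05, 0.05, 3, 1, 0.5),        # dominant mid level
                c(0.5, 0.25, 0.12, 0.06, 0.03),  # noise-like decay
                wtfd:::with_seed(6, stats::runif(7)))
  for (e in cases) {
    d <- discard_noisy_levels(energy_profile(e), 0.4)
    expect_equal(d, oracle_d(e, 0.4))
    expect_gte(d, 1L)
  }
  # never-satisfied criterion caps at J - 1 with a warning
  expect_warning(
    d <- discard_noisy_levels(energy_profile(c(0.1, 0.02, 0.88)), 0.4),
    "never satisfied")
  expect_equal(d, 2L)
})

test_that("selection picks the last level above the energy-fraction threshold", {
  # worked example: fractions (0.66, 0.33, 0.010, 0.002) -> M = 2
  expect_equal(select_levels(energy_profile(c(0.60, 0.30, 0.009, 0.002))), 2L)
  # decaying profile: M is the last level with fraction > p
  e <- c(0.5, 0.3, 0.15, 0.04, 0.008, 0.002)
  expect_equal(select_levels(energy_profile(e), p = 0.01), 4L)
  expect_equal(select_levels(energy_profile(e), p = 0.1), 3L)
  # p = 0 with strictly positive fractions selects everything
  expect_equal(select_levels(energy_profile(e), p = 0), 6L)
})

test_that("selection is robust to small circular shifts of the input", {
  changed <- 0L
  for (s in 1:20) {
    rec <- simulate_fpcg("normal", snr_db = 8, duration = 10, fs = 1000,
                         seed = 500 + s)
    x <- rec$samples
    o1 <- wtfd_once(x, 1000)
    o2 <- wtfd_once(c(x[-(1:5)], x[1:5]), 1000)
    if (!identical(c(o1$d, o1$m), c(o2$d, o2$m))) changed <- changed + 1L
  }
  expect_lte(changed, 2L)  # < 10% of trials
})
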