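# Katz fractal dimension, the sliding trace, peak peeling, pruning, masks.

test_that("Katz FD matches hand-derived values and its lower bound", {
  # straight segments of any slope give exactly 1
  expect_identical(katz_fd(seq(0, 1, length.out = 50)), 1)
  expect_identical(katz_fd(rep(0.3, 10)), 1)
  expect_identical(katz_fd(5 * (1:20)), 1)
  # zigzag (0,1,0,1,0): L_c = 4*sqrt(2), d = 4, n_s = 4
  zz <- log10(4) / (log10(4 / (4 * sqrt(2))) + log10(4))
  expect_equal(katz_fd(c(0, 1, 0, 1, 0)), zz, tolerance = 1e-12)
  expect_equal(zz, 4 / 3, tolerance = 1e-12)
  # FD >= 1 on arbitrary windows
  for (s in 1:25) {
    y <- wtfd:::with_seed(s, stats::rnorm(50, sd = stats::runif(1, 0.01, 2)))
    expect_gte(katz_fd(y), 1)
  }
  expect_error(katz_fd(c(1, 2)), "3 points")
})

test_that("sliding trace equals a brute-force window sweep with edge filling", {
  fs <- 1000
  y <- wtfd:::with_seed(7, stats::rnorm(300, sd = 0.3))
  tr <- sliding_fd(y, fs)
  expect_equal(tr$window, 50L)  # int(0.05 * 1000)
  expect_length(tr$values, 300)
  w <- 50L
  brute <- vapply(seq_len(300 - w + 1), function(t) katz_fd(y[t:(t + w - 1)]),
                  numeric(1))
  head_fill <- ceiling((w - 1) / 2)
  expected <- c(rep(brute[1], head_fill), brute,
                rep(brute[length(brute)], (w - 1) - head_fill))
  expect_equal(tr$values, expected, tolerance = 1e-12)
  expect_true(all(tr$values >= 1))
  # constant input -> identically 1
  expect_true(all(sliding_fd(rep(2, 200), fs)$values == 1))
  expect_error(sliding_fd(stats::rnorm(40), fs), "exceeds")
})

test_that("the trace maximum localizes an isolated burst", {
  fs <- 1000
  x <- numeric(1000)
  burst <- synthesize_beat("S1", fs)
  x[401:460] <- burst
  tr <- sliding_fd(x, fs)
  peak_at <- which.max(tr$values)
  expect_gte(peak_at, 401 - 25)
  expect_lte(peak_at, 460 + 25)
})

test_that("peak peeling keeps the baseline at exactly 1 and converges", {
  fs <- 1000
  # flat trace: single iteration, untouched
  flat <- fd_ppa(rep(1, 900), fs = fs)
  expect_true(all(flat$fdpp == 1))
  expect_true(all(flat$n_inner == 1L))
  # re-running on an all-baseline trace changes nothing (idempotence)
  again <- fd_ppa(flat$fdpp, fs = fs)
  expect_identical(again$fdpp, flat$fdpp)

  # one tall peak on an exact baseline: off-peak samples end at exactly 1,
  # peak support exceeds 1
  v <- rep(1, 860)
  v[200:230] <- 1.5
  pp <- fd_ppa(v, fs = fs)
  expect_true(all(pp$fdpp >= 1))
  expect_true(all(pp$fdpp[200:230] > 1))
  expect_true(all(pp$fdpp[c(1:150, 300:400)] == 1))

  # with baseline fluctuation the peeled trace stays >= 1 and the tall peak
  # is still the dominant detection
  vn <- 1 + abs(wtfd:::with_seed(8, stats::rnorm(860, sd = 1e-4)))
  vn[200:230] <- vn[200:230] + 0.5
  ppn <- fd_ppa(vn, fs = fs)
  expect_true(all(ppn$fdpp >= 1))
  expect_true(all(ppn$fdpp[200:230] > 1))
})

test_that("epochs are thresholded independently so faint peaks survive", {
  fs <- 1000
  v <- rep(1, 860)                    # two 430-sample epochs
  v[100:130] <- 2.0                   # loud peak, epoch 1
  v[600:630] <- 1.02                  # faint peak, epoch 2
  # the faint peak sits below epoch 1's mean + sd threshold...
  mu1 <- mean(v[1:430]); sd1 <- stats::sd(v[1:430])
  expect_lt(1.02, mu1 + sd1)
  # ...yet survives because its own epoch thresholds it locally
  pp <- fd_ppa(v, fs = fs, epoch_ms = 430)
  expect_true(any(pp$fdpp[600:630] > 1))
  expect_equal(nrow(pp$epochs), 2)
  expect_equal(unname(pp$epochs[2, "end"]), 860)
  expect_error(fd_ppa(v, fs = fs, epoch_ms = 50), "at least 100")
})

test_that("pruning applies the duration and amplitude clauses per mode", {
  fs <- 1000  # duration threshold int(0.015 * fs) = 15 samples
  lvl <- numeric(600)
  fdpp <- rep(1, 600)
  fdpp[101:110] <- 1.5; lvl[101:110] <- 0.9   # short, strong
  fdpp[201:210] <- 1.5; lvl[201:210] <- 0.1   # short, weak
  fdpp[301:330] <- 1.5; lvl[301:330] <- 0.9   # long, strong
  fdpp[401:430] <- 1.5; lvl[401:430] <- 0.1   # long, weak

  res_and <- prune_small_peaks(make_fdpp(fdpp, fs), lvl, fs, mode = "and")
  expect_true(all(res_and$fdpp[101:110] > 1))   # amplitude clause fails
  expect_true(all(res_and$fdpp[201:210] == 1))  # both clauses hold
  expect_true(all(res_and$fdpp[301:330] > 1))
  expect_true(all(res_and$fdpp[401:430] > 1))   # duration clause fails

  res_or <- prune_small_peaks(make_fdpp(fdpp, fs), lvl, fs, mode = "or")
  expect_true(all(res_or$fdpp[101:110] == 1))   # too short
  expect_true(all(res_or$fdpp[201:210] == 1))
  expect_true(all(res_or$fdpp[301:330] > 1))    # long and strong survives
  expect_true(all(res_or$fdpp[401:430] == 1))   # too weak
})

test_that("signal and noise masks are complementary indicators of the peaks", {
  fdpp <- rep(1, 300)
  fdpp[50:80] <- 1.2
  mk <- build_masks(make_fdpp(fdpp))
  expect_true(all(mk$sbth + mk$nbth == 1))
  expect_true(all(mk$sbth * mk$nbth == 0))
  expect_equal(mk$sbth, as.numeric(fdpp != 1))
  # all-baseline trace: sbth all 0, nbth all 1
  mk0 <- build_masks(make_fdpp(rep(1, 100)))
  expect_true(all(mk0$sbth == 0) && all(mk0$nbth == 1))
})
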