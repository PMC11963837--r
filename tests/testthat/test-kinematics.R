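# Changepoints, movement cycles, amplitude classes, cycle AUC, spectrogram.

test_that("changepoint matches the exhaustive-search oracle on short traces", {
  x <- c(rep(0, 50), rep(20, 50))
  k <- detect_change_point(x, penalty = 10)
  expect_identical(as.integer(k), 51L)          # first sample of the new regime
  expect_identical(as.integer(k), oracle_change_point(x, 10))
  # constant trace -> no-change sentinel
  expect_true(is.na(detect_change_point(rep(3, 40))))
  # two steps, second twice as large: the larger step wins and matches the oracle
  x2 <- piecewise_trace(c(0, 5, 20), c(40, 30, 30))
  k2 <- detect_change_point(x2, penalty = 10)
  expect_identical(as.integer(k2), oracle_change_point(x2, 10))
  expect_identical(as.integer(k2), 71L)
  expect_gt(attr(k2, "improvement"), 10)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(8:200, 1)
    x <- piecewise_trace(stats::runif(3, 0, 30), c(n %/% 3, n %/% 3, n - 2 * (n %/% 3)),
                         jitter = 0.5)
    pen <- stats::runif(1, 0, 50)
    expect_identical(as.integer(detect_change_point(x, pen)),
                     as.integer(oracle_change_point(x, pen)))
  }
})

test_that("default changepoint penalty flags motionless traces as no-change", {
  set.seed(8)
  flat <- stats::rnorm(100, 0, 0.1)
  expect_true(is.na(detect_change_point(flat)))
  onset <- c(stats::rnorm(50, 0, 0.1), 15 + 10 * sin(2 * pi * 6 * (0:49) / 120))
  expect_false(is.na(detect_change_point(onset)))
})

test_that("cycles tile the trace minimum-to-minimum with correct amplitudes", {
  # one triangle period 0 -> 25 -> 0
  tri <- whisker_trace(c(seq(0, 25, by = 5), seq(20, 0, by = -5)), fps = 10,
                       rebased = TRUE)
  cyc <- detect_cycles(tri)
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$amplitude, 25)
  expect_equal(cyc$start_index, 1L)
  expect_equal(cyc$end_index, length(tri$angles))
  expect_equal(tri$angles[cyc$max_index], 25)
  # protraction/retraction spans: min before max before end
  expect_true(cyc$min_index <= cyc$max_index && cyc$max_index <= cyc$end_index)
  # flat trace -> no cycles
  flat <- whisker_trace(rep(0, 50), fps = 10, rebased = TRUE)
  expect_equal(nrow(detect_cycles(flat)), 0L)
  # 8 Hz sinusoid over 2 s: 16 +- 1 cycles, spans tile without overlap
  tr <- simulate_whisker_trace(8, 30, noise_sd = 0, fps = 120, duration_s = 2)
  cyc8 <- detect_cycles(tr)
  expect_true(abs(nrow(cyc8) - 16) <= 1)
  expect_identical(cyc8$start_index[-1], cyc8$end_index[-nrow(cyc8)])
  expect_true(all(cyc8$amplitude >= 0))
})

test_that("amplitude classification thresholds on the window mean with ties short", {
  cyc <- data.frame(start_index = c(1, 10, 20), min_index = c(1, 10, 20),
                    max_index = c(5, 15, 25), end_index = c(10, 20, 30),
                    amplitude = c(10, 20, 30))
  cls <- classify_amplitudes(cyc)
  expect_equal(cls$threshold, 20)
  expect_equal(cls$long_count, 1L)
  expect_equal(cls$short_count, 2L)      # the tie at 20 counts as short
  expect_equal(sum(cls$proportions), 1)
  all_equal <- transform(cyc, amplitude = 7)
  expect_equal(classify_amplitudes(all_equal)$short_count, 3L)
  two <- transform(cyc[1:2, ], amplitude = c(5, 35))
  expect_equal(classify_amplitudes(two)$threshold, 20)
  expect_equal(classify_amplitudes(two)$long_count, 1L)
  expect_error(classify_amplitudes(cyc[0, ]), "no cycles")
})

test_that("cycle AUC is the trapezoidal integral and scales linearly", {
  # triangle 0 -> 20 -> 0 over 1 s at 10 fps: area 10 degree-seconds
  ang <- c(seq(0, 20, length.out = 6), seq(16, 0, length.out = 5))
  tr <- whisker_trace(ang, fps = 10, rebased = TRUE)
  cyc <- detect_cycles(tr)
  expect_equal(cycle_auc(tr, cyc[1, ]), 10)
  tr2 <- whisker_trace(2 * ang, fps = 10, rebased = TRUE)
  expect_equal(cycle_auc(tr2, detect_cycles(tr2)[1, ]), 20)   # linearity
})

test_that("spectrogram localizes programmed tones within one bin", {
  tr <- simulate_whisker_trace(8, 30, noise_sd = 0, fps = 120, duration_s = 4)
  sp <- movement_spectrogram(tr)
  peaks <- apply(sp$power, 2, function(p) sp$frequencies[which.max(p)])
  expect_true(all(abs(peaks - 8) <= 1))
  expect_equal(sp$frequencies[1], 0)
  expect_equal(max(sp$frequencies), tr$fps / 2)
  # flat (constant) trace: without demeaning all power sits at 0 Hz
  flat <- whisker_trace(rep(5, 240), fps = 120, rebased = FALSE)
  spf <- movement_spectrogram(flat, demean = FALSE)
  expect_equal(spf$frequencies[which.max(rowMeans(spf$power))], 0)
  # only Hann sidelobes (~ -31 dB) remain beyond the DC main lobe
  expect_lt(sum(spf$power[-(1:3), ]), 0.01 * sum(spf$power))
  # two tones: the two largest local maxima sit within 1 Hz of 3 and 15
  t3 <- simulate_whisker_trace(3, 10, noise_sd = 0, fps = 120, duration_s = 4)
  t15 <- simulate_whisker_trace(15, 10, noise_sd = 0, fps = 120, duration_s = 4)
  both <- whisker_trace(t3$angles + t15$angles - min(t3$angles + t15$angles),
                        fps = 120, rebased = TRUE)
  pw <- rowMeans(movement_spectrogram(both)$power)
  fr <- movement_spectrogram(both)$frequencies
  is_peak <- c(FALSE, pw[2:(length(pw) - 1)] > pw[1:(length(pw) - 2)] &
                 pw[2:(length(pw) - 1)] > pw[3:length(pw)], FALSE)
  top2 <- sort(fr[is_peak][order(pw[is_peak], decreasing = TRUE)][1:2])
  expect_lte(abs(top2[1] - 3), 1)
  expect_lte(abs(top2[2] - 15), 1)
  expect_error(movement_spectrogram(whisker_trace(c(0, 1), fps = 120)),
               "shorter than one")
})

test_that("frequency and amplitude recovery on seeded sinusoids (+-1 Hz, +-10%)", {
  for (f in c(2, 5, 8, 12)) {
    for (a in c(10, 40)) {
      tr <- simulate_whisker_trace(f, a, noise_sd = 0.1, fps = 120,
                                   duration_s = 4, seed = 100 * f + a)
      cyc <- detect_cycles(tr)
      span_s <- (cyc$end_index[nrow(cyc)] - cyc$start_index[1]) / tr$fps
      expect_lt(abs(nrow(cyc) / span_s - f), 1)
      expect_lt(abs(mean(cyc$amplitude) - a) / a, 0.10)
      sp <- movement_spectrogram(tr)
      expect_lte(abs(sp$frequencies[which.max(rowMeans(sp$power))] - f), 1)
    }
  }
})

test_that("transection schedule collapses cycle AUC by at least 80%", {
  base <- simulate_whisker_trace(8, 20, fps = 120, duration_s = 2, seed = 41)
  post <- simulate_whisker_trace(8, 20, fps = 120, duration_s = 2, seed = 42,
                                 multiplier = 0.05)
  auc_of <- function(tr) {
    cyc <- detect_cycles(tr)
    mean(vapply(seq_len(nrow(cyc)), function(i) cycle_auc(tr, cyc[i, ]), numeric(1)))
  }
  expect_gt(1 - auc_of(post) / auc_of(base), 0.80)
})
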