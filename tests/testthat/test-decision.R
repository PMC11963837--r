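# Thresholds, the ten decision models, the per-frame movement rule, session
# verdicts, decision percentage, and d-prime.

test_that("group threshold is mean + sample sd per zone", {
  ts <- group_threshold(c(1, 2, 3))
  expect_equal(unname(ts$thresholds), 3)     # mean 2 + sd 1
  expect_equal(ts$mode, "group_mean_plus_std")
  expect_equal(unname(group_threshold(c(4, 4))$thresholds), 4)
  m <- cbind(A = c(1, 2, 3), M = c(2, 4, 6))
  tm <- group_threshold(m)
  expect_equal(tm$thresholds, c(A = 3, M = 6))
  expect_true(all(tm$thresholds >= colMeans(m)))
  expect_error(group_threshold(matrix(1, 1, 1)), "insufficient")
})

test_that("individual threshold is the plain mean, order-invariant", {
  expect_equal(unname(individual_threshold(4)$thresholds), 4)
  expect_equal(unname(individual_threshold(c(2, 6))$thresholds), 4)
  set.seed(2)
  v <- stats::runif(9)
  expect_equal(individual_threshold(v)$thresholds,
               individual_threshold(sample(v))$thresholds)
  # with identical sessions, group >= individual (sd >= 0)
  expect_gte(group_threshold(v)$thresholds[[1]],
             individual_threshold(v)$thresholds[[1]])
})

test_that("two-session threshold averages baseline and paralyzed sessions", {
  expect_equal(unname(two_session_threshold(6, 2)$thresholds), 4)
  expect_equal(unname(two_session_threshold(3, 3)$thresholds), 3)
  t2 <- two_session_threshold(c(A = 8, M = 2), c(A = 2, M = 1))
  expect_equal(t2$thresholds, c(A = 5, M = 1.5))
  expect_true(t2$thresholds[["A"]] > 2 && t2$thresholds[["A"]] < 8)
  expect_error(two_session_threshold(-1, 2), ">= 0")
})

test_that("low flags are strictly-below with ties not low", {
  ts <- threshold_set(c(A = 3, M = 3))
  expect_identical(low_flags(c(A = 2, M = 2), ts), c(A = 1L, M = 1L))
  expect_identical(low_flags(c(A = 3, M = 5), ts), c(A = 0L, M = 0L))
  expect_error(low_flags(c(A = 1, X = 1), ts), "zone mismatch")
})

test_that("the ten models combine flags with the printed OR / AND-sum semantics", {
  expect_true(apply_model(2, c(A = 1L, M = 1L))$paralyzed)
  expect_false(apply_model(2, c(A = 1L, M = 0L))$paralyzed)
  expect_true(apply_model(1, c(A = 1L, M = 0L))$paralyzed)
  expect_true(apply_model(6, c(A = 0L, M = 0L, P = 1L))$paralyzed)
  expect_false(apply_model(7, c(A = 1L, M = 1L, P = 0L))$paralyzed)
  expect_true(apply_model(10, c(Total = 1L))$paralyzed)
  expect_error(model_spec(11), "unknown model")
  expect_error(apply_model(9, c(A = 1L, M = 1L)), "cover the model")
  # model lattice: AND over zones Z implies OR over Z, for all flag patterns
  and_or <- list(c(3, 1), c(5, 4), c(7, 6), c(9, 8))
  for (pair in and_or) {
    zones <- model_spec(pair[1])$zones
    grids <- expand.grid(rep(list(0:1), length(zones)))
    for (i in seq_len(nrow(grids))) {
      flags <- stats::setNames(as.integer(grids[i, ]), zones)
      if (apply_model(pair[1], flags)$paralyzed) {
        expect_true(apply_model(pair[2], flags)$paralyzed)
      }
    }
  }
})

test_that("frame movement rule: sum of anterior and middle flags below 2", {
  expect_false(frame_movement(1L, 1L))
  expect_true(frame_movement(0L, 1L))
  expect_true(frame_movement(0L, 0L))
  ts <- threshold_set(c(A = 0.5, M = 0.5))
  mv <- frame_movement_series(c(0.1, 0.9, 0.1), c(0.1, 0.1, 0.9), ts)
  expect_identical(mv, c(FALSE, TRUE, TRUE))
})

test_that("session verdict switches strictly above 90% stillness", {
  expect_true(session_verdict(rep(c(TRUE, FALSE), c(5, 95)))$paralyzed)
  v90 <- session_verdict(rep(c(TRUE, FALSE), c(10, 90)))
  expect_false(v90$paralyzed)               # exactly 90% still is not paralyzed
  expect_equal(v90$stillness_fraction, 0.9)
  expect_false(session_verdict(rep(TRUE, 100))$paralyzed)
  # monotone stillness: appending a still frame never flips paralyzed -> not
  set.seed(6)
  for (i in 1:20) {
    mv <- stats::runif(50) < stats::runif(1)
    before <- session_verdict(mv)$paralyzed
    after <- session_verdict(c(mv, FALSE))$paralyzed
    if (before) expect_true(after)
  }
})

test_that("decision percentage counts detected truly-paralyzed days", {
  truth <- rep(TRUE, 20)
  expect_equal(decision_percentage(rep(TRUE, 20), truth), 100)
  expect_equal(decision_percentage(rep(c(TRUE, FALSE), 10), truth), 50)
  expect_equal(decision_percentage(rep(FALSE, 20), truth), 0)
  expect_error(decision_percentage(rep(TRUE, 5), rep(FALSE, 5)), "undefined")
  expect_error(decision_percentage(TRUE, c(TRUE, TRUE)), "same days")
})

test_that("d-prime: zero at symmetry, frozen oracle value, monotone, corrected", {
  expect_equal(d_prime(0.5, 0.5), 0)
  for (x in c(0.1, 0.3, 0.7, 0.9)) expect_equal(d_prime(x, x), 0)
  # inverse-normal oracle: qnorm(0.84) = 0.9944579, so d' = 1.9889158
  expect_equal(d_prime(0.84, 0.16), 1.9889158, tolerance = 1e-6)
  hits <- seq(0.05, 0.95, by = 0.15)
  expect_true(all(diff(vapply(hits, d_prime, numeric(1), fa_rate = 0.2)) > 0))
  expect_true(all(diff(vapply(hits, function(f) d_prime(0.8, f), numeric(1))) < 0))
  # 1/(2N) extreme-rate correction
  expect_equal(d_prime(1, 0.5, n_trials = 10), stats::qnorm(1 - 1 / 20))
  expect_equal(d_prime(0, 0.5, n_trials = 10), stats::qnorm(1 / 20))
  expect_error(d_prime(1, 0.5), "n_trials")
})

test_that("timeline inference flags transection sessions and releases crush recovery", {
  tl <- simulate_timeline("transection", seed = 5)
  res <- infer_timeline(tl$summaries, model = 2, threshold_mode = "two_session")
  expect_equal(decision_percentage(res$paralyzed, tl$labels), 100)
  expect_false(res$paralyzed[1])            # baseline is never flagged

  tlc <- simulate_timeline("crush", seed = 6)
  resc <- infer_timeline(tlc$summaries, model = 2, threshold_mode = "two_session")
  flagged <- which(resc$paralyzed)
  expect_equal(min(flagged), 2L)
  # release within one session of the programmed recovery boundary
  expect_lte(abs((max(flagged) + 1L) - tlc$recovery_session), 1L)
  expect_false(any(resc$paralyzed[(tlc$recovery_session + 2L):23L]))

  # sham scored against a transection anchor raises no false alarm
  tls <- simulate_timeline("sham", seed = 7)
  ress <- infer_timeline(tls$summaries, model = 2, threshold_mode = "two_session",
                         anchor = tl$summaries)
  expect_false(any(ress$paralyzed))
})
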