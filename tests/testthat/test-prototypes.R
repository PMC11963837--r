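# Basal and emotional expression prototypes and similarity traces.

test_that("basal prototype is the element-wise mean of the last n pre-stimulus frames", {
  v <- c(0.2, 0.5, 0.3, 0)
  m <- matrix(rep(v, each = 12), 12)
  p <- basal_prototype(m, n = 12)
  expect_equal(p$vector, v)
  expect_equal(p$label, "basal")
  # mean of v and -v is the zero vector
  p0 <- basal_prototype(rbind(v, -v), n = 2)
  expect_equal(p0$vector, rep(0, 4))
  # brute-force column mean on random vectors
  set.seed(17)
  big <- matrix(stats::runif(260 * 24), 260, 24)
  p250 <- basal_prototype(big, n = 250)
  expect_equal(p250$vector, colMeans(big[11:260, ]))
  expect_equal(p250$n_source_frames, 250L)
  expect_error(basal_prototype(big[1:100, ], n = 250), "only 100")
})

test_that("similarity trace is per-frame Pearson r with affine invariance", {
  set.seed(23)
  v <- stats::runif(30)
  proto <- facial_prototype(v, "basal", 1)
  m <- rbind(v, 2 * v + 1, -v)
  tr <- similarity_trace(m, proto)
  expect_equal(tr$r, c(1, 1, -1))
  # orthogonalized centered pair -> r = 0
  a <- stats::rnorm(50)
  b <- stats::rnorm(50)
  b <- b - mean(b)
  a <- a - mean(a)
  b_orth <- b - sum(a * b) / sum(a * a) * a
  r0 <- similarity_trace(rbind(b_orth), facial_prototype(a, "basal", 1))$r
  expect_lt(abs(r0), 1e-12)
  expect_warning(sc <- similarity_trace(rbind(v, rep(1, 30)), proto), "constant")
  expect_true(is.na(sc$r[2]))
  expect_error(similarity_trace(m, facial_prototype(rep(2, 30), "basal", 1)),
               "constant")
})

test_that("emotional prototype averages the k least-correlated frames", {
  set.seed(29)
  base <- stats::runif(40)
  proto <- facial_prototype(base, "basal", 250)
  # 30 near-basal frames + 10 programmed outliers
  outlier <- rev(base)
  frames <- rbind(matrix(rep(base, each = 30), 30) + stats::rnorm(30 * 40, 0, 1e-4),
                  matrix(rep(outlier, each = 10), 10) + stats::rnorm(10 * 40, 0, 1e-4))
  emo <- emotional_prototype(frames, proto, k = 10, label = "disgust")
  # brute-force selection oracle
  r <- apply(frames, 1, stats::cor, y = base)
  sel <- order(r, seq_along(r))[1:10]
  expect_identical(sort(sel), 31:40)
  expect_equal(emo$vector, colMeans(frames[sel, ]))
  expect_equal(emo$label, "disgust")
  # degenerate k = frame count -> mean of everything
  all_mean <- emotional_prototype(frames, proto, k = 40)
  expect_equal(all_mean$vector, colMeans(frames))
  expect_error(emotional_prototype(frames[1:5, ], proto, k = 10), ">= 10")
})

test_that("stimulus window arithmetic", {
  w <- stimulus_window(400, pre_s = 5, post_s = 5, fps = 30)
  expect_length(w, 300L)
  expect_equal(w[1], 250)
  expect_equal(w[151], 400)       # first post-stimulus frame
})

test_that("onset report measures pre/post similarity difference with truncation flag", {
  r <- c(rep(0.2, 50), rep(0.6, 50))
  tr <- structure(list(r = r, event_time = 50 / 30, fps = 30, label = "pleasure"),
                  class = "fapa_similarity")
  rep1 <- expression_onset_report(tr, window_s = 1)
  expect_equal(rep1$difference, 0.4, tolerance = 1e-9)
  expect_false(rep1$truncated)
  flat <- structure(list(r = rep(0.5, 100), event_time = 1, fps = 30,
                         label = "basal"), class = "fapa_similarity")
  expect_equal(expression_onset_report(flat, window_s = 0.5)$difference, 0)
  expect_warning(big <- expression_onset_report(tr, window_s = 10), "truncated")
  expect_true(big$truncated)
})

test_that("prototype confusion matrix is diagonal-dominant on programmed patterns", {
  protos <- list(); held <- list()
  for (p in 1:3) {
    s <- simulate_expression_session(p, seed = 10 * p)
    hs <- hog_series(s$stack)$vectors
    basal <- basal_prototype(hs[seq_len(s$stim_start - 1), ])
    stim <- hs[s$stim_start:nrow(hs), ]
    protos[[p]] <- emotional_prototype(stim[1:20, ], basal, k = 10,
                                       label = c("pleasure", "disgust", "neutral")[p])
    held[[p]] <- stim[21:40, ]
  }
  conf <- sapply(1:3, function(p) {
    sapply(1:3, function(q) mean(similarity_trace(held[[q]], protos[[p]])$r))
  })
  for (q in 1:3) expect_equal(which.max(conf[q, ]), q)
  # a prototype correlates perfectly with itself
  expect_equal(similarity_trace(rbind(protos[[1]]$vector), protos[[1]])$r, 1)
})

test_that("paralyzed sessions show no post-stimulus similarity rise", {
  # stimulation frames carry no deformation: the face is frozen except for
  # residual basal jitter
  s <- simulate_expression_session(1, seed = 77, basal_mult = 0.15)
  hs <- hog_series(s$stack)$vectors
  basal <- basal_prototype(hs[seq_len(s$stim_start - 1), ])
  # build the "paralyzed" session: same pre-stimulus statistics, stim frames
  # drawn from the same basal process (no programmed expression)
  s2 <- simulate_expression_session(2, seed = 78, basal_mult = 0.15)
  hs2 <- hog_series(s2$stack)$vectors
  tr <- similarity_trace(hs2[seq_len(s2$stim_start - 1), ], basal,
                         event_time = 200 / 30, fps = 30)
  repp <- expression_onset_report(tr, window_s = 2)
  expect_lt(abs(repp$difference), 2 * stats::sd(tr$r, na.rm = TRUE))
})
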