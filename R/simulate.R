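# Deterministic synthetic-data generators. Every fixture used by the test
# suite is produced here: whisker angle traces with injury schedules,
# face-like textured videos with zone-wise programmable motion,
# 23-session evaluation timelines, expression sessions with programmed
# deformation patterns, and motion-coupled Poisson spike trains. All
# generators are reproducible given a seed, which is recorded in the
# returned ground truth.

#' The 23-session evaluation schedule
#'
#' Session labels of the standard paralysis timeline: one baseline
#' (day -1), three early post-injury evaluations (0.5, 6 and 24 h), then one
#' per day from day 2 to day 20.
#'
#' @return Character vector of 23 session labels.
#' @export
session_schedule <- function() {
  c("baseline", "0.5h", "6h", "24h", paste0("day", 2:20))
}

#' Simulate a whisker angle trace
#'
#' `angle(t) = amplitude * multiplier * (0.5 + 0.5 sin(2 pi f t)) + noise`,
#' rebased so the session minimum is 0. The default noise (0.1 deg) reflects
#' the sub-degree jitter of centroid-based angle estimates from a
#' high-contrast painted marker.
#'
#' @param freq oscillation frequency in Hz (must be below Nyquist).
#' @param amplitude peak-to-trough amplitude in degrees.
#' @param noise_sd Gaussian angle noise, degrees.
#' @param fps frame rate (default 120, the whisker camera).
#' @param duration_s trace length in seconds.
#' @param multiplier schedule multiplier (0 = fully paralyzed).
#' @param seed RNG seed.
#' @return A rebased [whisker_trace()] with attribute `ground_truth`
#'   (programmed frequency, effective amplitude, cycle count, seed).
#' @export
simulate_whisker_trace <- function(freq, amplitude, noise_sd = 0.1, fps = 120,
                                   duration_s = 2, multiplier = 1, seed = 1L) {
  if (freq >= fps / 2) stop("frequency must be below the Nyquist rate fps/2")
  stopifnot(amplitude >= 0, noise_sd >= 0, multiplier >= 0)
  set.seed(seed)
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  raw <- amplitude * multiplier * (0.5 + 0.5 * sin(2 * pi * freq * t)) +
    stats::rnorm(n, 0, noise_sd)
  trace <- whisker_trace(raw - min(raw), fps = fps, rebased = TRUE)
  attr(trace, "ground_truth") <- list(
    freq = freq, amplitude = amplitude * multiplier,
    n_cycles = freq * duration_s, noise_sd = noise_sd,
    multiplier = multiplier, seed = seed)
  trace
}

# Per-zone band textures for a size x size face; zones are vertical thirds.
make_face_textures <- function(size) {
  w3 <- size %/% 3L
  widths <- c(A = w3, M = w3, P = size - 2L * w3)
  lapply(widths, function(w) smooth_noise_texture(size, w))
}

#' Render a synthetic face video with zone-wise programmable motion
#'
#' Each of the three vertical face zones (anterior | middle | posterior)
#' carries a fixed band-limited random texture that is rigidly translated
#' per frame along a smooth bounded random path, scaled by that zone's
#' motion multiplier (wrap-around padding keeps the frame filled). A
#' multiplier of 0 freezes the zone exactly. Four landmark coordinates (two
#' "eye" points in the middle zone, two "nose" points in the anterior zone)
#' are recorded as metadata.
#'
#' @param multipliers named motion multipliers `c(A=, M=, P=)`, all >= 0.
#' @param size frame side in pixels (>= 96 so each zone holds at least one
#'   32-px HOG cell).
#' @param fps frame rate (default 30, the face camera).
#' @param duration_s video length in seconds.
#' @param seed RNG seed.
#' @param walk_scale displacement standard deviation in pixels at
#'   multiplier 1.
#' @param noise_sd per-pixel Gaussian intensity noise (default 0, the
#'   noiseless stated world).
#' @param textures optional precomputed textures (list A/M/P), so several
#'   sessions can share one face.
#' @return A [frame_stack()] with attributes `zones` (a [zone_config()]),
#'   `landmarks` (a [landmark_set()]), and `ground_truth` (multipliers,
#'   integer displacements per zone, seed).
#' @export
render_face_video <- function(multipliers = c(A = 1, M = 1, P = 1), size = 96L,
                              fps = 30, duration_s = 2, seed = 1L,
                              walk_scale = 3, noise_sd = 0, textures = NULL) {
  stopifnot(all(multipliers >= 0), all(c("A", "M", "P") %in% names(multipliers)))
  if (size < 96L) stop("size must be >= 96 so each zone holds a full HOG cell")
  set.seed(seed)
  if (is.null(textures)) textures <- make_face_textures(size)
  n <- round(duration_s * fps)
  w3 <- size %/% 3L
  col_start <- c(A = 0L, M = w3, P = 2L * w3)
  widths <- vapply(textures, ncol, integer(1L))
  disp <- list()
  for (z in c("A", "M", "P")) {
    dr <- smooth_path(n); dc <- smooth_path(n)
    d <- round(multipliers[[z]] * walk_scale * cbind(dr, dc))
    disp[[z]] <- sweep(d, 2L, d[1L, ])   # first frame at rest
  }
  frames <- array(0, dim = c(size, size, n))
  for (i in seq_len(n)) {
    for (z in c("A", "M", "P")) {
      cols <- (col_start[[z]] + 1L):(col_start[[z]] + widths[[z]])
      frames[, cols, i] <- circ_shift(textures[[z]],
                                      disp[[z]][i, 1L], disp[[z]][i, 2L])
    }
  }
  if (noise_sd > 0) {
    frames <- pmin(pmax(frames + stats::rnorm(length(frames), 0, noise_sd)), 1)
  }
  stack <- frame_stack(frames, fps = fps, source_id = "synthetic-face")
  attr(stack, "zones") <- default_zone_config(size, size)
  attr(stack, "landmarks") <- landmark_set(
    eye_1 = c(round(size * 0.25), w3 + round(w3 * 0.3)),
    eye_2 = c(round(size * 0.25), w3 + round(w3 * 0.7)),
    nose_1 = c(round(size * 0.70), round(w3 * 0.3)),
    nose_2 = c(round(size * 0.80), round(w3 * 0.6)))
  attr(stack, "ground_truth") <- list(multipliers = multipliers,
                                      displacements = disp, seed = seed,
                                      walk_scale = walk_scale)
  stack
}

# Per-session (A, M, P) motion multipliers for one injury model over the
# 23-session schedule. Transection: anterior/middle movement lost from the
# first post-injury session on, permanently. Crush: lost until the recovery
# session, then ramping linearly back to baseline over three sessions
# (0.6, 0.8, 1.0). The posterior (ear) zone never stops moving. Sham: all 1.
schedule_multipliers <- function(injury_model, recovery_session = 15L) {
  n <- 23L
  m <- matrix(1, n, 3L, dimnames = list(session_schedule(), c("A", "M", "P")))
  if (injury_model == "transection") {
    m[2:n, c("A", "M")] <- 0
  } else if (injury_model == "crush") {
    m[2:n, c("A", "M")] <- 0
    ramp <- c(0.6, 0.8, 1)
    for (j in seq_along(ramp)) {
      s <- recovery_session + j - 1L
      if (s <= n) m[s, c("A", "M")] <- ramp[j]
    }
    if (recovery_session + 3L <= n) m[(recovery_session + 3L):n, c("A", "M")] <- 1
  } else if (injury_model != "sham") {
    stop("unknown injury model: ", injury_model)
  }
  m
}

#' Simulate a 23-session facial-paralysis evaluation timeline
#'
#' Renders one short face video per session of the standard schedule (the
#' same face texture throughout, session-specific motion paths), runs the
#' zone-crop + HOG + Diff pipeline, and returns per-session movement
#' summaries together with ground-truth paralysis labels for scoring.
#'
#' @param injury_model `"transection"`, `"crush"`, or `"sham"`.
#' @param seed RNG seed; per-session seeds are derived from it.
#' @param recovery_session first recovered session of the crush model
#'   (default 15, i.e. day 12 of the schedule).
#' @param size,fps,duration_s,walk_scale forwarded to [render_face_video()].
#' @param params HOG parameters.
#' @return List with `summaries` (23 x 4 matrix: zones A, M, P and `Total`),
#'   `labels` (logical; `TRUE` = truly paralyzed), `sessions`,
#'   `multipliers`, `injury_model`, `recovery_session`, `seed`.
#' @export
simulate_timeline <- function(injury_model = c("transection", "crush", "sham"),
                              seed = 1L, recovery_session = 15L, size = 96L,
                              fps = 30, duration_s = 2, walk_scale = 3,
                              params = hog_params()) {
  injury_model <- match.arg(injury_model)
  mult <- schedule_multipliers(injury_model, recovery_session)
  n_sessions <- nrow(mult)
  set.seed(seed)
  textures <- make_face_textures(size)
  summaries <- matrix(0, n_sessions, 4L,
                      dimnames = list(rownames(mult), c("A", "M", "P", "Total")))
  for (s in seq_len(n_sessions)) {
    stack <- render_face_video(mult[s, ], size = size, fps = fps,
                               duration_s = duration_s,
                               seed = (seed %% 1000000L) * 1000L + s,
                               walk_scale = walk_scale, textures = textures)
    zones <- crop_stack(stack, attr(stack, "zones"))
    for (z in c("A", "M", "P")) {
      summaries[s, z] <- session_summary(hog_diff_series(hog_series(zones[[z]], params, z)))
    }
    summaries[s, "Total"] <- session_summary(hog_diff_series(hog_series(stack, params)))
  }
  labels <- switch(injury_model,
                   transection = c(FALSE, rep(TRUE, n_sessions - 1L)),
                   crush = c(FALSE, rep(TRUE, recovery_session - 2L),
                             rep(FALSE, n_sessions - recovery_session + 1L)),
                   sham = rep(FALSE, n_sessions))
  list(summaries = summaries, labels = labels, sessions = rownames(mult),
       multipliers = mult, injury_model = injury_model,
       recovery_session = recovery_session, seed = seed)
}

#' Simulate an expression session with a programmed deformation pattern
#'
#' Pre-stimulation frames carry low-amplitude spontaneous motion in every
#' zone; stimulation frames additionally displace one pattern-specific zone
#' by a fixed offset plus small jitter, emulating a stereotyped facial
#' expression. Three built-in patterns (1 = anterior, 2 = middle,
#' 3 = posterior signature) stand in for the sucrose / quinine / water
#' responses.
#'
#' @param pattern integer 1-3 selecting the deformation signature.
#' @param n_pre,n_stim number of pre-stimulation and stimulation frames.
#' @param size frame side in pixels.
#' @param fps frame rate.
#' @param seed RNG seed.
#' @param basal_mult amplitude multiplier of the spontaneous basal motion.
#' @return List with `stack` (a [frame_stack()]), `stim_start` (index of the
#'   first stimulation frame), `pattern`, and `zones`.
#' @export
simulate_expression_session <- function(pattern = 1L, n_pre = 260L, n_stim = 40L,
                                        size = 96L, fps = 30, seed = 1L,
                                        basal_mult = 0.2) {
  stopifnot(pattern %in% 1:3)
  offsets <- list(`1` = c(zone = "A", dr = 4, dc = 2),
                  `2` = c(zone = "M", dr = -3, dc = 4),
                  `3` = c(zone = "P", dr = 5, dc = -3))
  sig <- offsets[[as.character(pattern)]]
  n <- n_pre + n_stim
  stack <- render_face_video(c(A = basal_mult, M = basal_mult, P = basal_mult),
                             size = size, fps = fps, duration_s = n / fps,
                             seed = seed)
  zones <- attr(stack, "zones")
  rect <- zones[[sig[["zone"]]]]
  cols <- (rect[3L] + 1L):rect[4L]
  jitter <- matrix(round(stats::rnorm(2L * n_stim, 0, 0.7)), ncol = 2L)
  for (k in seq_len(n_stim)) {
    i <- n_pre + k
    stack$frames[, cols, i] <- circ_shift(
      stack$frames[, cols, i],
      as.integer(sig[["dr"]]) + jitter[k, 1L],
      as.integer(sig[["dc"]]) + jitter[k, 2L])
  }
  list(stack = stack, stim_start = n_pre + 1L, pattern = pattern, zones = zones)
}

#' Simulate a motion-coupled Poisson spike train
#'
#' Inhomogeneous Poisson spikes with rate
#' `rate(t) = rate_base + gain * motion(t - lag_s)`, thinned on a 1-ms grid.
#' Before the motion trace starts, its first value is used.
#'
#' @param rate_base baseline firing rate, Hz (>= 0).
#' @param motion numeric movement trace sampled at `motion_fs`, or `NULL`
#'   for a homogeneous train.
#' @param motion_fs sampling rate of `motion`, Hz.
#' @param gain rate gain per unit of motion (Hz per motion unit).
#' @param lag_s neural lag behind the motion, seconds.
#' @param duration_s recording length, seconds.
#' @param seed RNG seed.
#' @return A [spike_train()].
#' @export
simulate_spikes <- function(rate_base, motion = NULL, motion_fs = 30, gain = 0,
                            lag_s = 0, duration_s = 60, seed = 1L) {
  set.seed(seed)
  dt <- 0.001
  t <- seq(0, duration_s - dt, by = dt)
  if (is.null(motion) || gain == 0) {
    rate <- rep(rate_base, length(t))
  } else {
    mt <- (seq_along(motion) - 1L) / motion_fs
    m <- stats::approx(mt, motion, xout = t - lag_s, rule = 2L)$y
    rate <- rate_base + gain * m
  }
  if (any(rate < 0)) stop("negative instantaneous rate; reduce gain or raise rate_base")
  hits <- stats::runif(length(t)) < rate * dt
  spike_train(t[hits], duration = duration_s)
}
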