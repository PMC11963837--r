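# Whisker kinematics: movement-onset changepoint, protraction/retraction
# cycles, amplitude classes, cycle area, and the movement spectrogram.

#' Detect the movement-onset changepoint of an angle trace
#'
#' Mean-shift changepoint detection: the trace is split into two segments and
#' scored by the summed squared residuals about each segment's mean,
#' `C(A1) + C(A2)`. The best split is the one maximizing the improvement
#' `C(A) - [C(A1) + C(A2)]`; it is accepted only when the improvement exceeds
#' the penalty `t` (the criterion `C(A1) + C(A2) + t < C(A)`). Every split
#' point is evaluated (exhaustively, via cumulative sums).
#'
#' @param trace a [whisker_trace()] or numeric vector (length >= 4).
#' @param penalty acceptance penalty `t` in cost units; defaults to five
#'   times the trace variance.
#' @return Integer index of the first sample of the second segment, with the
#'   attribute `improvement`; `NA_integer_` (a motionless trace) when no
#'   split clears the penalty.
#' @export
detect_change_point <- function(trace, penalty = NULL) {
  x <- if (inherits(trace, "fapa_whisker_trace")) trace$angles else as.numeric(trace)
  n <- length(x)
  if (n < 4L) stop("changepoint detection needs at least 4 samples")
  if (is.null(penalty)) penalty <- 5 * stats::var(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  total <- cs2[n] - cs[n]^2 / n
  k <- 2:n                       # first index of the second segment
  n1 <- k - 1L
  n2 <- n - n1
  c1 <- cs2[n1] - cs[n1]^2 / n1
  c2 <- (cs2[n] - cs2[n1]) - (cs[n] - cs[n1])^2 / n2
  improvement <- total - (c1 + c2)
  best <- which.max(improvement)
  if (improvement[best] <= penalty) {
    return(structure(NA_integer_, improvement = 0))
  }
  structure(as.integer(k[best]), improvement = improvement[best])
}

# Strict local minima of x, with plateau midpoints, optionally including
# endpoints that sit strictly below their neighbour. Returns sorted indices.
local_minima <- function(x, include_endpoints = TRUE) {
  r <- rle(x)
  m <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- floor((starts + ends) / 2)
  idx <- integer(0)
  if (m >= 3L) {
    interior <- 2:(m - 1L)
    is_min <- r$values[interior] < r$values[interior - 1L] &
      r$values[interior] < r$values[interior + 1L]
    idx <- mids[interior][is_min]
  }
  if (include_endpoints && m >= 2L) {
    if (r$values[1L] < r$values[2L]) idx <- c(starts[1L], idx)
    if (r$values[m] < r$values[m - 1L]) idx <- c(idx, ends[m])
  }
  sort(idx)
}

# Topographic prominence of a local minimum at index i: the smaller of the
# maximum rises encountered walking left and right before meeting a value
# below x[i] (or the boundary).
min_prominence_at <- function(x, i) {
  v <- x[i]
  climb <- function(ix) {
    best <- v
    for (j in ix) {
      if (x[j] < v) break
      if (x[j] > best) best <- x[j]
    }
    best - v
  }
  left <- if (i > 1L) climb((i - 1L):1L) else Inf
  right <- if (i < length(x)) climb((i + 1L):length(x)) else Inf
  min(left, right)
}

#' Decompose an angle trace into whisker movement cycles
#'
#' Local minima are located throughout the signal (strict minima with plateau
#' midpoint tie-break; an endpoint strictly below its neighbour also counts,
#' so a single minimum-to-minimum arc forms one cycle). Consecutive minima
#' delimit cycles; within each cycle the amplitude is the maximum minus the
#' minimum angle, protraction spans minimum to maximum and retraction maximum
#' to cycle end. Minima with topographic prominence below `min_prominence`
#' are discarded, which suppresses spurious cycles from tracking jitter; the
#' default is one quarter of the trace's full range (0 disables filtering).
#'
#' @param trace a [whisker_trace()] (length >= 3).
#' @param min_prominence minimum prominence in degrees, or `NULL` for the
#'   adaptive default.
#' @return A data frame with one row per cycle: `start_index`, `min_index`,
#'   `max_index`, `end_index`, `amplitude` (degrees). Zero rows when fewer
#'   than two minima survive (a flat or paralyzed trace).
#' @export
detect_cycles <- function(trace, min_prominence = NULL) {
  stopifnot(inherits(trace, "fapa_whisker_trace"))
  x <- trace$angles
  if (length(x) < 3L) stop("cycle detection needs at least 3 frames")
  if (is.null(min_prominence)) min_prominence <- 0.25 * diff(range(x))
  mins <- local_minima(x)
  if (min_prominence > 0 && length(mins) > 0L) {
    keep <- vapply(mins, function(i) min_prominence_at(x, i) >= min_prominence,
                   logical(1L))
    mins <- mins[keep]
  }
  if (length(mins) < 2L) {
    return(data.frame(start_index = integer(0), min_index = integer(0),
                      max_index = integer(0), end_index = integer(0),
                      amplitude = numeric(0)))
  }
  n_cyc <- length(mins) - 1L
  out <- data.frame(start_index = mins[-length(mins)], min_index = NA_integer_,
                    max_index = NA_integer_, end_index = mins[-1L],
                    amplitude = NA_real_)
  for (i in seq_len(n_cyc)) {
    span <- out$start_index[i]:out$end_index[i]
    out$min_index[i] <- span[which.min(x[span])]
    out$max_index[i] <- span[which.max(x[span])]
    out$amplitude[i] <- max(x[span]) - min(x[span])
  }
  out
}

#' Classify cycle amplitudes as long or short
#'
#' The mean amplitude of the cycles inside the evaluation window (default the
#' first 2 s) is the session's amplitude threshold; cycles strictly above it
#' are long, cycles at or below it are short.
#'
#' @param cycles data frame from [detect_cycles()] (>= 1 cycle).
#' @param window_s evaluation window in seconds used to form the threshold.
#' @param fps frame rate; when `NULL`, all cycles form the threshold.
#' @return List with `threshold`, `long_count`, `short_count`, and
#'   `proportions` (named fractions summing to 1).
#' @export
classify_amplitudes <- function(cycles, window_s = 2, fps = NULL) {
  if (nrow(cycles) == 0L) stop("undefined amplitude classes: no cycles")
  amp <- cycles$amplitude
  in_window <- if (is.null(fps)) rep(TRUE, length(amp)) else {
    (cycles$start_index - 1L) / fps < window_s
  }
  if (!any(in_window)) in_window <- rep(TRUE, length(amp))
  threshold <- mean(amp[in_window])
  long <- amp > threshold
  list(threshold = threshold,
       long_count = sum(long),
       short_count = sum(!long),
       proportions = c(long = mean(long), short = mean(!long)))
}

#' Area under the curve of one movement cycle
#'
#' Trapezoidal integral of the angle signal over the cycle's time span, in
#' degree-seconds.
#'
#' @param trace a [whisker_trace()].
#' @param cycle one row of the [detect_cycles()] data frame.
#' @return Scalar AUC.
#' @export
cycle_auc <- function(trace, cycle) {
  stopifnot(inherits(trace, "fapa_whisker_trace"))
  idx <- cycle$start_index:cycle$end_index
  trapz((idx - 1L) / trace$fps, trace$angles[idx])
}

#' Short-time Fourier spectrogram of whisker movement
#'
#' Hann-windowed short-time Fourier power with a 0.5-s window and 50%
#' overlap; frequencies run from 0 to the Nyquist rate. By default each
#' window is mean-removed before transforming, so the large DC offset of a
#' rebased angle trace does not leak into (and mask) the low movement
#' frequencies.
#'
#' @param trace a [whisker_trace()].
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap.
#' @param demean remove each window's mean before the transform.
#' @return List with `times` (window centers, s), `frequencies` (Hz), and
#'   `power` (frequencies x times matrix).
#' @export
movement_spectrogram <- function(trace, window_s = 0.5, overlap = 0.5,
                                 demean = TRUE) {
  stopifnot(inherits(trace, "fapa_whisker_trace"))
  x <- trace$angles
  fs <- trace$fps
  win <- round(window_s * fs)
  if (length(x) < win) stop("trace shorter than one spectrogram window")
  hop <- max(1L, round(win * (1 - overlap)))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  nf <- win %/% 2L + 1L
  power <- matrix(0, nf, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + win - 1L)]
    if (demean) seg <- seg - mean(seg)
    seg <- seg * hann
    sp <- stats::fft(seg)
    power[, k] <- Mod(sp[seq_len(nf)])^2
  }
  list(times = (starts - 1L + win / 2) / fs,
       frequencies = (seq_len(nf) - 1L) * fs / win,
       power = power)
}
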