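# Shared in-code fixtures. Everything is generated at test time; no binary
# fixtures live on disk.

# A frame with a square marker blob centred at (row, col).
blob_frame <- function(h = 80, w = 80, row, col, half = 1L, value = 1,
                       background = 0) {
  f <- matrix(background, h, w)
  f[(row - half):(row + half), (col - half):(col + half)] <- value
  f
}

# Frames whose marker blob is placed so the centroid angle about `insertion`
# equals the angle implied by the (rounded) blob position; returns the list
# of frames and the angles actually realized by the rounded positions.
whisker_frames <- function(angles_deg, insertion = c(60, 20), radius = 30,
                           h = 80, w = 80) {
  frames <- list(); realized <- numeric(length(angles_deg))
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    r <- round(insertion[1] - radius * sin(th))
    c <- round(insertion[2] + radius * cos(th))
    frames[[i]] <- blob_frame(h, w, r, c)
    realized[i] <- atan2(insertion[1] - r, c - insertion[2]) * 180 / pi
  }
  list(frames = frames, realized = realized)
}

# Exhaustive-search changepoint oracle: piecewise-constant mean model with
# SSE cost, computed directly from segment means (independent of the
# cumulative-sum implementation path).
oracle_change_point <- function(x, penalty) {
  sse <- function(s) sum((s - mean(s))^2)
  n <- length(x)
  total <- sse(x)
  best_k <- NA_integer_; best_imp <- -Inf
  for (k in 2:n) {
    imp <- total - (sse(x[1:(k - 1)]) + sse(x[k:n]))
    if (imp > best_imp) { best_imp <- imp; best_k <- k }
  }
  if (best_imp > penalty) best_k else NA_integer_
}

# Deterministic piecewise-constant trace with optional jitter.
piecewise_trace <- function(levels, lens, jitter = 0) {
  x <- rep(levels, lens)
  if (jitter > 0) x <- x + stats::rnorm(length(x), 0, jitter)
  x
}
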