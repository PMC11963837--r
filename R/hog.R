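# Histogram-of-oriented-gradients frame descriptors and the scalar
# frame-difference (Diff) series that all paralysis decisions consume.
#
# Descriptor parameters follow the published processing: 8 unsigned
# orientation bins, 32-pixel square cells, one cell per block, and power-law
# (gamma) intensity compression applied before the gradients.

#' HOG descriptor parameters
#'
#' @param orientations number of unsigned orientation bins over 0-180 degrees.
#' @param cell_size square cell side in pixels.
#' @param cells_per_block cells per normalization block (1 = per-cell L2).
#' @param gamma exponent of the power-law intensity compression applied
#'   before gradient extraction (0.5 = square-root compression).
#' @return A list of class `fapa_hog_params`.
#' @export
hog_params <- function(orientations = 8L, cell_size = 32L, cells_per_block = 1L,
                       gamma = 0.5) {
  stopifnot(orientations >= 1L, cell_size >= 1L, cells_per_block >= 1L, gamma > 0)
  if (cells_per_block != 1L) {
    stop("only cells_per_block = 1 (per-cell normalization) is implemented")
  }
  structure(list(orientations = as.integer(orientations),
                 cell_size = as.integer(cell_size),
                 cells_per_block = as.integer(cells_per_block),
                 gamma = gamma),
            class = "fapa_hog_params")
}

#' Length of a HOG vector for a given frame geometry
#' @param height,width frame size in pixels.
#' @param params a [hog_params()].
#' @return Integer vector length `floor(H/cell) * floor(W/cell) * orientations`.
#' @export
hog_length <- function(height, width, params = hog_params()) {
  (height %/% params$cell_size) * (width %/% params$cell_size) * params$orientations
}

#' Compute the HOG descriptor of one frame
#'
#' Gamma compression is applied first, gradients are taken by central
#' differences with replicated borders, unsigned orientations (0-180 degrees)
#' are histogrammed per cell weighted by gradient magnitude (nearest-bin
#' assignment), and each cell histogram is L2-normalized (zero-gradient cells
#' stay zero). The vector is flattened cell-row-major, bins contiguous per
#' cell.
#'
#' @param frame grayscale matrix, intensities in `[0, 1]`.
#' @param params a [hog_params()].
#' @return Numeric vector of length [hog_length()].
#' @export
compute_hog <- function(frame, params = hog_params()) {
  cs <- params$cell_size
  nb <- params$orientations
  h <- nrow(frame); w <- ncol(frame)
  if (h < cs || w < cs) {
    stop("frame (", h, " x ", w, ") smaller than one ", cs, "-px cell")
  }
  I <- frame^params$gamma
  gx <- (I[, c(2:w, w), drop = FALSE] - I[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (I[c(2:h, h), , drop = FALSE] - I[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- floor(ori / (180 / nb))
  bin[bin >= nb] <- nb - 1L

  nr <- h %/% cs; nc <- w %/% cs
  rows <- seq_len(nr * cs); cols <- seq_len(nc * cs)
  i <- rep.int(rows, length(cols))
  j <- rep(cols, each = length(rows))
  cell_id <- ((i - 1L) %/% cs) * nc + ((j - 1L) %/% cs)   # row-major cells
  feat <- cell_id * nb + bin[cbind(i, j)] + 1L

  L <- nr * nc * nb
  vec <- numeric(L)
  acc <- rowsum(as.numeric(mag[cbind(i, j)]), feat)
  vec[as.integer(rownames(acc))] <- acc

  m <- matrix(vec, nrow = nb)                              # columns = cells
  norms <- sqrt(colSums(m^2))
  keep <- norms > 1e-12
  m[, keep] <- sweep(m[, keep, drop = FALSE], 2L, norms[keep], `/`)
  as.numeric(m)
}

#' Per-frame HOG series of a stack
#'
#' @param stack a [frame_stack()].
#' @param params a [hog_params()].
#' @param zone zone label carried as metadata (`"A"`, `"M"`, `"P"` or
#'   `"whole"`).
#' @return Object of class `fapa_hog_series`: list with `vectors` (frames x L
#'   matrix), `params`, `zone`.
#' @export
hog_series <- function(stack, params = hog_params(), zone = "whole") {
  stopifnot(inherits(stack, "fapa_frames"))
  n <- n_frames(stack)
  L <- hog_length(dim(stack$frames)[1L], dim(stack$frames)[2L], params)
  vectors <- matrix(0, n, L)
  for (i in seq_len(n)) vectors[i, ] <- compute_hog(get_frame(stack, i), params)
  structure(list(vectors = vectors, params = params, zone = zone),
            class = "fapa_hog_series")
}

#' Scalar frame-difference (Diff) series
#'
#' Reduces each frame's HOG descriptor to its distance from the first frame's
#' descriptor: `Diff(x) = ||HOG(frame 1) - HOG(frame x)||`. By construction
#' `Diff(1) = 0`; larger values mean more facial movement. The published
#' frame subtraction yields a vector; the reduction to a scalar uses the
#' Euclidean norm by default (symmetric, zero iff the descriptors are
#' identical), with an L1 alternative.
#'
#' @param series a `fapa_hog_series` or a frames x L numeric matrix.
#' @param metric `"L2"` (default) or `"L1"`.
#' @return Numeric vector of per-frame differences, `[1] == 0`.
#' @export
hog_diff_series <- function(series, metric = c("L2", "L1")) {
  metric <- match.arg(metric)
  vectors <- if (inherits(series, "fapa_hog_series")) series$vectors else as.matrix(series)
  if (nrow(vectors) < 1L) stop("need at least one frame")
  delta <- sweep(vectors, 2L, vectors[1L, ])
  d <- switch(metric,
              L2 = sqrt(rowSums(delta^2)),
              L1 = rowSums(abs(delta)))
  d[1L] <- 0
  d
}

#' Session movement summary
#'
#' Arithmetic mean of a session's Diff series: the per-session scalar fed to
#' the paralysis thresholds. Larger values mean the mouse moved its face
#' more.
#'
#' @param diff numeric Diff series.
#' @return Scalar mean.
#' @export
session_summary <- function(diff) {
  stopifnot(length(diff) >= 1L)
  mean(diff)
}

#' Min-max normalization of per-session summaries
#'
#' The "N" of the normalized decision models: a mouse's session summaries are
#' rescaled to `[0, 1]` so thresholds compare across mice. Z-score
#' normalization is available as an alternative.
#'
#' @param values per-session scalars (length >= 2, not all equal).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Normalized values.
#' @export
normalize_sessions <- function(values, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("normalization needs at least 2 sessions")
  rng <- range(values)
  if (diff(rng) < .Machine$double.eps) {
    stop("degenerate normalization: all session values are equal")
  }
  switch(method,
         minmax = (values - rng[1L]) / diff(rng),
         zscore = (values - mean(values)) / stats::sd(values))
}
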