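# Facial-expression prototypes: the basal (resting-face) HOG template, the
# stimulus-evoked emotional prototypes, and per-frame similarity traces used
# to detect evoked expressions.

#' HOG prototype (averaged facial template)
#'
#' @param vector averaged HOG vector.
#' @param label one of `"basal"`, `"pleasure"`, `"disgust"`, `"neutral"`.
#' @param n_source_frames number of frames averaged.
#' @param params the [hog_params()] behind the vectors.
#' @return An object of class `fapa_prototype`.
#' @export
facial_prototype <- function(vector, label, n_source_frames, params = hog_params()) {
  stopifnot(n_source_frames >= 1L)
  structure(list(vector = as.numeric(vector), label = label,
                 n_source_frames = as.integer(n_source_frames), params = params),
            class = "fapa_prototype")
}

hog_matrix <- function(hogs) {
  if (inherits(hogs, "fapa_hog_series")) hogs$vectors else as.matrix(hogs)
}

#' Basal facial prototype
#'
#' Element-wise mean of the HOG vectors of the `n` frames immediately
#' preceding oral stimulation (default 250 frames).
#'
#' @param hogs a `fapa_hog_series` or frames x L matrix from the
#'   pre-stimulation period, ordered so the last rows are closest to the
#'   stimulus.
#' @param n number of frames to average (the last `n` pre-stimulation
#'   frames).
#' @return A `"basal"` [facial_prototype()].
#' @export
basal_prototype <- function(hogs, n = 250L) {
  m <- hog_matrix(hogs)
  if (nrow(m) < n) {
    stop("basal prototype needs ", n, " pre-stimulation frames, only ",
         nrow(m), " available")
  }
  rows <- (nrow(m) - n + 1L):nrow(m)
  params <- if (inherits(hogs, "fapa_hog_series")) hogs$params else hog_params()
  facial_prototype(colMeans(m[rows, , drop = FALSE]), "basal", n, params)
}

#' Per-frame similarity to a prototype
#'
#' Pearson correlation between each frame's HOG vector and the prototype
#' vector, computed across vector elements. Frames with a constant HOG
#' vector have undefined correlation and are emitted as `NA` with a warning.
#'
#' @param hogs a `fapa_hog_series` or frames x L matrix.
#' @param proto a [facial_prototype()] (non-constant).
#' @param event_time optional stimulus onset in seconds, carried as metadata.
#' @param fps optional frame rate, carried as metadata.
#' @return Object of class `fapa_similarity`: list with `r` (per-frame
#'   correlations in `[-1, 1]`), `event_time`, `fps`, `label`.
#' @export
similarity_trace <- function(hogs, proto, event_time = NA_real_, fps = NA_real_) {
  stopifnot(inherits(proto, "fapa_prototype"))
  m <- hog_matrix(hogs)
  if (ncol(m) != length(proto$vector)) stop("HOG vector length mismatch with prototype")
  if (stats::sd(proto$vector) < .Machine$double.eps) {
    stop("prototype vector is constant; correlation undefined")
  }
  sds <- apply(m, 1L, stats::sd)
  r <- rep(NA_real_, nrow(m))
  ok <- sds > .Machine$double.eps
  if (any(!ok)) warning(sum(!ok), " frame(s) with constant HOG vector: similarity NA")
  if (any(ok)) {
    r[ok] <- as.numeric(stats::cor(t(m[ok, , drop = FALSE]), proto$vector))
  }
  structure(list(r = r, event_time = event_time, fps = fps, label = proto$label),
            class = "fapa_similarity")
}

#' Emotional prototype from stimulation frames
#'
#' The `k` stimulation frames least correlated with the basal prototype
#' (lowest Pearson r, ties broken by earlier frame index) are averaged
#' element-wise into the emotional prototype: pleasure for sucrose, disgust
#' for quinine, neutral for water.
#'
#' @param hogs_stim a `fapa_hog_series` or frames x L matrix of stimulation
#'   frames.
#' @param basal the basal [facial_prototype()].
#' @param k number of most-different frames to average (default 10).
#' @param label prototype label (`"pleasure"`, `"disgust"`, `"neutral"`).
#' @return A [facial_prototype()].
#' @export
emotional_prototype <- function(hogs_stim, basal, k = 10L, label = "pleasure") {
  m <- hog_matrix(hogs_stim)
  if (nrow(m) < k) stop("emotional prototype needs >= ", k, " stimulation frames")
  r <- similarity_trace(m, basal)$r
  r[is.na(r)] <- Inf                     # constant frames never selected
  sel <- order(r, seq_along(r))[seq_len(k)]
  params <- if (inherits(hogs_stim, "fapa_hog_series")) hogs_stim$params else basal$params
  facial_prototype(colMeans(m[sel, , drop = FALSE]), label, k, params)
}

#' Stimulus analysis window in frames
#'
#' Frame indices spanning the pre/post analysis window around a stimulus
#' frame; the published expression analysis uses 5 s before and 5 s after
#' delivery at 30 fps (300 frames).
#'
#' @param event_frame frame index of stimulus onset (first post-stimulus
#'   frame).
#' @param pre_s,post_s window extents in seconds.
#' @param fps frame rate.
#' @return Integer vector of frame indices of length `(pre_s + post_s) * fps`.
#' @export
stimulus_window <- function(event_frame, pre_s = 5, post_s = 5, fps = 30) {
  n_pre <- round(pre_s * fps); n_post <- round(post_s * fps)
  (event_frame - n_pre):(event_frame + n_post - 1L)
}

#' Pre/post expression-onset summary of a similarity trace
#'
#' Mean similarity in the windows before and after the stimulus and their
#' difference; a positive difference means the face moved toward the
#' prototype after the stimulus. Windows extending past the trace are
#' truncated with a warning and flagged.
#'
#' @param trace a [similarity_trace()] with `event_time` and `fps` set.
#' @param window_s window length on each side in seconds (default 10).
#' @return List with `pre_mean`, `post_mean`, `difference`, `label`,
#'   `truncated`.
#' @export
expression_onset_report <- function(trace, window_s = 10) {
  stopifnot(inherits(trace, "fapa_similarity"))
  if (is.na(trace$event_time) || is.na(trace$fps)) {
    stop("trace needs event_time and fps for an onset report")
  }
  n <- length(trace$r)
  ev <- floor(trace$event_time * trace$fps) + 1L
  if (ev < 1L || ev > n) stop("event_time outside the trace")
  win <- round(window_s * trace$fps)
  pre_idx <- max(1L, ev - win):(ev - 1L)
  post_idx <- ev:min(n, ev + win - 1L)
  truncated <- (ev - win < 1L) || (ev + win - 1L > n)
  if (truncated) warning("analysis window truncated at the trace boundary")
  pre <- mean(trace$r[pre_idx], na.rm = TRUE)
  post <- mean(trace$r[post_idx], na.rm = TRUE)
  list(pre_mean = pre, post_mean = post, difference = post - pre,
       label = trace$label, truncated = truncated)
}
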