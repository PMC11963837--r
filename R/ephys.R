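# Spike-train statistics: peristimulus time histograms, baseline z-scores,
# and cross-covariance between firing and behavioral traces. Spike sorting
# happens upstream; trains arrive as sorted spike times.

#' Sorted spike train
#'
#' @param spike_times spike times in seconds, within `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param unit_id unit identifier.
#' @return An object of class `fapa_spikes`.
#' @export
spike_train <- function(spike_times, duration, unit_id = 1L) {
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) stop("spike times must not contain NA")
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  if (length(spike_times) > 0L &&
      (spike_times[1L] < 0 || spike_times[length(spike_times)] > duration)) {
    stop("spike times must lie within [0, duration]")
  }
  structure(list(spike_times = spike_times, duration = duration,
                 unit_id = unit_id),
            class = "fapa_spikes")
}

#' Bin a spike train into counts
#'
#' @param train a [spike_train()].
#' @param bin_s bin width in seconds.
#' @return Integer vector of counts over `floor(duration / bin_s)` bins.
#' @export
bin_spikes <- function(train, bin_s) {
  stopifnot(inherits(train, "fapa_spikes"), bin_s > 0)
  nb <- floor(train$duration / bin_s)
  idx <- floor(train$spike_times / bin_s) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

#' Peristimulus time histogram
#'
#' Event-aligned spike counts in 100-ms bins, averaged over events and
#' converted to rate (spikes/s). Events whose window falls outside the
#' recording are dropped with a warning.
#'
#' @param train a [spike_train()].
#' @param events event times in seconds (>= 1).
#' @param pre_s,post_s window extents around each event (default 10 s each).
#' @param bin_s bin width (default 0.1 s).
#' @return Object of class `fapa_psth`: list with `rate` (spikes/s per bin),
#'   `counts` (summed counts per bin), `bin_centers` (s, 0 = event),
#'   `bin_width`, `window`, `n_events`.
#' @export
psth <- function(train, events, pre_s = 10, post_s = 10, bin_s = 0.1) {
  stopifnot(inherits(train, "fapa_spikes"), length(events) >= 1L)
  ok <- events - pre_s >= 0 & events + post_s <= train$duration
  if (!all(ok)) {
    warning(sum(!ok), " event(s) dropped: window exceeds the recording")
    events <- events[ok]
  }
  if (length(events) == 0L) stop("no event window fits inside the recording")
  nb <- round((pre_s + post_s) / bin_s)
  edges <- -pre_s + (0:nb) * bin_s
  counts <- integer(nb)
  for (ev in events) {
    rel <- train$spike_times - ev
    rel <- rel[rel >= edges[1L] & rel < edges[nb + 1L]]
    if (length(rel) > 0L) {
      counts <- counts + tabulate(findInterval(rel, edges), nbins = nb)
    }
  }
  structure(list(rate = counts / (length(events) * bin_s),
                 counts = counts,
                 bin_centers = edges[-(nb + 1L)] + bin_s / 2,
                 bin_width = bin_s,
                 window = c(pre_s = pre_s, post_s = post_s),
                 n_events = length(events)),
            class = "fapa_psth")
}

#' Baseline z-score of a PSTH
#'
#' `z = (rate - m) / sd` with mean and sample standard deviation taken from
#' the pre-event baseline bins (default the 10 s before the event). A
#' display clip range (e.g. `c(-2, 2)`) only affects the `z_clipped` copy;
#' raw z values are always retained.
#'
#' @param p a [psth()] with at least `baseline_s` of pre-event bins.
#' @param baseline_s baseline extent before the event (default 10 s).
#' @param clip optional length-2 display clipping range.
#' @return Object of class `fapa_ztrace`: list with `z`, `z_clipped`
#'   (or `NULL`), `bin_centers`, `baseline_mean`, `baseline_sd`.
#' @export
zscore_psth <- function(p, baseline_s = 10, clip = NULL) {
  stopifnot(inherits(p, "fapa_psth"))
  base <- p$bin_centers < 0 & p$bin_centers >= -baseline_s
  if (sum(base) < 2L) stop("PSTH lacks a ", baseline_s, "-s pre-event baseline")
  m <- mean(p$rate[base])
  s <- stats::sd(p$rate[base])
  if (s < .Machine$double.eps) {
    stop("zero baseline standard deviation; use a longer baseline")
  }
  z <- (p$rate - m) / s
  structure(list(z = z,
                 z_clipped = if (!is.null(clip)) pmin(pmax(z, clip[1L]), clip[2L]),
                 bin_centers = p$bin_centers,
                 baseline_mean = m, baseline_sd = s),
            class = "fapa_ztrace")
}

#' Normalized cross-covariance of two equally sampled series
#'
#' Mean-removed cross-covariance normalized by the square root of the
#' product of the zero-lag autocovariances, so identical signals score 1 at
#' lag 0. A positive lag means `x` leads `y` (x at time t matches y at
#' t + lag).
#'
#' @param x,y numeric series of equal length and sampling rate, both
#'   non-constant.
#' @param max_lag maximum lag in samples.
#' @param normalize set `FALSE` for the raw (unnormalized) covariance.
#' @return List with `lag` (samples, -max_lag..max_lag) and `value`.
#' @export
cross_covariance <- function(x, y, max_lag, normalize = TRUE) {
  stopifnot(length(x) == length(y), max_lag >= 0, length(x) > max_lag)
  if (stats::sd(x) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps) {
    stop("cross-covariance of a constant series is undefined")
  }
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  lags <- -max_lag:max_lag
  v <- vapply(lags, function(l) {
    if (l >= 0) sum(xc[seq_len(n - l)] * yc[seq_len(n - l) + l])
    else sum(xc[seq_len(n + l) - l] * yc[seq_len(n + l)])
  }, numeric(1L))
  if (normalize) v <- v / sqrt(sum(xc^2) * sum(yc^2))
  list(lag = lags, value = v)
}

#' Correlation between two cross-covariance traces
#'
#' Pearson correlation across lags, used to ask whether expression-aligned
#' and movement-aligned neural cross-covariances carry the same structure.
#'
#' @param cc_expression,cc_movement results of [cross_covariance()] on the
#'   same lag grid (or bare numeric vectors of equal length).
#' @return Pearson r.
#' @export
covariance_correlation <- function(cc_expression, cc_movement) {
  a <- if (is.list(cc_expression)) cc_expression$value else cc_expression
  b <- if (is.list(cc_movement)) cc_movement$value else cc_movement
  if (length(a) != length(b)) stop("cross-covariance traces differ in length")
  stats::cor(a, b)
}
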