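# Painted-whisker tracking: marker segmentation, mask cleanup, angle
# extraction, and assembly of the per-frame angle trace.
#
# A single whisker on each side is marked with acrylic paint; frames are
# binarized by color distance to the paint reference, the mask is cleaned of
# stray pixels within a 5-px margin of the main area, and the whisker angle
# is the angle of the mask centroid about the insertion point in the
# whiskerpad. Protraction (forward sweep) increases the angle. The session
# minimum is rebased to 0 degrees.

#' Per-frame whisker angle trace
#'
#' @param angles numeric angles in degrees, one per frame.
#' @param fps frames per second.
#' @param insertion optional (row, col) insertion point used to extract the
#'   angles.
#' @param rebased logical; `TRUE` when the session minimum has been shifted
#'   to exactly 0 degrees.
#' @return An object of class `fapa_whisker_trace`.
#' @export
whisker_trace <- function(angles, fps, insertion = NULL, rebased = FALSE) {
  if (length(angles) < 2L) stop("a whisker trace needs at least 2 frames")
  if (!all(is.finite(angles))) stop("whisker angles must be finite")
  if (rebased && abs(min(angles)) > 1e-9) {
    stop("a rebased trace must have minimum exactly 0")
  }
  structure(list(angles = as.numeric(angles), fps = fps,
                 insertion = insertion, rebased = rebased),
            class = "fapa_whisker_trace")
}

#' Rebase a trace so the session minimum is 0 degrees
#' @param trace a [whisker_trace()].
#' @return The rebased trace.
#' @export
rebase_trace <- function(trace) {
  whisker_trace(trace$angles - min(trace$angles), trace$fps,
                insertion = trace$insertion, rebased = TRUE)
}

#' @export
print.fapa_whisker_trace <- function(x, ...) {
  cat(sprintf("<fapa_whisker_trace> %d frames @ %.6g fps, range [%.3g, %.3g] deg%s\n",
              length(x$angles), x$fps, min(x$angles), max(x$angles),
              if (x$rebased) ", rebased" else ""))
  invisible(x)
}

#' Segment the painted whisker marker
#'
#' Binarizes a frame by per-channel Chebyshev distance to the paint reference
#' color: a pixel is marker iff every channel is within `tolerance` of the
#' reference.
#'
#' @param frame grayscale matrix or `H x W x 3` RGB array in `[0, 1]`.
#' @param color_ref scalar intensity (gray) or RGB triple matching `frame`.
#' @param tolerance per-channel distance (>= 0), same scale as intensities.
#' @return Logical mask. An empty mask is legal and returned as is.
#' @export
segment_marker <- function(frame, color_ref, tolerance) {
  stopifnot(tolerance >= 0)
  if (is.matrix(frame)) {
    abs(frame - color_ref[1L]) <= tolerance
  } else {
    stopifnot(length(dim(frame)) == 3L, dim(frame)[3L] == length(color_ref))
    d <- abs(frame[, , 1L] - color_ref[1L])
    for (k in 2:dim(frame)[3L]) d <- pmax(d, abs(frame[, , k] - color_ref[k]))
    d <= tolerance
  }
}

#' Remove stray pixels around the segmented marker
#'
#' Keeps the largest connected component of the mask plus any marker pixels
#' within `radius` pixels of it; isolated speckles farther away are dropped.
#' This realizes the "eliminate pixels outside the required area (within a
#' range of 5 pixels around)" cleanup rule and, unlike a plain morphological
#' opening, never erodes the principal blob itself.
#'
#' @param mask logical matrix.
#' @param radius cleanup margin in pixels (default 5).
#' @return Cleaned logical mask; an all-false mask is returned with a
#'   warning.
#' @export
clean_mask <- function(mask, radius = 5) {
  stopifnot(radius >= 1)
  if (!any(mask)) {
    warning("empty mask: no marker pixels to clean")
    return(mask)
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  core <- lab == which.max(sizes)
  mask & dilate_mask(core, radius)
}

#' Whisker angle from a marker mask
#'
#' Angle of the mask centroid about the insertion point, measured
#' counterclockwise from the +x (column) axis; image rows grow downward, so
#' the row difference is negated: `atan2(ins_row - centroid_row,
#' centroid_col - ins_col)`, in degrees.
#'
#' @param mask logical matrix with at least one marker pixel.
#' @param insertion numeric `(row, col)` whiskerpad insertion point.
#' @return Angle in degrees.
#' @export
whisker_angle <- function(mask, insertion) {
  if (!any(mask)) stop("missing marker: empty mask")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- unname(colMeans(idx))
  unname(atan2(insertion[1L] - centroid[1L], centroid[2L] - insertion[2L]) * 180 / pi)
}

#' Build the whisker angle trace of a session
#'
#' Runs segmentation, cleanup, and angle extraction per frame, linearly
#' interpolates frames with a missing marker (up to `max_gap` consecutive
#' frames; edge gaps take the nearest valid angle), and rebases the trace so
#' the session minimum is exactly 0 degrees.
#'
#' @param stack a [frame_stack()] or list of frames (matrices or RGB arrays).
#' @param color_ref marker reference color (see [segment_marker()]).
#' @param tolerance per-channel color tolerance.
#' @param insertion `(row, col)` insertion point.
#' @param fps frame rate when `stack` is a bare list of frames.
#' @param radius cleanup margin passed to [clean_mask()].
#' @param max_gap longest run of missing-marker frames to interpolate.
#' @return A rebased [whisker_trace()].
#' @export
build_trace <- function(stack, color_ref, tolerance, insertion,
                        fps = NULL, radius = 5, max_gap = 5L) {
  if (inherits(stack, "fapa_frames")) {
    frames <- lapply(seq_len(n_frames(stack)), function(i) get_frame(stack, i))
    fps <- fps %||% stack$fps
  } else {
    frames <- stack
    if (is.null(fps)) stop("'fps' is required when frames are given as a list")
  }
  n <- length(frames)
  if (n < 2L) stop("a session needs at least 2 frames")
  angles <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mask <- segment_marker(frames[[i]], color_ref, tolerance)
    if (any(mask)) mask <- suppressWarnings(clean_mask(mask, radius))
    if (any(mask)) angles[i] <- whisker_angle(mask, insertion)
  }
  missing <- is.na(angles)
  if (all(missing)) stop("tracking failure: marker never detected")
  if (mean(missing) > 0.5) {
    stop("tracking failure: marker missing in ", round(100 * mean(missing)),
         "% of frames")
  }
  if (any(missing)) {
    runs <- rle(missing)
    if (any(runs$lengths[runs$values] > max_gap)) {
      stop("tracking failure: more than ", max_gap,
           " consecutive frames without marker")
    }
    angles <- stats::approx(which(!missing), angles[!missing], xout = seq_len(n),
                            rule = 2L)$y
  }
  whisker_trace(angles - min(angles), fps = fps, insertion = insertion,
                rebased = TRUE)
}
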