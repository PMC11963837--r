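# Frame containers, plain-text frame I/O, and face-zone cropping.
#
# Frames are grayscale matrices with intensities in [0, 1], stored as an
# H x W x N array. Pixel coordinates are (row, col), 0-based in all on-disk
# configuration, origin at the top-left; zone rectangles are half-open.

#' Ordered stack of grayscale video frames
#'
#' Container for an ordered sequence of equally sized grayscale frames with a
#' frame rate. Timestamps are derived as `(index - 1) / fps`.
#'
#' @param frames an `H x W x N` numeric array, a single matrix, or a list of
#'   equally sized matrices, intensities in `[0, 1]`.
#' @param fps frames per second (> 0).
#' @param source_id free-text provenance label.
#' @return An object of class `fapa_frames` with elements `frames`, `fps`,
#'   `source_id` and `timestamps`.
#' @export
frame_stack <- function(frames, fps, source_id = "") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share the same height x width")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("'frames' must be an H x W x N array, matrix, or list of matrices")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) stop("'fps' must be a positive scalar")
  if (dim(frames)[3L] < 1L) stop("a frame stack needs at least one frame")
  rng <- range(frames)
  if (!all(is.finite(rng)) || rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    stop("frame intensities must be finite and within [0, 1]")
  }
  n <- dim(frames)[3L]
  structure(
    list(frames = frames, fps = fps, source_id = source_id,
         timestamps = (seq_len(n) - 1L) / fps),
    class = "fapa_frames")
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]

#' Extract one frame
#' @param stack a [frame_stack()].
#' @param i frame index (1-based).
#' @return The i-th frame as a matrix.
#' @export
get_frame <- function(stack, i) stack$frames[, , i]

#' @export
print.fapa_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fapa_frames> %d frame(s), %d x %d px, %.6g fps, %.3g s\n",
              d[3L], d[1L], d[2L], x$fps, d[3L] / x$fps))
  invisible(x)
}

#' Convert an RGB array to grayscale
#'
#' Luminance conversion with ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param rgb an `H x W x 3` array in `[0, 1]`, or a matrix (returned as is).
#' @return A grayscale matrix.
#' @export
rgb_to_gray <- function(rgb) {
  if (is.matrix(rgb)) return(rgb)
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

#' Read an ASCII portable graymap (PGM, magic "P2")
#'
#' @param path file path.
#' @return A matrix with intensities scaled to `[0, 1]`.
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tok) < 4L || tok[1L] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L]); maxv <- as.numeric(tok[4L])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != h * w) stop("corrupt PGM, expected ", h * w, " pixels, got ", length(px))
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxv
}

#' Write a matrix as an ASCII PGM (P2) file
#'
#' @param frame matrix with intensities in `[0, 1]`.
#' @param path output path.
#' @param maxval maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(frame, path, maxval = 255L) {
  v <- round(pmin(pmax(frame, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), as.character(maxval)), con)
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Load a session's frames from disk
#'
#' Reads a directory of lexically ordered ASCII PGM frames into a
#' [frame_stack()]. Compressed video containers (MP4/AVI) are not supported in
#' this build; sessions are exchanged as frame directories.
#'
#' @param path directory containing `*.pgm` frames.
#' @param fps frame rate to attach (default 30, the face-camera rate).
#' @param fps_override optional frame rate taking precedence over `fps`.
#' @return A [frame_stack()].
#' @export
extract_frames <- function(path, fps = 30, fps_override = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (!dir.exists(path)) {
    stop("cannot decode '", path, "': compressed video is not supported; ",
         "supply a directory of ASCII PGM frames")
  }
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) stop("empty input: no .pgm frames under ", path)
  frames <- lapply(files, read_pgm)
  frame_stack(frames, fps = fps_override %||% fps, source_id = path)
}

#' Write a frame stack as a directory of PGM frames
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(stack)
  for (i in seq_len(n)) {
    write_pgm(get_frame(stack, i), file.path(dir, sprintf("frame_%06d.pgm", i)))
  }
  invisible(dir)
}

#' Anatomical landmark set for frame alignment
#'
#' Four (row, col) pixel coordinates: two on the eye and two on the nose,
#' used as control points for session-to-reference registration.
#'
#' @param eye_1,eye_2,nose_1,nose_2 numeric `(row, col)` pairs (0-based or
#'   1-based is the caller's convention; alignment only uses relative
#'   geometry, the same convention must be used for both sets).
#' @return A 4 x 2 matrix of class `fapa_landmarks` with labelled rows.
#' @export
landmark_set <- function(eye_1, eye_2, nose_1, nose_2) {
  pts <- rbind(eye_1 = eye_1, eye_2 = eye_2, nose_1 = nose_1, nose_2 = nose_2)
  if (ncol(pts) != 2L || nrow(pts) != 4L || !all(is.finite(pts))) {
    stop("a landmark set is four finite (row, col) points")
  }
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  if (any(d < .Machine$double.eps)) stop("landmark points must be pairwise distinct")
  structure(pts, class = "fapa_landmarks")
}

#' Face zone crop rectangles
#'
#' Three axis-aligned rectangles labelled anterior (A: nose, lips, mouth,
#' whiskers), middle (M: cheek, eye) and posterior (P: ear). Rectangles are
#' 0-based, half-open `(row_start, row_end, col_start, col_end)`.
#'
#' @param A,M,P integer vectors `c(row_start, row_end, col_start, col_end)`.
#' @return A named list of class `fapa_zones`.
#' @export
zone_config <- function(A, M, P) {
  zones <- list(A = as.numeric(A), M = as.numeric(M), P = as.numeric(P))
  for (z in names(zones)) {
    r <- zones[[z]]
    if (length(r) != 4L || any(!is.finite(r)) || r[1L] < 0 || r[3L] < 0 ||
        r[2L] <= r[1L] || r[4L] <= r[3L]) {
      stop("zone ", z, " must be a non-empty half-open rectangle ",
           "(row_start, row_end, col_start, col_end)")
    }
  }
  structure(zones, class = "fapa_zones")
}

#' Default vertical-band zone layout
#'
#' Splits the frame into three equal-width vertical bands A | M | P, the
#' lateral-face layout used by the synthetic generator.
#'
#' @param height,width frame geometry in pixels.
#' @return A [zone_config()].
#' @export
default_zone_config <- function(height, width) {
  w3 <- width %/% 3L
  zone_config(A = c(0, height, 0, w3),
              M = c(0, height, w3, 2L * w3),
              P = c(0, height, 2L * w3, width))
}

#' Crop the three face zones out of a frame
#'
#' @param frame a grayscale matrix.
#' @param zones a [zone_config()].
#' @return Named list of sub-matrices `A`, `M`, `P`.
#' @export
crop_zones <- function(frame, zones) {
  stopifnot(inherits(zones, "fapa_zones"))
  h <- nrow(frame); w <- ncol(frame)
  out <- lapply(zones, function(r) {
    if (r[2L] > h || r[4L] > w) stop("zone rectangle out of frame bounds")
    frame[(r[1L] + 1L):r[2L], (r[3L] + 1L):r[4L], drop = FALSE]
  })
  names(out) <- names(zones)
  out
}

#' Crop every frame of a stack into per-zone stacks
#'
#' @param stack a [frame_stack()].
#' @param zones a [zone_config()].
#' @return Named list of three [frame_stack()]s.
#' @export
crop_stack <- function(stack, zones) {
  stopifnot(inherits(stack, "fapa_frames"), inherits(zones, "fapa_zones"))
  h <- dim(stack$frames)[1L]; w <- dim(stack$frames)[2L]
  out <- lapply(zones, function(r) {
    if (r[2L] > h || r[4L] > w) stop("zone rectangle out of frame bounds")
    frame_stack(stack$frames[(r[1L] + 1L):r[2L], (r[3L] + 1L):r[4L], , drop = FALSE],
                fps = stack$fps, source_id = stack$source_id)
  })
  names(out) <- names(zones)
  out
}
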