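# Landmark-based frame registration.
#
# Each session video is registered onto a reference (baseline) video through
# the four anatomical control points (two eye, two nose). The default
# transform family is a similarity (rotation + translation + uniform scale):
# the head-fixed face is close to rigid, and with only four control points a
# similarity fit is less prone to shear artifacts than a full affine. An
# affine fit is available behind `method = "affine"`.

#' Least-squares similarity transform between point sets
#'
#' Umeyama closed-form fit of `dst ~ s * R %*% src + t` over paired (row, col)
#' points.
#'
#' @param src,dst n x 2 matrices of paired (row, col) coordinates.
#' @return List with `R` (2 x 2 rotation), `s` (scale), `t` (length-2
#'   translation), and `angle_deg` (rotation angle, counterclockwise in
#'   (row, col) axes).
#' @export
fit_similarity <- function(src, dst) {
  src <- unclass(src); dst <- unclass(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst), nrow(src) >= 2L)
  n <- nrow(src)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  Xs <- sweep(src, 2L, mu_s); Xd <- sweep(dst, 2L, mu_d)
  var_s <- sum(Xs^2) / n
  if (var_s < 1e-12) stop("singular transform: source landmarks are coincident")
  Sigma <- crossprod(Xd, Xs) / n
  sv <- svd(Sigma)
  if (min(sv$d) < 1e-9 * max(sv$d, 1e-300)) {
    stop("singular transform: landmarks are degenerate (collinear or coincident)")
  }
  S <- diag(2L)
  if (det(sv$u) * det(sv$v) < 0) S[2L, 2L] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- sum(diag(S %*% diag(sv$d, 2L))) / var_s
  t_vec <- as.numeric(mu_d - s * (R %*% mu_s))
  list(R = R, s = s, t = t_vec,
       angle_deg = atan2(R[2L, 1L], R[1L, 1L]) * 180 / pi)
}

# Affine least-squares fit: dst = A src + t (6 parameters).
fit_affine <- function(src, dst) {
  src <- unclass(src); dst <- unclass(dst)
  stopifnot(nrow(src) >= 3L)
  X <- cbind(src, 1)
  coef <- tryCatch(qr.solve(X, dst), error = function(e) {
    stop("singular transform: landmarks are degenerate for an affine fit")
  })
  list(A = t(coef[1:2, , drop = FALSE]), t = as.numeric(coef[3L, ]))
}

#' Apply a fitted transform to points
#'
#' @param tf a transform from [fit_similarity()] or an affine fit.
#' @param pts n x 2 matrix of (row, col) points.
#' @return Transformed n x 2 matrix.
#' @export
transform_points <- function(tf, pts) {
  pts <- unclass(pts)
  A <- if (!is.null(tf$A)) tf$A else tf$s * tf$R
  sweep(pts %*% t(A), 2L, tf$t, `+`)
}

# Bilinear sampling of `frame` at fractional (row, col) coordinates; points
# outside the field are filled with 0.
sample_bilinear <- function(frame, rc) {
  h <- nrow(frame); w <- ncol(frame)
  r <- rc[, 1L]; cc <- rc[, 2L]
  r0 <- floor(r); c0 <- floor(cc)
  dr <- r - r0; dc <- cc - c0
  fetch <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- frame[cbind(ri[ok], ci[ok])]
    v
  }
  fetch(r0, c0) * (1 - dr) * (1 - dc) +
    fetch(r0, c0 + 1) * (1 - dr) * dc +
    fetch(r0 + 1, c0) * dr * (1 - dc) +
    fetch(r0 + 1, c0 + 1) * dr * dc
}

#' Align a frame stack onto a reference landmark frame
#'
#' Warps every frame by the least-squares transform mapping the session
#' landmarks onto the reference landmarks. One transform is fitted per session
#' (the head-fixed default); passing a list of per-frame landmark sets fits
#' one transform per frame. Output geometry equals the reference geometry and
#' out-of-field pixels are filled with 0. Resampling is bilinear.
#'
#' @param stack a [frame_stack()].
#' @param landmarks a [landmark_set()] located on the session frames, or a
#'   list of one landmark set per frame.
#' @param reference a [landmark_set()] located on the reference frame.
#' @param ref_dim `c(height, width)` of the reference frame (defaults to the
#'   stack's own geometry).
#' @param method `"similarity"` (default) or `"affine"`.
#' @return A new, aligned [frame_stack()].
#' @export
align_frames <- function(stack, landmarks, reference,
                         ref_dim = dim(stack$frames)[1:2],
                         method = c("similarity", "affine")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "fapa_frames"))
  n <- n_frames(stack)
  per_frame <- is.list(landmarks) && !inherits(landmarks, "fapa_landmarks")
  if (per_frame && length(landmarks) != n) {
    stop("per-frame alignment needs one landmark set per frame")
  }
  fit <- function(lm) {
    if (method == "similarity") fit_similarity(lm, reference) else fit_affine(lm, reference)
  }
  grid <- cbind(rep(seq_len(ref_dim[1L]), times = ref_dim[2L]),
                rep(seq_len(ref_dim[2L]), each = ref_dim[1L]))
  inverse_coords <- function(tf) {
    # map output (reference) pixels back into source coordinates
    A <- if (!is.null(tf$A)) tf$A else tf$s * tf$R
    Ainv <- solve(A)
    sweep(grid, 2L, tf$t) %*% t(Ainv)
  }
  out <- array(0, dim = c(ref_dim[1L], ref_dim[2L], n))
  if (!per_frame) {
    src_rc <- inverse_coords(fit(landmarks))
    for (i in seq_len(n)) {
      out[, , i] <- matrix(sample_bilinear(get_frame(stack, i), src_rc),
                           ref_dim[1L], ref_dim[2L])
    }
  } else {
    for (i in seq_len(n)) {
      src_rc <- inverse_coords(fit(landmarks[[i]]))
      out[, , i] <- matrix(sample_bilinear(get_frame(stack, i), src_rc),
                           ref_dim[1L], ref_dim[2L])
    }
  }
  out <- pmin(pmax(out, 0), 1)
  frame_stack(out, fps = stack$fps, source_id = stack$source_id)
}
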