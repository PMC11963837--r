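# Internal numeric / raster helpers shared across modules.

#' Trapezoidal integral
#'
#' @param x abscissa (strictly increasing).
#' @param y ordinates, same length as `x`.
#' @return The trapezoid-rule integral of `y` over `x`.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Offsets (drow, dcol) of a Euclidean disk of the given radius.
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Shift a logical matrix by (dr, dc) without wrap-around; vacated cells FALSE.
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Circular (torus) shift of a numeric matrix by integer (dr, dc).
circ_shift <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1L - dr) %% h) + 1L, ((seq_len(w) - 1L - dc) %% w) + 1L, drop = FALSE]
}

# 8-connected component labelling by flood fill. Returns an integer matrix,
# 0 = background. Intended for the modest mask sizes of whisker videography.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack) > 0L) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((q - 1L) %% h) + 1L
      cc <- ((q - 1L) %/% h) + 1L
      for (dr in -1L:1L) {
        rr <- r + dr
        if (rr < 1L || rr > h) next
        for (dc in -1L:1L) {
          c2 <- cc + dc
          if (c2 < 1L || c2 > w) next
          qq <- (c2 - 1L) * h + rr
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- cur
            stack <- c(stack, qq)
          }
        }
      }
    }
  }
  lab
}

# Binary dilation with a Euclidean disk structuring element.
dilate_mask <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off[k, 1L], off[k, 2L])
  }
  out
}

# Band-limited random texture in [0.1, 0.9]: uniform noise smoothed by two
# passes of a 3x3 box filter, so every HOG cell carries gradient content.
smooth_noise_texture <- function(h, w) {
  m <- matrix(stats::runif(h * w), h, w)
  for (pass in 1:2) {
    acc <- matrix(0, h, w)
    for (dr in -1:1) for (dc in -1:1) acc <- acc + circ_shift(m, dr, dc)
    m <- acc / 9
  }
  rng <- range(m)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, h, w))
  0.1 + 0.8 * (m - rng[1]) / diff(rng)
}

# Zero-mean, unit-sd smooth random series (moving-average filtered white
# noise); used as a bounded displacement path for synthetic zone motion.
smooth_path <- function(n, span = 7L) {
  x <- stats::rnorm(n + 2L * span)
  x <- stats::filter(x, rep(1 / span, span), sides = 2L)
  x <- as.numeric(x[(span + 1L):(span + n)])
  x <- x - mean(x)
  s <- stats::sd(x)
  if (is.na(s) || s < .Machine$double.eps) return(rep(0, n))
  x / s
}
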