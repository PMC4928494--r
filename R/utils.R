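# Internal helpers shared across modules: geometry, angles, filtering.

# Angles are radians, measured from the +x axis toward +y. Image coordinates
# have the origin at the top-left corner with y pointing down, so a positive
# angle turns clockwise on screen. Public APIs that take/return degrees say so.

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Separable Gaussian kernel, truncated at 3 sigma, unit sum.
gaussian_kernel2d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian blur of an H x W matrix with replicate (edge-clamp) boundary.
# A constant matrix maps to itself exactly up to floating point.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0 || any(dim(m) < 2)) return(m)
  rng <- range(m)
  if (rng[2] - rng[1] == 0) return(m) # constant is its own blur
  k <- gaussian_kernel2d(sigma)
  if (any(dim(k) > dim(m))) {
    # crop the kernel to the image size (odd extents), renormalize
    half <- function(d) max(0L, (d - 1L) %/% 2L)
    hr <- half(nrow(m)); hc <- half(ncol(m))
    ctr <- (nrow(k) + 1L) %/% 2L
    k <- k[(ctr - hr):(ctr + hr), (ctr - hc):(ctr + hc), drop = FALSE]
    k <- k / sum(k)
    if (any(dim(k) > dim(m))) return(m)
  }
  out <- EBImage::filter2(m, k, boundary = "replicate")
  out[] <- pmax(out, 0)
  out
}

# Bilinear resize of an H x W matrix.
resize_mat <- function(m, h, w) {
  h <- max(1L, as.integer(h)); w <- max(1L, as.integer(w))
  if (nrow(m) == h && ncol(m) == w) return(m)
  out <- EBImage::resize(m, w = h, h = w) # EBImage dim1 is its "width"
  matrix(as.numeric(out), h, w)
}

# Min-max normalize to [0, 1]; (numerically) constant input maps to all
# zeros rather than having round-off noise blown up to full range.
minmax01 <- function(m, warn_constant = FALSE, what = "map") {
  rng <- range(m)
  if (!all(is.finite(rng))) stop("non-finite values in ", what)
  if (rng[2] - rng[1] <= 1e-9 * max(abs(rng), 1)) {
    if (warn_constant) warning(what, " is constant; returning all zeros")
    m[] <- 0
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

# Clamp continuous gaze coordinates to the image domain [0, W] x [0, H].
clamp_to_image <- function(x, y, image_size) {
  list(x = pmin(pmax(x, 0), image_size[2]), y = pmin(pmax(y, 0), image_size[1]))
}

# Continuous coordinate -> 1-based pixel index (row = y, col = x).
px_index <- function(x, y, image_size) {
  list(
    row = pmin(pmax(floor(y) + 1L, 1L), image_size[1]),
    col = pmin(pmax(floor(x) + 1L, 1L), image_size[2])
  )
}

# Centered moving average with edge shrinkage (window truncated at ends).
moving_average <- function(v, width) {
  width <- as.integer(width)
  if (width <= 1L) return(v)
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(v)
  cs <- cumsum(c(0, v))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_fix_matrix <- function(fixations) {
  if (is.matrix(fixations)) {
    stopifnot(ncol(fixations) >= 2)
    return(cbind(x = fixations[, 1], y = fixations[, 2]))
  }
  if (is.data.frame(fixations)) {
    xc <- intersect(c("x", "x_px"), names(fixations))[1]
    yc <- intersect(c("y", "y_px"), names(fixations))[1]
    if (is.na(xc) || is.na(yc)) stop("fixations need x/y (or x_px/y_px) columns")
    return(cbind(x = fixations[[xc]], y = fixations[[yc]]))
  }
  stop("fixations must be a matrix or data frame of x,y positions")
}
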