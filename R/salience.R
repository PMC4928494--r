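#' Bottom-up salience maps from RGB images
#'
#' Computes a bottom-up salience map in the style of the Itti-Koch-Niebur
#' architecture: intensity, color-opponency (red-green, blue-yellow) and
#' orientation (Gabor energy at 0/45/90/135 degrees) features are extracted
#' on a 9-level dyadic Gaussian pyramid, combined by center-surround
#' differencing (center scales 2-4, surround deltas 3-4), passed through the
#' map-normalization operator that promotes maps with a single dominant peak,
#' summed into per-channel conspicuity maps at a common scale, averaged with
#' equal weights, upsampled to image resolution and min-max normalized to
#' \[0, 1\].
#'
#' The computation is fully deterministic: the same image always yields the
#' same map. A constant (featureless) image has no contrast at any scale; its
#' salience is defined as all zeros and a warning is raised.
#'
#' @param image an RGB image: an H x W x 3 numeric array with values in
#'   \[0, 255\] (an H x W matrix is treated as grayscale). Both dimensions
#'   must be at least 64 pixels so the coarsest pyramid level is defined.
#' @param px_per_dva pixels per degree of visual angle, stored on the result
#'   for downstream geometry (default 25).
#' @return a `salience_map`: an H x W matrix in \[0, 1\] with attributes
#'   `kind = "salience"` and `px_per_dva`.
#' @seealso [compute_intensity()], [chance_level()], [prepare_salience_state()]
#' @export
#' @examples
#' img <- array(30, dim = c(64, 64, 3))
#' img[25:40, 25:40, ] <- 220            # one conspicuous square
#' s <- compute_salience(img)
#' which(s == max(s), arr.ind = TRUE)[1, ]
compute_salience <- function(image, px_per_dva = 25) {
  image <- validate_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]

  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  intens <- (r + g + b) / 3

  n_levels <- 9L # levels 0..8
  pyr_i <- build_pyramid(intens, n_levels)

  # Broadly tuned color channels, normalized by intensity where it is
  # appreciable (dividing out luminance decouples hue from brightness).
  imax <- max(intens)
  denom <- ifelse(intens > imax / 10, intens, Inf)
  Rc <- pmax(r - (g + b) / 2, 0) / denom
  Gc <- pmax(g - (r + b) / 2, 0) / denom
  Bc <- pmax(b - (r + g) / 2, 0) / denom
  Yc <- pmax((r + g) / 2 - abs(r - g) / 2 - b, 0) / denom
  pyr_rg <- build_pyramid(Rc - Gc, n_levels)
  pyr_by <- build_pyramid(Bc - Yc, n_levels)

  thetas <- c(0, 45, 90, 135)
  pyr_o <- lapply(thetas, function(th) {
    lapply(pyr_i, gabor_energy, theta_deg = th)
  })

  centers <- 2:4
  deltas <- 3:4
  # common scale for conspicuity maps: level 4
  ch <- dim(pyr_i[[5]])

  conspicuity_sum <- function(maps) {
    out <- matrix(0, ch[1], ch[2])
    for (m in maps) out <- out + resize_mat(normalize_map(m), ch[1], ch[2])
    out
  }

  maps_i <- list(); maps_c <- list()
  maps_o <- lapply(thetas, function(th) list())
  for (c0 in centers) {
    for (d in deltas) {
      s0 <- c0 + d
      cs <- function(pc, ps) {
        abs(pc[[c0 + 1]] - resize_mat(ps[[s0 + 1]], nrow(pc[[c0 + 1]]), ncol(pc[[c0 + 1]])))
      }
      maps_i[[length(maps_i) + 1]] <- cs(pyr_i, pyr_i)
      # double-opponency: center RG against surround GR, BY against YB
      maps_c[[length(maps_c) + 1]] <- cs(pyr_rg, lapply(pyr_rg, function(m) -m))
      maps_c[[length(maps_c) + 1]] <- cs(pyr_by, lapply(pyr_by, function(m) -m))
      for (k in seq_along(thetas)) {
        maps_o[[k]][[length(maps_o[[k]]) + 1]] <- cs(pyr_o[[k]], pyr_o[[k]])
      }
    }
  }

  ci <- normalize_map(conspicuity_sum(maps_i))
  cc <- normalize_map(conspicuity_sum(maps_c))
  co <- matrix(0, ch[1], ch[2])
  for (k in seq_along(thetas)) co <- co + normalize_map(conspicuity_sum(maps_o[[k]]))
  co <- normalize_map(co)

  s <- (ci + cc + co) / 3
  s <- resize_mat(s, h, w)
  s <- minmax01(s, warn_constant = TRUE, what = "salience map")
  new_salience_map(s, kind = "salience", px_per_dva = px_per_dva)
}

#' Normalized image-intensity map
#'
#' The grayscale value at each pixel (mean of the R, G and B channels),
#' min-max normalized to \[0, 1\] within the image. A constant image yields
#' all zeros with a warning.
#'
#' @inheritParams compute_salience
#' @return a `salience_map` with `kind = "intensity"`.
#' @export
compute_intensity <- function(image, px_per_dva = 25) {
  image <- validate_image(image, min_size = 1L)
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  gray <- minmax01(gray, warn_constant = TRUE, what = "intensity map")
  new_salience_map(gray, kind = "intensity", px_per_dva = px_per_dva)
}

#' Chance level of map values at random locations
#'
#' Draws `n_samples` uniformly random pixel locations and returns the 95\%
#' confidence interval of the mean map value, the reference against which
#' map values at fixated locations are compared.
#'
#' @param map a `salience_map` (or plain matrix).
#' @param n_samples number of random locations (at least 100).
#' @param seed integer seed; the same seed always gives the same interval.
#' @param conf confidence level (default 0.95).
#' @return a one-row tibble with columns `mean`, `low`, `high`, `n_samples`.
#' @export
chance_level <- function(map, n_samples = 10000, seed = 1, conf = 0.95) {
  stopifnot(is.matrix(map), n_samples >= 100)
  set.seed(as.integer(seed))
  idx <- sample.int(length(map), n_samples, replace = TRUE)
  v <- map[idx]
  m <- mean(v)
  se <- stats::sd(v) / sqrt(n_samples)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tibble::tibble(mean = m, low = m - z * se, high = m + z * se,
                 n_samples = as.integer(n_samples))
}

# ---- internals --------------------------------------------------------------

validate_image <- function(image, min_size = 64L) {
  if (is.matrix(image)) image <- array(rep(image, 3), dim = c(dim(image), 3))
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] >= 3)) {
    stop("image must be an H x W x 3 array (or an H x W grayscale matrix)")
  }
  if (!all(is.finite(image))) stop("image contains non-finite values")
  if (any(dim(image)[1:2] < min_size)) {
    stop("image too small for the salience pyramid: minimum size is ",
         min_size, " x ", min_size, " pixels")
  }
  image[, , 1:3, drop = FALSE]
}

# Dyadic Gaussian pyramid, levels 0..(n_levels-1).
build_pyramid <- function(m, n_levels) {
  pyr <- vector("list", n_levels)
  pyr[[1]] <- m
  for (k in 2:n_levels) {
    sm <- blur_gaussian(pyr[[k - 1]], 1)
    pyr[[k]] <- resize_mat(sm, max(1, ceiling(nrow(sm) / 2)),
                           max(1, ceiling(ncol(sm) / 2)))
  }
  pyr
}

# Map-normalization operator: scale to [0, 1], then multiply by
# (1 - mean-of-other-local-maxima)^2 so maps with one dominant peak are
# promoted and maps with many similar peaks are suppressed.
normalize_map <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  m <- m / mx
  lm <- local_maxima_values(m, floor_frac = 0.05)
  others <- lm[lm < 1 - 1e-9]
  mbar <- if (length(others)) mean(others) else 0
  m * (1 - mbar)^2
}

# Values of 3x3 local maxima above a floor fraction of the global max.
local_maxima_values <- function(m, floor_frac = 0.05) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(max(m))
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  nb <- pad[2:(h + 1), 2:(w + 1)]
  is_max <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (nb >= pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  vals <- m[is_max & m > floor_frac * max(m)]
  if (!length(vals)) max(m) else vals
}

# Gabor energy (quadrature pair) at one orientation; zero matrix when the
# level is smaller than the kernel.
gabor_energy <- function(m, theta_deg, wavelength = 7, sigma = 3) {
  r <- as.integer(ceiling(2.5 * sigma))
  size <- 2L * r + 1L
  if (any(dim(m) < size)) return(m * 0)
  key <- sprintf("g_%s_%s_%s", theta_deg, wavelength, sigma)
  kern <- gabor_cache[[key]]
  if (is.null(kern)) {
    th <- deg2rad(theta_deg)
    xs <- matrix(rep(seq(-r, r), each = size), size, size)  # column offset (x)
    ys <- matrix(rep(seq(-r, r), times = size), size, size) # row offset (y)
    xr <- xs * cos(th) + ys * sin(th)
    yr <- -xs * sin(th) + ys * cos(th)
    env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
    even <- env * cos(2 * pi * xr / wavelength)
    odd <- env * sin(2 * pi * xr / wavelength)
    even <- even - mean(even) # zero-DC so flat regions give no response
    kern <- list(even = even, odd = odd)
    gabor_cache[[key]] <- kern
  }
  e <- EBImage::filter2(m, kern$even, boundary = "replicate")
  o <- EBImage::filter2(m, kern$odd, boundary = "replicate")
  sqrt(e^2 + o^2)
}

gabor_cache <- new.env(parent = emptyenv())

new_salience_map <- function(values, kind, px_per_dva) {
  structure(values, kind = kind, px_per_dva = px_per_dva,
            class = c("salience_map", class(values)))
}

#' @export
print.salience_map <- function(x, ...) {
  cat(sprintf("<salience_map kind=%s %d x %d px, %g px/dva, range [%.3g, %.3g]>\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "px_per_dva"),
              min(x), max(x)))
  invisible(x)
}
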