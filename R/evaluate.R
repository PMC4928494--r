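#' Fixation probability density over the image
#'
#' Marks fixation locations in a pixel matrix, smooths with a 2-D Gaussian
#' (sd = 1 dva, absorbing eye-tracker error and natural fixation
#' variability), bins into 1 x 1 dva bins (24 x 32 for the default 600 x 800
#' px / 25 px-per-dva geometry; a partial last bin absorbs remainder
#' pixels), floors empty bins at `2^-52` and normalizes the matrix to sum 1.
#'
#' @param fixations data frame (columns x, y or x_px, y_px) or 2-column
#'   matrix of fixation positions in pixels.
#' @param image_size `c(H, W)` in pixels.
#' @param px_per_dva pixels per dva (bin size).
#' @param sigma_dva smoothing sd in dva (default 1).
#' @param source label stored on the result (default "observed").
#' @return a `fixation_pdf`: a bins matrix summing to 1, all entries > 0,
#'   with attributes `px_per_dva`, `image_size`, `source`.
#' @export
fixation_pdf <- function(fixations, image_size, px_per_dva = 25,
                         sigma_dva = 1, source = "observed") {
  fm <- as_fix_matrix(fixations)
  if (!nrow(fm)) stop("no fixations supplied")
  h <- image_size[1]; w <- image_size[2]
  on_img <- fm[, 1] >= -px_per_dva & fm[, 1] <= w + px_per_dva &
            fm[, 2] >= -px_per_dva & fm[, 2] <= h + px_per_dva
  fm <- fm[on_img, , drop = FALSE]
  if (!nrow(fm)) stop("no fixations on the image")
  p <- px_index(fm[, 1], fm[, 2], image_size)
  mark <- matrix(0, h, w)
  idx <- (p$col - 1L) * h + p$row
  tab <- table(idx)
  mark[as.integer(names(tab))] <- as.numeric(tab)
  sm <- blur_gaussian(mark, sigma_dva * px_per_dva)
  bins <- bin_matrix(sm, px_per_dva)
  new_fixation_pdf(bins, px_per_dva, image_size, source)
}

#' Fixation PDF predicted directly by a map
#'
#' Bins a salience/intensity/prediction map into 1 x 1 dva bins (per-bin
#' sums), floors empty bins at `2^-52` and normalizes to sum 1. An all-zero
#' map yields the uniform PDF.
#'
#' @param map a `salience_map` or plain H x W matrix.
#' @param px_per_dva pixels per dva.
#' @param source label stored on the result (default: the map's kind).
#' @return a `fixation_pdf`.
#' @export
map_pdf <- function(map, px_per_dva = NULL, source = NULL) {
  px_per_dva <- px_per_dva %||% attr(map, "px_per_dva") %||% 25
  source <- source %||% attr(map, "kind") %||% "map"
  bins <- bin_matrix(unclass(map), px_per_dva)
  new_fixation_pdf(bins, px_per_dva, dim(map), source)
}

#' Symmetric Kullback-Leibler divergence between two fixation PDFs
#'
#' `D = D_KL(P || Q) + D_KL(Q || P)`, computed over the 1 x 1 dva bins. The
#' default log base 2 reports the divergence in bits; `base = exp(1)` gives
#' nats.
#'
#' @param P,Q `fixation_pdf` objects (or normalized matrices) of matching
#'   shape.
#' @param base logarithm base (default 2: bits).
#' @return nonnegative scalar divergence.
#' @export
kl_divergence <- function(P, Q, base = 2) {
  if (!all(dim(P) == dim(Q))) stop("PDFs have mismatched shapes")
  p <- as.numeric(P); q <- as.numeric(Q)
  sum(log(p / q, base = base) * p) + sum(log(q / p, base = base) * q)
}

#' AUROC of model values at fixated vs. random locations
#'
#' Scores the model (a salience/intensity map or a fixation PDF) at the
#' fixated locations and at `n_random` uniformly random image locations and
#' computes the area under the ROC curve with the midrank (tie-aware)
#' convention: 0.5 is chance, 1 is perfect discrimination. The AUROC is
#' invariant under strictly monotone transformations of the model values.
#'
#' @param model a `salience_map`, `fixation_pdf`, or plain matrix (treated
#'   as a per-pixel map unless it carries fixation-PDF attributes).
#' @param fixations data frame or matrix of fixation x/y positions (px).
#' @param n_random number of random locations (default: number of
#'   fixations).
#' @param seed integer seed for the random locations.
#' @param image_size image geometry; required when `model` is a
#'   `fixation_pdf` without a stored size.
#' @return a one-row `eval_result` tibble: metric, value, n_fixations,
#'   n_random, seed.
#' @export
auroc <- function(model, fixations, n_random = NULL, seed = 1,
                  image_size = NULL) {
  fm <- as_fix_matrix(fixations)
  if (nrow(fm) < 1) stop("no fixations supplied")
  image_size <- image_size %||% attr(model, "image_size") %||% dim(model)
  n_random <- n_random %||% nrow(fm)
  set.seed(as.integer(seed))
  rx <- stats::runif(n_random, 0, image_size[2])
  ry <- stats::runif(n_random, 0, image_size[1])
  v_fix <- model_value_at(model, fm[, 1], fm[, 2], image_size)
  v_rnd <- model_value_at(model, rx, ry, image_size)
  tibble::tibble(metric = "auroc",
                 value = auroc_midrank(v_fix, v_rnd),
                 n_fixations = nrow(fm), n_random = as.integer(n_random),
                 seed = as.integer(seed))
}

auroc_midrank <- function(pos, neg) {
  r <- rank(c(pos, neg)) # midranks for ties
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Interobserver consistency via ROC analysis
#'
#' Builds the group's fixation PDF and scores the individual observer's
#' fixated locations against it versus random locations. With a full cohort
#' (a data frame containing an `observer_id` column) the leave-one-out AUROC
#' is computed for every observer against the remaining group.
#'
#' @param observer_fixations fixations of the held-out observer, or a full
#'   cohort data frame with an `observer_id` column (then
#'   `group_fixations` is ignored).
#' @param group_fixations fixations of the remaining group.
#' @param image_size `c(H, W)` px.
#' @param px_per_dva pixels per dva.
#' @param seed integer seed.
#' @param n_random random locations per comparison (default: number of
#'   observer fixations).
#' @return an `eval_result` tibble (one row per observer for a cohort).
#' @export
interobserver_auroc <- function(observer_fixations, group_fixations = NULL,
                                image_size, px_per_dva = 25, seed = 1,
                                n_random = NULL) {
  if (is.data.frame(observer_fixations) &&
      "observer_id" %in% names(observer_fixations)) {
    ids <- unique(observer_fixations$observer_id)
    if (length(ids) < 2) stop("interobserver analysis needs at least 2 observers")
    return(purrr::map_dfr(ids, function(id) {
      cols <- setdiff(names(observer_fixations), "observer_id")
      ind <- observer_fixations[observer_fixations$observer_id == id, cols]
      grp <- observer_fixations[observer_fixations$observer_id != id, cols]
      res <- interobserver_auroc(ind, grp, image_size, px_per_dva, seed, n_random)
      res$observer_id <- id
      res
    }))
  }
  if (is.null(group_fixations) || !nrow(as_fix_matrix(group_fixations))) {
    stop("interobserver analysis needs a nonempty group")
  }
  gpdf <- fixation_pdf(group_fixations, image_size, px_per_dva, source = "group")
  auroc(gpdf, observer_fixations, n_random = n_random, seed = seed,
        image_size = image_size)
}

#' Average several fixation PDFs
#'
#' Element-wise mean, renormalized; the across-image average PDF is the
#' central-bias predictor.
#'
#' @param pdfs list of `fixation_pdf` objects of matching shape.
#' @return a `fixation_pdf` with source "average".
#' @export
average_pdf <- function(pdfs) {
  if (!length(pdfs)) stop("no PDFs to average")
  d <- dim(pdfs[[1]])
  if (!all(vapply(pdfs, function(p) all(dim(p) == d), logical(1)))) {
    stop("PDFs have mismatched shapes")
  }
  m <- Reduce(`+`, lapply(pdfs, unclass)) / length(pdfs)
  m <- pmax(m, 2^-52)
  m <- m / sum(m)
  new_fixation_pdf(m, attr(pdfs[[1]], "px_per_dva"),
                   attr(pdfs[[1]], "image_size"), "average")
}

#' Centroid (center of mass) of fixation locations with bootstrap CI
#'
#' @param fixations data frame or matrix of x/y positions (px).
#' @param weights optional per-fixation weights.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return a one-row tibble: x, y, x_lo, x_hi, y_lo, y_hi, n.
#' @export
centroid <- function(fixations, weights = NULL, n_boot = 1000, seed = 1,
                     conf = 0.95) {
  fm <- as_fix_matrix(fixations)
  n <- nrow(fm)
  if (!n) stop("no fixations supplied")
  w <- weights %||% rep(1, n)
  cx <- sum(w * fm[, 1]) / sum(w); cy <- sum(w * fm[, 2]) / sum(w)
  if (n == 1) {
    return(tibble::tibble(x = cx, y = cy, x_lo = cx, x_hi = cx,
                          y_lo = cy, y_hi = cy, n = 1L))
  }
  set.seed(as.integer(seed))
  bx <- numeric(n_boot); by <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bx[i] <- sum(w[idx] * fm[idx, 1]) / sum(w[idx])
    by[i] <- sum(w[idx] * fm[idx, 2]) / sum(w[idx])
  }
  a <- (1 - conf) / 2
  tibble::tibble(x = cx, y = cy,
                 x_lo = stats::quantile(bx, a, names = FALSE),
                 x_hi = stats::quantile(bx, 1 - a, names = FALSE),
                 y_lo = stats::quantile(by, a, names = FALSE),
                 y_hi = stats::quantile(by, 1 - a, names = FALSE),
                 n = as.integer(n))
}

# ---- internals --------------------------------------------------------------

# Sum pixel values into 1 x 1 dva bins; the last bin absorbs remainder
# pixels when the image extent is not an integer number of dva.
bin_matrix <- function(m, px_per_dva) {
  h <- nrow(m); w <- ncol(m)
  nbr <- max(1L, floor(h / px_per_dva + 1e-9))
  nbc <- max(1L, floor(w / px_per_dva + 1e-9))
  ri <- pmin(floor((seq_len(h) - 0.5) / px_per_dva) + 1L, nbr)
  ci <- pmin(floor((seq_len(w) - 0.5) / px_per_dva) + 1L, nbc)
  rs <- rowsum(m, ri)
  t(rowsum(t(rs), ci))
}

new_fixation_pdf <- function(bins, px_per_dva, image_size, source) {
  s <- sum(bins)
  if (s <= 0) bins[] <- 1 # all-zero map: uniform PDF
  bins <- pmax(bins, 2^-52)
  bins <- bins / sum(bins)
  structure(bins, px_per_dva = px_per_dva, image_size = image_size,
            source = source, class = c("fixation_pdf", class(bins)))
}

# Model value at continuous pixel coordinates: direct pixel lookup for
# per-pixel maps, bin lookup for fixation PDFs.
model_value_at <- function(model, x, y, image_size) {
  if (inherits(model, "fixation_pdf")) {
    h <- image_size[1]; w <- image_size[2]
    s <- attr(model, "px_per_dva")
    r <- pmin(pmax(floor(pmin(pmax(y, 0), h - 1e-9) / s) + 1L, 1L), nrow(model))
    c <- pmin(pmax(floor(pmin(pmax(x, 0), w - 1e-9) / s) + 1L, 1L), ncol(model))
    return(model[(c - 1L) * nrow(model) + r])
  }
  p <- px_index(x, y, dim(model))
  unclass(model)[(p$col - 1L) * nrow(model) + p$row]
}

#' @export
print.fixation_pdf <- function(x, ...) {
  cat(sprintf("<fixation_pdf source=%s %d x %d bins (1 dva), sum=%.3f>\n",
              attr(x, "source"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}
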