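# Feature construction for the clustering step: the 4-D feature space is
# (intensity, D2x, D2y, D2z) where the intensity channel always comes from
# the unsmoothed stack and the axial second derivatives from the (optionally
# Gaussian-smoothed) stack.

#' Logarithmic dynamics compression
#'
#' Applies `log(1 + I)` voxelwise and rescales the result back to the input
#' intensity range. The map is monotone, so voxel ordering by intensity is
#' preserved; it compresses the bright tail, which helps when somata
#' saturate relative to thin neurites.
#'
#' @param stack an [image_stack] or 3-D array.
#' @return an [image_stack] with the same voxel size and range.
#' @export
log_transform <- function(stack) {
  st <- as_stack(stack)
  x <- st$data
  if (any(x < 0)) {
    warning("negative intensities clamped to 0 before log transform")
    x[x < 0] <- 0
  }
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(st)
  y <- log1p(x - lo)
  y <- y / max(y) * (hi - lo) + lo
  image_stack(y, st$voxel_size, st$dtype_range)
}

#' Gaussian smoothing in voxel space
#'
#' Separable Gaussian convolution with symmetric (reflective) boundary
#' handling. `sigma` is in voxels; a scalar is applied isotropically, a
#' length-3 vector `(sz, sy, sx)` anisotropically. `sigma = 0` returns the
#' input unchanged.
#'
#' @param stack an [image_stack] or 3-D array.
#' @param sigma standard deviation(s) in voxels, `>= 0`.
#' @return smoothed [image_stack].
#' @export
gaussian_smooth <- function(stack, sigma) {
  st <- as_stack(stack)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L) stop("sigma must be a scalar or length 3")
  if (all(sigma == 0)) return(st)
  sm <- gaussian_smooth_cpp(as.numeric(st$data), dim(st$data),
                            as.numeric(sigma))
  image_stack(array(sm, dim(st$data)), st$voxel_size, st$dtype_range)
}

#' Axial second derivatives
#'
#' Central second difference `[1, -2, 1]` along each axis in voxel units;
#' boundary slices replicate the nearest edge value, so the stencil output
#' is 0 there for linear profiles. Bright tubular or blob-like structure
#' gives negative values inside and positive values at the outer border
#' along each axis, which is what the class-selection rules exploit.
#'
#' @param stack an [image_stack] or 3-D array; each axis must have length
#'   >= 3.
#' @return list of 3-D arrays `d2z`, `d2y`, `d2x`.
#' @export
second_derivatives <- function(stack) {
  st <- as_stack(stack)
  x <- st$data
  d <- dim(x)
  if (any(d < 3))
    stop("second derivatives need every axis length >= 3 (got ",
         paste(d, collapse = "x"), ")")
  stencil <- function(arr, axis) {
    n <- dim(arr)[axis]
    up <- c(2:n, n)       # nearest-edge replication
    dn <- c(1, 1:(n - 1))
    if (axis == 1) arr[up, , , drop = FALSE] + arr[dn, , , drop = FALSE] - 2 * arr
    else if (axis == 2) arr[, up, , drop = FALSE] + arr[, dn, , drop = FALSE] - 2 * arr
    else arr[, , up, drop = FALSE] + arr[, , dn, drop = FALSE] - 2 * arr
  }
  list(d2z = stencil(x, 1L), d2y = stencil(x, 2L), d2x = stencil(x, 3L))
}

#' Background exclusion mask
#'
#' Foreground = voxels with intensity strictly above a threshold chosen by
#' Otsu's criterion, a percentile, or an absolute value. Background voxels
#' are excluded from clustering to cut its cost; the threshold is
#' deliberately permissive (it only needs to discard empty space).
#'
#' @param stack an [image_stack] or 3-D array.
#' @param method `"otsu"`, `"percentile"` or `"absolute"`.
#' @param value percentile in (0, 100) or absolute threshold; unused for
#'   Otsu.
#' @return logical 3-D array, with the threshold in attribute
#'   `"threshold"`.
#' @export
background_mask <- function(stack, method = c("otsu", "percentile",
                                              "absolute"),
                            value = NULL) {
  st <- as_stack(stack)
  method <- match.arg(method)
  x <- st$data
  if (min(x) == max(x)) stop("no foreground separable: stack is constant")
  thr <- switch(method,
    otsu = otsu_threshold(x),
    percentile = {
      if (is.null(value) || value <= 0 || value >= 100)
        stop("percentile method needs value in (0, 100)")
      as.numeric(stats::quantile(x, value / 100, type = 1))
    },
    absolute = {
      if (is.null(value)) stop("absolute method needs a threshold value")
      as.numeric(value)
    })
  mask <- x > thr
  if (!any(mask)) stop("no foreground separable: threshold above maximum")
  attr(mask, "threshold") <- thr
  mask
}

# Otsu's threshold on a 256-bin histogram: maximize between-class variance
# w0*w1*(mu0-mu1)^2 over bin boundaries; returns the intensity at the best
# boundary.
otsu_threshold <- function(x, nbins = 256L) {
  lo <- min(x); hi <- max(x)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins), nbins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)
  edges[k + 1L]
}

#' Assemble the 4-D feature volume
#'
#' Builds the clustering features over foreground voxels: intensity from the
#' raw (unsmoothed) stack and the three axial second derivatives from the
#' stack smoothed with `sigma`. With `standardize = TRUE` each channel is
#' z-scored over foreground; the affine parameters are kept so class means
#' can always be reported in original units, where the selection rules
#' (derivative signs, intensity ranking) are applied.
#'
#' @param stack an [image_stack].
#' @param sigma smoothing std-dev in voxels for the derivative channels
#'   (0 = derivatives on the raw stack).
#' @param foreground logical 3-D array from [background_mask()]; `NULL`
#'   uses all voxels.
#' @param standardize z-score channels over foreground (default TRUE).
#' @return object of class `feature_volume`: `X` (n x 4 matrix in
#'   clustering space, columns intensity/d2x/d2y/d2z), `raw` (same in
#'   original units), `foreground`, `center`, `scale`, `sigma`, `shape`,
#'   `voxel_size`.
#' @export
build_features <- function(stack, sigma = 0, foreground = NULL,
                           standardize = TRUE) {
  st <- as_stack(stack)
  if (is.null(foreground))
    foreground <- array(TRUE, dim(st$data))
  if (!any(foreground)) stop("foreground is empty")
  sm <- gaussian_smooth(st, sigma)
  d2 <- second_derivatives(sm)
  fg <- as.vector(foreground)
  raw <- cbind(intensity = as.numeric(st$data)[fg],
               d2x = as.numeric(d2$d2x)[fg],
               d2y = as.numeric(d2$d2y)[fg],
               d2z = as.numeric(d2$d2z)[fg])
  if (standardize) {
    center <- colMeans(raw)
    scale <- apply(raw, 2, sd)
    scale[scale == 0] <- 1
    X <- sweep(sweep(raw, 2, center), 2, scale, "/")
  } else {
    center <- c(0, 0, 0, 0)
    scale <- c(1, 1, 1, 1)
    X <- raw
  }
  structure(list(X = X, raw = raw, foreground = foreground,
                 center = center, scale = scale, sigma = sigma,
                 shape = dim(st$data), voxel_size = st$voxel_size),
            class = "feature_volume")
}
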