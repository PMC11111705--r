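#' @useDynLib arborseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans median rnorm rpois runif setNames coef lm sd
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- ImageStack --------------------------------------------------------

#' Construct a 3-D image stack
#'
#' An `image_stack` bundles a 3-D intensity array indexed `(z, y, x)` with
#' its anisotropic voxel size in micrometres. All geometric quantities
#' downstream (skeleton edge lengths, radii, Sholl distances, surface areas)
#' are derived from `voxel_size`.
#'
#' @param data numeric or integer 3-D array indexed `(z, y, x)`. A matrix is
#'   accepted and treated as a single-slice volume (with a warning).
#' @param voxel_size numeric length-3 vector `(dz, dy, dx)` in micrometres,
#'   all strictly positive and finite.
#' @param dtype_range numeric length-2 `(min, max)` of the source bit depth;
#'   inferred from the data when missing.
#' @return an object of class `image_stack` with fields `data`,
#'   `voxel_size`, `dtype_range`.
#' @export
image_stack <- function(data, voxel_size = c(1, 1, 1), dtype_range = NULL) {
  if (is.matrix(data)) {
    warning("2-D input treated as a single-slice volume")
    data <- array(data, dim = c(1L, dim(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array indexed (z, y, x); got ",
         length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("every axis must have length >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive finite values (dz, dy, dx)")
  if (is.null(dtype_range)) {
    mx <- max(data)
    dtype_range <-
      if (min(data) >= 0 && mx <= 255 && is_whole(data)) c(0, 255)
      else if (min(data) >= 0 && mx <= 65535 && is_whole(data)) c(0, 65535)
      else range(data)
  }
  structure(list(data = data, voxel_size = voxel_size,
                 dtype_range = as.numeric(dtype_range)),
            class = "image_stack")
}

is_whole <- function(x) {
  is.integer(x) || all(abs(x - round(x)) < 1e-9)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d x %d (z, y, x), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], dtype range [%.4g, %.4g]\n",
              min(x$data), max(x$data), x$dtype_range[1], x$dtype_range[2]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

as_stack <- function(x, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "image_stack")) x else image_stack(x, voxel_size)
}

# ---- TIFF I/O ----------------------------------------------------------

#' Read a multi-page TIFF as an image stack
#'
#' Pages become z-slices; axis order of the result is `(z, y, x)`. Integer
#' samples are preserved losslessly. Multi-channel (RGB) input is rejected.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param voxel_size `(dz, dy, dx)` in micrometres. TIFF metadata rarely
#'   carries a trustworthy 3-D voxel size, so it must be given explicitly;
#'   omitting it falls back to 1 um isotropic with a warning because every
#'   metric morphometric downstream depends on it.
#' @return an [image_stack].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  if (is.null(voxel_size)) {
    warning("no voxel_size given; assuming 1 um isotropic - metric ",
            "morphometrics will be in voxel units")
    voxel_size <- c(1, 1, 1)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1]])
  if (length(dims) == 3L)
    stop("multi-channel input not supported (page has ", dims[3],
         " channels)")
  data <- array(0, dim = c(length(pages), dims[1], dims[2]))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!identical(dim(p), dims)) stop("TIFF pages differ in shape")
    data[i, , ] <- p
  }
  if (length(pages) == 1L)
    message("single-page TIFF read as a one-slice volume")
  image_stack(data, voxel_size)
}

#' Write an image stack (or 3-D array) to a multi-page TIFF
#'
#' Integer data are written losslessly with the smallest sample size that
#' holds the maximum value (8 or 16 bits; wider data fall back to 32-bit
#' float samples, exact for integers below 2^24).
#'
#' @param stack an [image_stack] or a 3-D array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected a 3-D volume")
  mx <- max(data)
  mn <- min(data)
  if (mn < 0) stop("negative values cannot be written to unsigned TIFF")
  whole <- is_whole(data)
  if (!whole)
    stop("non-integer volumes are not supported by the TIFF writer; ",
         "scale to integers first")
  if (mx <= 255) {
    bits <- 8L; scale <- 255
  } else if (mx <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    # 32-bit samples are quantized as floor(x * (2^32 - 1)); centring each
    # integer in its quantization bin makes the stored word the value itself
    bits <- 32L; scale <- NA
  }
  pages <- lapply(seq_len(dim(data)[1]), function(z) {
    m <- matrix(data[z, , ], nrow = dim(data)[2], ncol = dim(data)[3])
    if (bits == 32L) (m + 0.5) / (2^32 - 1) else m / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}

#' Write a non-negative integer label volume to TIFF
#'
#' @param labels 3-D integer array, 0 = background.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  if (any(labels < 0)) stop("negative labels are not allowed")
  if (!is_whole(labels)) stop("labels must be integers")
  write_stack(array(as.numeric(labels), dim = dim(labels)), path)
}

#' Read a label volume written by [write_labels()]
#'
#' @param path TIFF path.
#' @return 3-D integer array.
#' @export
read_labels <- function(path) {
  st <- suppressWarnings(read_stack(path, voxel_size = c(1, 1, 1)))
  array(as.integer(round(st$data)), dim = dim(st$data))
}

# ---- markers -----------------------------------------------------------

#' Construct a marker set
#'
#' Markers are user-supplied point annotations in 0-based voxel coordinates
#' `(z, y, x)`: soma positions seeding watershed cores, or ground-truth
#' spine centres for evaluation.
#'
#' @param df data frame with columns `label`, `z`, `y`, `x`.
#' @param kind one of `"soma"`, `"core"`, `"spine_center"`.
#' @return object of class `marker_set` (a validated data frame).
#' @export
marker_set <- function(df, kind = c("soma", "core", "spine_center")) {
  kind <- match.arg(kind)
  need <- c("label", "z", "y", "x")
  if (!all(need %in% names(df)))
    stop("markers need columns label, z, y, x")
  df <- unique(df[, need, drop = FALSE])
  if (nrow(df) > 0) {
    if (anyDuplicated(df$label))
      stop("duplicate marker label: ",
           paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
    if (any(df$label < 1) || !is_whole(df$label))
      stop("marker labels must be positive integers")
  }
  df$label <- as.integer(df$label)
  structure(df, class = c("marker_set", "data.frame"), kind = kind)
}

#' Read markers from CSV
#'
#' Expects a header `label,z,y,x` with 0-based voxel coordinates.
#'
#' @param path CSV path.
#' @param kind marker kind, see [marker_set()].
#' @return a `marker_set`.
#' @export
read_markers <- function(path, kind = "soma") {
  df <- read.csv(path)
  marker_set(df, kind)
}

#' Write markers to CSV
#' @param markers a `marker_set` or data frame with label,z,y,x.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  write.csv(as.data.frame(markers)[, c("label", "z", "y", "x")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_markers_in_bounds <- function(markers, dims) {
  if (nrow(markers) == 0) return(invisible(TRUE))
  bad <- markers$z < 0 | markers$z > dims[1] - 1 |
         markers$y < 0 | markers$y > dims[2] - 1 |
         markers$x < 0 | markers$x > dims[3] - 1
  if (any(bad))
    stop("marker(s) out of volume bounds: label ",
         paste(markers$label[bad], collapse = ", "))
  invisible(TRUE)
}

# ---- configuration -----------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the two-step reconstruction. Defaults follow
#' the reference workflow: 10 K-means replicates with at most 1000 Lloyd
#' iterations each, and pruning of connected components below 7 voxels
#' (the smallest 3-D symmetric structure).
#'
#' @param sigmas numeric vector of Gaussian smoothing standard deviations in
#'   voxels; 0 means the derivatives are computed on the unsmoothed image.
#'   Several values yield a multi-scale segmentation merged by voxelwise OR.
#' @param K `"auto"` for the iterative smallest-K search, or a fixed
#'   integer number of classes.
#' @param K_min,K_max search range for automatic K selection.
#' @param kmeans_replicates independent K-means restarts; best inertia wins.
#' @param kmeans_max_iter maximum Lloyd iterations per replicate.
#' @param background_method background exclusion: `"otsu"`, `"percentile"`
#'   or `"absolute"`.
#' @param background_value threshold parameter (percentile in (0,100) or
#'   absolute intensity); ignored for `"otsu"`.
#' @param min_cluster_voxels components smaller than this are removed from
#'   the final mask.
#' @param core_size_threshold component size (voxels) above which a
#'   connected cluster becomes a core in automatic core mode.
#' @param core_radius radius (voxels) of the ball grown around a manual
#'   soma marker to seed a robust watershed well.
#' @param log_transform apply `log(1 + I)` dynamics compression first.
#' @param standardize z-score the four feature channels over foreground
#'   before clustering (class statistics are always reported in original
#'   units).
#' @param radius_mode node radius source for SWC export: `"edt"` (distance
#'   transform, default) or `"intensity"`.
#' @param random_seed integer seed controlling K-means initialisation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sigmas = c(0),
                            K = "auto",
                            K_min = 2L, K_max = 10L,
                            kmeans_replicates = 10L,
                            kmeans_max_iter = 1000L,
                            background_method = "otsu",
                            background_value = NULL,
                            min_cluster_voxels = 7L,
                            core_size_threshold = 500L,
                            core_radius = 2L,
                            log_transform = FALSE,
                            standardize = TRUE,
                            radius_mode = "edt",
                            random_seed = 42L) {
  stopifnot(length(sigmas) >= 1, all(sigmas >= 0),
            kmeans_replicates >= 1, kmeans_max_iter >= 1,
            min_cluster_voxels >= 1, core_size_threshold >= 1,
            core_radius >= 0)
  if (!identical(K, "auto")) {
    K <- as.integer(K)
    if (is.na(K) || K < 2) stop("K must be 'auto' or an integer >= 2")
  }
  background_method <- match.arg(background_method,
                                 c("otsu", "percentile", "absolute"))
  radius_mode <- match.arg(radius_mode, c("edt", "intensity"))
  structure(list(sigmas = as.numeric(sigmas), K = K,
                 K_min = as.integer(K_min), K_max = as.integer(K_max),
                 kmeans_replicates = as.integer(kmeans_replicates),
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 background_method = background_method,
                 background_value = background_value,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 core_size_threshold = as.integer(core_size_threshold),
                 core_radius = as.integer(core_radius),
                 log_transform = isTRUE(log_transform),
                 standardize = isTRUE(standardize),
                 radius_mode = radius_mode,
                 random_seed = as.integer(random_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
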