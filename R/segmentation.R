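# Step 1: K-means clustering in the 4-D feature space, automatic choice of
# the number of classes, selection of neuronal classes by the signs of the
# class-mean second derivatives, multi-scale OR merge, and mask clean-up.

# deterministic greedy spread-out initialization: first centre sampled
# uniformly, each further centre is the point farthest (min distance) from
# the chosen set.
greedy_init <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2min <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  if (K > 1) for (k in 2:K) {
    idx[k] <- which.max(d2min)
    d2k <- rowSums(sweep(X, 2, X[idx[k], ])^2)
    d2min <- pmin(d2min, d2k)
  }
  X[idx, , drop = FALSE]
}

#' Fit K-means in the 4-D feature space
#'
#' Best-of-replicates Lloyd K-means on the standardized features: each
#' replicate draws a fresh greedy spread-out initialization from
#' `seed + replicate - 1` and the model with the lowest within-cluster sum
#' of squares wins, making the fit deterministic given the seed. Classes
#' are then relabelled 1..K by increasing mean intensity (class 1 =
#' dimmest), and per-class means of intensity and the three second
#' derivatives are reported in original (unstandardized) units, since the
#' neuronal-class selection rules read raw derivative signs.
#'
#' @param features a `feature_volume` from [build_features()].
#' @param K number of classes, `>= 2`.
#' @param replicates independent restarts (default 10).
#' @param max_iter Lloyd iteration cap per replicate (default 1000).
#' @param seed integer seed.
#' @return object of class `cluster_model`: `K`, `centroids` (K x 4,
#'   intensity-sorted, standardized space), `class_stats` (data frame with
#'   class, n, mean_intensity, mean_d2x, mean_d2y, mean_d2z in original
#'   units), `labels` (per-foreground-voxel class id), `inertia`, `seed`,
#'   `replicates`, `max_iter`, `sigma`.
#' @export
fit_kmeans <- function(features, K, replicates = 10L, max_iter = 1000L,
                       seed = 42L) {
  stopifnot(inherits(features, "feature_volume"))
  K <- as.integer(K)
  if (K < 2) stop("K must be >= 2")
  X <- features$X
  if (nrow(X) < K)
    stop("K (", K, ") exceeds the number of foreground voxels (",
         nrow(X), ")")
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- withr::with_seed(seed + r - 1L, {
      init <- greedy_init(X, K)
      tryCatch(
        suppressWarnings(kmeans(X, centers = init, iter.max = max_iter,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
    })
    if (is.null(fit) || length(unique(fit$cluster)) < K) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("K-means failed for K = ", K,
         " (degenerate data: fewer than K distinct points?)")
  # sort classes by mean ORIGINAL intensity, dimmest first
  raw <- features$raw
  mean_int <- tapply(raw[, "intensity"], best$cluster, mean)
  ord <- order(mean_int)                 # old label -> position
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  labels <- relabel[best$cluster]
  stats <- do.call(rbind, lapply(seq_len(K), function(k) {
    m <- labels == k
    data.frame(class = k, n = sum(m),
               mean_intensity = mean(raw[m, "intensity"]),
               mean_d2x = mean(raw[m, "d2x"]),
               mean_d2y = mean(raw[m, "d2y"]),
               mean_d2z = mean(raw[m, "d2z"]))
  }))
  structure(list(K = K,
                 centroids = best$centers[ord, , drop = FALSE],
                 class_stats = stats,
                 labels = labels,
                 inertia = best$tot.withinss,
                 seed = seed, replicates = replicates,
                 max_iter = max_iter, sigma = features$sigma),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: K = %d, inertia = %.4g\n", x$K, x$inertia))
  print(x$class_stats, row.names = FALSE)
  invisible(x)
}

#' Automatic selection of the number of classes
#'
#' Searches K upward for the smallest partition in which the outer borders
#' of bright structure along x, y and z are each encoded by their own
#' class: for each K it fits K-means and accepts iff the classes attaining
#' the maximal mean second derivative along x, y and z (original units)
#' (i) all have strictly positive means, and (ii) are three distinct
#' classes. A class attaining the argmax for two axes rejects the K.
#'
#' @param features a `feature_volume`.
#' @param K_min,K_max search range (defaults 2 and 10).
#' @param replicates,max_iter,seed passed to [fit_kmeans()].
#' @return list `K` (the accepted value), `model` (its `cluster_model`),
#'   `diagnostics` (per-K data frame: argmax classes, their means,
#'   accepted flag).
#' @export
auto_select_K <- function(features, K_min = 2L, K_max = 10L,
                          replicates = 10L, max_iter = 1000L, seed = 42L) {
  stopifnot(K_min >= 2, K_min <= K_max)
  diag <- list()
  for (K in K_min:K_max) {
    model <- tryCatch(
      fit_kmeans(features, K, replicates, max_iter, seed),
      error = function(e) NULL)
    if (is.null(model)) {
      diag[[length(diag) + 1L]] <- data.frame(
        K = K, cx = NA, cy = NA, cz = NA, mx = NA, my = NA, mz = NA,
        accepted = FALSE)
      next
    }
    st <- model$class_stats
    cx <- which.max(st$mean_d2x)
    cy <- which.max(st$mean_d2y)
    cz <- which.max(st$mean_d2z)
    ok <- st$mean_d2x[cx] > 0 && st$mean_d2y[cy] > 0 &&
      st$mean_d2z[cz] > 0 && length(unique(c(cx, cy, cz))) == 3L
    diag[[length(diag) + 1L]] <- data.frame(
      K = K, cx = cx, cy = cy, cz = cz,
      mx = st$mean_d2x[cx], my = st$mean_d2y[cy], mz = st$mean_d2z[cz],
      accepted = ok)
    if (ok)
      return(list(K = K, model = model,
                  diagnostics = do.call(rbind, diag)))
  }
  stop("no border-encoding partition found for K in ", K_min, "..", K_max,
       " (structureless input?)")
}

#' Select the neuronal classes of a fitted model
#'
#' Neuronal structure is encoded by the classes whose mean second
#' derivatives along all three axes are negative (bright interior); these
#' are normally the top-intensity classes. Class 1 (the dimmest, the
#' homogeneous background class) is never returned. A warning is emitted
#' when the selection is not a suffix of the intensity ranking, since that
#' indicates an atypical partition worth inspecting.
#'
#' @param model a `cluster_model`.
#' @return integer vector of selected class ids.
#' @export
select_neuronal_classes <- function(model) {
  st <- model$class_stats
  neg <- st$mean_d2x < 0 & st$mean_d2y < 0 & st$mean_d2z < 0
  sel <- st$class[neg]
  if (1L %in% sel) {
    warning("class 1 (lowest intensity) has all-negative mean second ",
            "derivatives; excluded from the neuronal selection")
    sel <- setdiff(sel, 1L)
  }
  if (length(sel) == 0)
    stop("no neuronal class found: no class has all-negative mean second ",
         "derivatives")
  suffix <- (model$K - length(sel) + 1L):model$K
  if (!setequal(sel, suffix))
    warning("selected classes {", paste(sort(sel), collapse = ", "),
            "} are not the top-intensity classes")
  sort(sel)
}

#' Fill enclosed cavities of a binary mask
#'
#' Background connected components (6-connectivity) with no path to the
#' volume border become foreground; existing foreground is never removed.
#' Intensity inhomogeneity inside thick structures (somata) otherwise
#' leaves false-negative holes in the segmentation.
#'
#' @param mask logical 3-D array.
#' @return logical 3-D array.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  out <- fill_holes_cpp(mask, dim(mask))
  array(out, dim(mask))
}

#' Remove connected components below a size threshold
#'
#' Components are 26-connected; the default threshold of 7 voxels removes
#' anything smaller than the smallest 3-D symmetric structure (a centre
#' voxel plus its 6 face neighbours), which is where background
#' inhomogeneity noise lives. Idempotent.
#'
#' @param mask logical 3-D array.
#' @param min_voxels minimum surviving component size (default 7).
#' @return logical 3-D array.
#' @export
remove_small_clusters <- function(mask, min_voxels = 7L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, min_voxels >= 1)
  lab <- cc_label_cpp(mask, dim(mask), 26L)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  out <- array(lab %in% keep, dim(mask))
  out
}

# internal: one clustering level -> binary mask over foreground
segment_one_level <- function(stack, sigma, foreground, config) {
  features <- build_features(stack, sigma, foreground,
                             standardize = config$standardize)
  if (identical(config$K, "auto")) {
    sel_K <- auto_select_K(features, config$K_min, config$K_max,
                           config$kmeans_replicates, config$kmeans_max_iter,
                           config$random_seed)
    model <- sel_K$model
  } else {
    model <- fit_kmeans(features, config$K, config$kmeans_replicates,
                        config$kmeans_max_iter, config$random_seed)
  }
  classes <- select_neuronal_classes(model)
  mask <- array(FALSE, dim(stack$data))
  mask[foreground] <- model$labels %in% classes
  list(mask = mask, model = model, classes = classes, sigma = sigma)
}

#' Segment a stack into a neuronal mask
#'
#' The full first step: optional log transform, background exclusion, then
#' for each smoothing level in `config$sigmas` a K-means clustering of the
#' 4-D features with class selection; the per-level binary masks are merged
#' by voxelwise OR (multi-scale union), holes are filled and small
#' components pruned.
#'
#' @param stack an [image_stack].
#' @param config a [pipeline_config()].
#' @return object of class `segmentation_mask`: `mask` (logical 3-D
#'   array), `provenance` (per-level sigma, K, selected classes, class
#'   stats, threshold).
#' @export
segment <- function(stack, config = pipeline_config()) {
  st <- as_stack(stack)
  if (length(config$sigmas) == 0) stop("config$sigmas must be non-empty")
  work <- if (config$log_transform) log_transform(st) else st
  foreground <- background_mask(work, config$background_method,
                                config$background_value)
  levels <- lapply(config$sigmas, function(s)
    segment_one_level(work, s, foreground, config))
  mask <- Reduce(`|`, lapply(levels, `[[`, "mask"))
  mask <- fill_holes(mask)
  mask <- remove_small_clusters(mask, config$min_cluster_voxels)
  provenance <- lapply(levels, function(l)
    list(sigma = l$sigma, K = l$model$K, classes = l$classes,
         class_stats = l$model$class_stats,
         inertia = l$model$inertia))
  structure(list(mask = mask, provenance = provenance,
                 threshold = attr(foreground, "threshold"),
                 foreground = foreground),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %d voxels in %s volume, %d level(s)\n",
              sum(x$mask), paste(dim(x$mask), collapse = "x"),
              length(x$provenance)))
  for (l in x$provenance)
    cat(sprintf("  sigma %.3g: K = %d, classes {%s}\n", l$sigma, l$K,
                paste(l$classes, collapse = ", ")))
  invisible(x)
}

#' Learn on a crop, apply to the full volume
#'
#' For large stacks the K-means can be trained on a user-defined crop:
#' centroids and class selection are learned there, then every
#' full-volume foreground voxel is labelled by its nearest learned
#' centroid (features standardized with the crop's parameters) and the
#' mask is binarized and post-processed exactly as in [segment()].
#'
#' @param stack an [image_stack].
#' @param config a [pipeline_config()].
#' @param crop_bounds list with `z`, `y`, `x` integer ranges (1-based
#'   inclusive, e.g. `list(z = c(1, 16), y = c(1, 64), x = c(1, 64))`).
#' @return a `segmentation_mask`.
#' @export
fit_on_crop_apply_full <- function(stack, config, crop_bounds) {
  st <- as_stack(stack)
  d <- dim(st$data)
  b <- crop_bounds
  for (ax in c("z", "y", "x"))
    if (is.null(b[[ax]]) || length(b[[ax]]) != 2L)
      stop("crop_bounds must have z, y, x ranges")
  if (b$z[1] < 1 || b$z[2] > d[1] || b$y[1] < 1 || b$y[2] > d[2] ||
      b$x[1] < 1 || b$x[2] > d[3])
    stop("crop out of volume bounds")
  work <- if (config$log_transform) log_transform(st) else st
  crop <- image_stack(work$data[b$z[1]:b$z[2], b$y[1]:b$y[2],
                                b$x[1]:b$x[2], drop = FALSE],
                      st$voxel_size, st$dtype_range)
  fg_full <- background_mask(work, config$background_method,
                             config$background_value)
  fg_crop <- fg_full[b$z[1]:b$z[2], b$y[1]:b$y[2], b$x[1]:b$x[2],
                     drop = FALSE]
  if (!any(fg_crop)) stop("crop contains no foreground")
  masks <- list()
  provenance <- list()
  for (s in config$sigmas) {
    feats_crop <- build_features(crop, s, fg_crop,
                                 standardize = config$standardize)
    if (identical(config$K, "auto")) {
      sel_K <- auto_select_K(feats_crop, config$K_min, config$K_max,
                             config$kmeans_replicates,
                             config$kmeans_max_iter, config$random_seed)
      model <- sel_K$model
    } else {
      model <- fit_kmeans(feats_crop, config$K, config$kmeans_replicates,
                          config$kmeans_max_iter, config$random_seed)
    }
    classes <- select_neuronal_classes(model)
    # full-volume features standardized with the crop's parameters
    feats_full <- build_features(work, s, fg_full, standardize = FALSE)
    Xf <- sweep(sweep(feats_full$raw, 2, feats_crop$center), 2,
                feats_crop$scale, "/")
    assign <- nearest_centroid(Xf, model$centroids)
    m <- array(FALSE, d)
    m[fg_full] <- assign %in% classes
    masks[[length(masks) + 1L]] <- m
    provenance[[length(provenance) + 1L]] <-
      list(sigma = s, K = model$K, classes = classes,
           class_stats = model$class_stats, inertia = model$inertia)
  }
  mask <- Reduce(`|`, masks)
  mask <- fill_holes(mask)
  mask <- remove_small_clusters(mask, config$min_cluster_voxels)
  structure(list(mask = mask, provenance = provenance,
                 threshold = attr(fg_full, "threshold"),
                 foreground = fg_full),
            class = "segmentation_mask")
}

# assign rows of X to the nearest centroid (squared Euclidean)
nearest_centroid <- function(X, centroids) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; the ||x||^2 term is constant
  cross <- X %*% t(centroids)
  cn <- rowSums(centroids^2)
  scores <- sweep(-2 * cross, 2, cn, "+")
  max.col(-scores, ties.method = "first")
}
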