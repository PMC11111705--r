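# Step 2: marker-controlled watershed parcellation. Cores (somata or thick
# trunks) seed wells in the complemented, median-filtered intensity volume;
# morphological reconstruction erases every other regional minimum; the
# watershed assigns each voxel of the volume to one catchment basin; finally
# whole non-core clusters of the segmentation (detached spines, broken
# branches) are assigned to the core whose basin holds them.

#' Define cores automatically by component size
#'
#' In the super-resolution regime cores need no manual marking: 26-connected
#' components of the segmentation at or above `size_threshold` voxels become
#' cores (one label each, ordered by decreasing size); smaller components
#' are listed as spine clusters awaiting assignment.
#'
#' @param mask logical 3-D array (the segmentation).
#' @param size_threshold minimum core size in voxels.
#' @return object of class `core_set`: `cores` (integer 3-D label array),
#'   `n_cores`, `origin = "auto"`, `spine_clusters` (data frame of
#'   component id and size for sub-threshold components),
#'   `component_labels` (the full component labelling).
#' @export
define_cores_auto <- function(mask, size_threshold) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, size_threshold >= 1)
  if (!any(mask)) stop("mask is empty")
  lab <- cc_label_cpp(mask, dim(mask), 26L)
  sizes <- tabulate(lab[lab > 0L])
  big <- which(sizes >= size_threshold)
  if (length(big) == 0)
    stop("no core found: no component reaches ", size_threshold, " voxels")
  big <- big[order(sizes[big], decreasing = TRUE)]
  cores <- array(0L, dim(mask))
  for (i in seq_along(big)) cores[lab == big[i]] <- i
  small <- setdiff(which(sizes > 0), big)
  structure(list(cores = cores, n_cores = length(big), origin = "auto",
                 size_threshold = size_threshold,
                 spine_clusters = data.frame(component = small,
                                             size = sizes[small]),
                 component_labels = array(lab, dim(mask))),
            class = "core_set")
}

#' Define cores from soma markers
#'
#' Each marker seeds one core: a ball of `radius` voxels around the marker,
#' clipped to the volume, labelled with the marker's label. The ball makes
#' a single-click marker a robust watershed well. Markers falling outside
#' the segmentation mask are accepted with a warning (somata are often
#' under-segmented), but overlapping seed balls are an error.
#'
#' @param mask logical 3-D array (the segmentation).
#' @param markers a [marker_set()] of somata.
#' @param radius seed ball radius in voxels (default 2).
#' @return a `core_set` with `origin = "manual"`.
#' @export
define_cores_manual <- function(mask, markers, radius = 2L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (nrow(markers) == 0) stop("no markers given")
  d <- dim(mask)
  check_markers_in_bounds(markers, d)
  offs <- ball_offsets(radius)
  cores <- array(0L, d)
  owner <- integer(0)
  for (i in seq_len(nrow(markers))) {
    lbl <- markers$label[i]
    zz <- markers$z[i] + 1L + offs[, 1]
    yy <- markers$y[i] + 1L + offs[, 2]
    xx <- markers$x[i] + 1L + offs[, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    idx <- cbind(zz[ok], yy[ok], xx[ok])
    hit <- cores[idx]
    if (any(hit > 0))
      stop("marker seed regions overlap: labels ", unique(hit[hit > 0])[1],
           " and ", lbl)
    cores[idx] <- lbl
    if (!mask[markers$z[i] + 1L, markers$y[i] + 1L, markers$x[i] + 1L])
      warning("marker ", lbl, " lies outside the segmentation mask")
  }
  structure(list(cores = cores, n_cores = nrow(markers),
                 origin = "manual", radius = radius,
                 marker_labels = markers$label),
            class = "core_set")
}

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Impose regional minima at core locations
#'
#' Minima imposition on a topographic volume: the marker is set below the
#' global range at core voxels and above it elsewhere, and morphological
#' reconstruction by erosion of `pmin(vol + 1, marker)` under the marker
#' erases every regional minimum except those at the cores.
#'
#' @param vol numeric 3-D array (the topography, here the complemented
#'   median-filtered intensity).
#' @param cores integer 3-D array of core labels (0 = none).
#' @return numeric 3-D array whose regional minima coincide with the cores.
#' @export
impose_minima <- function(vol, cores) {
  stopifnot(identical(dim(vol), dim(cores)))
  if (!any(cores > 0)) stop("no cores to impose")
  lo <- min(vol) - 1
  hi <- max(vol) + 2
  marker <- array(hi, dim(vol))
  marker[cores > 0] <- lo
  mask <- pmin(vol + 1, marker)
  mask <- array(mask, dim(vol))
  out <- reconstruct_erode_cpp(as.numeric(marker), as.numeric(mask),
                               dim(vol))
  array(out, dim(vol))
}

#' Parcellate a segmentation into single-neuron labels
#'
#' The grayscale stack is filtered with a 3x3x3 median filter, complemented
#' (max - filtered), and its regional minima outside the cores are erased
#' by morphological reconstruction; a 3-D watershed then floods one
#' catchment basin per core over the whole volume. Segmentation voxels are
#' labelled as follows: connected clusters containing exactly one core keep
#' that core's label; clusters spanning several cores are split voxelwise
#' along the watershed lines; core-free clusters (detached spines, broken
#' branches) are assigned whole to the core whose basin holds the majority
#' of their voxels (see [assign_clusters()]).
#'
#' @param stack the raw [image_stack].
#' @param mask logical 3-D segmentation array.
#' @param cores a `core_set`.
#' @return object of class `parcellation`: `labels` (integer 3-D array, 0
#'   outside the mask), `basins` (integer 3-D array tiling the volume),
#'   `assignments` (data frame: cluster id, size, core, rule, tie flag),
#'   `watershed_lines` (logical 3-D array), `cores`.
#' @export
parcellate <- function(stack, mask, cores) {
  st <- as_stack(stack)
  stopifnot(identical(dim(st$data), dim(mask)))
  core_vol <- cores$cores
  if (!any(core_vol > 0)) stop("core set is empty")
  med <- median_filter3_cpp(as.numeric(st$data), dim(mask))
  comp <- max(med) - med
  topo <- impose_minima(array(comp, dim(mask)), core_vol)
  basins <- watershed_flood_cpp(as.numeric(topo), as.integer(core_vol),
                                dim(mask))
  basins <- array(basins, dim(mask))
  stopifnot(all(basins > 0))  # post-imposition every basin holds a core
  clusters <- array(cc_label_cpp(mask, dim(mask), 26L), dim(mask))
  assignments <- assign_clusters(clusters, basins, core_vol)
  labels <- array(0L, dim(mask))
  in_mask <- clusters > 0L
  lab_of <- integer(max(clusters, 1L))
  lab_of[assignments$cluster] <- assignments$core
  labels[in_mask] <- lab_of[clusters[in_mask]]
  multi <- assignments$cluster[assignments$rule == "split"]
  for (cl in multi) {
    sel <- clusters == cl
    labels[sel] <- basins[sel]
  }
  lines <- watershed_lines(basins)
  structure(list(labels = labels, basins = basins,
                 assignments = assignments, watershed_lines = lines,
                 cores = cores),
            class = "parcellation")
}

# boundary voxels: any 6-neighbour in a different basin
watershed_lines <- function(basins) {
  d <- dim(basins)
  out <- array(FALSE, d)
  shift_ne <- function(a, axis, by) {
    n <- dim(a)[axis]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    if (axis == 1) a[idx, , , drop = FALSE]
    else if (axis == 2) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    out <- out | (basins != shift_ne(basins, axis, by))
  out
}

#' Assign whole clusters to cores by basin majority
#'
#' Each connected cluster of the segmentation that contains no core voxels
#' is assigned to the core of the basin holding the majority of its voxels;
#' ties are broken by the basin containing the cluster's centroid, then by
#' the lowest core label. Clusters containing exactly one core keep it;
#' clusters containing two or more cores are flagged for voxelwise
#' splitting.
#'
#' @param clusters integer 3-D array of 26-connected component labels of
#'   the mask (0 = background).
#' @param basins integer 3-D array of catchment-basin core labels.
#' @param core_vol integer 3-D array of core labels.
#' @return data frame: `cluster`, `size`, `core`, `rule` (one of
#'   `"own_core"`, `"majority"`, `"centroid_tie"`, `"split"`), `tie`.
#' @export
assign_clusters <- function(clusters, basins, core_vol) {
  ncl <- max(clusters)
  if (ncl == 0) return(data.frame(cluster = integer(0), size = integer(0),
                                  core = integer(0), rule = character(0),
                                  tie = logical(0)))
  idx <- which(clusters > 0L)
  cl <- clusters[idx]
  bs <- basins[idx]
  cv <- core_vol[idx]
  out <- vector("list", ncl)
  d <- dim(clusters)
  zyx <- arrayInd(idx, d)
  for (k in seq_len(ncl)) {
    sel <- cl == k
    size <- sum(sel)
    own <- unique(cv[sel & cv > 0])
    if (length(own) == 1L) {
      out[[k]] <- data.frame(cluster = k, size = size, core = own,
                             rule = "own_core", tie = FALSE)
      next
    }
    if (length(own) > 1L) {
      out[[k]] <- data.frame(cluster = k, size = size, core = NA_integer_,
                             rule = "split", tie = FALSE)
      next
    }
    tab <- table(bs[sel])
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) {
      out[[k]] <- data.frame(cluster = k, size = size, core = top,
                             rule = "majority", tie = FALSE)
    } else {
      cen <- round(colMeans(zyx[sel, , drop = FALSE]))
      cen <- pmin(pmax(cen, 1), d)
      cb <- basins[cen[1], cen[2], cen[3]]
      core <- if (cb %in% top) cb else min(top)
      out[[k]] <- data.frame(cluster = k, size = size, core = core,
                             rule = "centroid_tie", tie = TRUE)
    }
  }
  do.call(rbind, out)
}

#' Correct a parcellation with additional markers
#'
#' Misassigned branches (typically from neurons whose soma lies outside the
#' field of view) are fixed by adding markers on them: the markers become
#' additional cores and the parcellation re-runs with the enlarged core
#' set. With no extra markers the result is returned unchanged.
#'
#' @param result a `parcellation`.
#' @param stack the raw [image_stack] used for the original run.
#' @param mask the segmentation mask used for the original run.
#' @param extra_markers a [marker_set()]; labels must not collide with
#'   existing core labels.
#' @return a new `parcellation`.
#' @export
correct_parcellation <- function(result, stack, mask, extra_markers) {
  if (is.null(extra_markers) || nrow(extra_markers) == 0) return(result)
  old <- result$cores
  radius <- if (!is.null(old$radius)) old$radius else 2L
  clash <- intersect(extra_markers$label, sort(unique(old$cores[old$cores > 0])))
  if (length(clash))
    stop("extra marker labels collide with existing cores: ",
         paste(clash, collapse = ", "))
  check_markers_in_bounds(extra_markers, dim(mask))
  new_cores <- old$cores
  offs <- ball_offsets(radius)
  d <- dim(mask)
  for (i in seq_len(nrow(extra_markers))) {
    lbl <- extra_markers$label[i]
    zz <- extra_markers$z[i] + 1L + offs[, 1]
    yy <- extra_markers$y[i] + 1L + offs[, 2]
    xx <- extra_markers$x[i] + 1L + offs[, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    idx <- cbind(zz[ok], yy[ok], xx[ok])
    hit <- new_cores[idx]
    if (any(hit > 0))
      stop("extra marker ", lbl, " overlaps core ", unique(hit[hit > 0])[1])
    new_cores[idx] <- lbl
  }
  cs <- structure(list(cores = new_cores,
                       n_cores = old$n_cores + nrow(extra_markers),
                       origin = old$origin, radius = radius),
                  class = "core_set")
  parcellate(stack, mask, cs)
}

#' @export
print.parcellation <- function(x, ...) {
  labs <- sort(unique(x$labels[x$labels > 0]))
  cat(sprintf("parcellation: %d neuron label(s) over %d mask voxels\n",
              length(labs), sum(x$labels > 0)))
  cat(sprintf("  %d cluster(s): %s\n", nrow(x$assignments),
              paste(sprintf("%d->%s", x$assignments$cluster,
                            ifelse(x$assignments$rule == "split", "split",
                                   x$assignments$core)),
                    collapse = " ")))
  invisible(x)
}
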