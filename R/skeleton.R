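# Reduction of a single-neuron volumetric segmentation to a rooted tree and
# SWC: topology-preserving 3-D thinning, voxel graph construction, cycle
# removal at the lowest-intensity points, rooting at the soma marker.

#' Skeletonize a single-neuron mask
#'
#' Topology-preserving curve thinning: simple points (whose removal changes
#' neither foreground 26-connectivity nor background 6-connectivity
#' locally) are deleted in six directional sub-iterations per cycle until
#' stable, preserving curve endpoints. The result is a 1-voxel-wide,
#' 26-connected subset of the mask.
#'
#' @param mask logical 3-D array; must be a single 26-connected component.
#' @return logical 3-D array (the skeleton).
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask is empty")
  lab <- cc_label_cpp(mask, dim(mask), 26L)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0])
    stop("mask has ", ncomp, " connected components (sizes ",
         paste(sizes, collapse = ", "),
         "); skeletonize one neuron at a time")
  }
  array(thin3d_cpp(mask, dim(mask)), dim(mask))
}

#' Build a voxel graph from a skeleton
#'
#' One node per skeleton voxel, an undirected edge between every pair of
#' 26-neighbouring skeleton voxels, with physical length
#' `sqrt((dz du_z)^2 + (dy du_y)^2 + (dx du_x)^2)` in micrometres. Node
#' intensity is sampled from the raw stack; node radius is either the
#' Euclidean distance transform of the mask at the node (physical units,
#' `radius_mode = "edt"`, geometrically verifiable) or proportional to
#' node intensity normalized by the skeleton maximum times `radius_scale`
#' (`radius_mode = "intensity"`).
#'
#' @param skel logical 3-D skeleton array.
#' @param stack the raw [image_stack].
#' @param mask the segmentation the skeleton came from (for EDT radii).
#' @param radius_mode `"edt"` or `"intensity"`.
#' @param radius_scale calibration factor for intensity radii (um).
#' @return object of class `skeleton_graph`: `nodes` (data frame id, z, y,
#'   x (0-based voxels), intensity, radius), `edges` (data frame from, to,
#'   length), `voxel_size`.
#' @export
graph_from_skeleton <- function(skel, stack, mask = NULL,
                                radius_mode = c("edt", "intensity"),
                                radius_scale = 1) {
  st <- as_stack(stack)
  radius_mode <- match.arg(radius_mode)
  stopifnot(identical(dim(skel), dim(st$data)))
  idx <- which(skel)
  if (length(idx) == 0) stop("skeleton is empty")
  d <- dim(skel)
  zyx <- arrayInd(idx, d)  # 1-based
  vs <- st$voxel_size
  intensity <- st$data[idx]
  if (radius_mode == "edt") {
    if (is.null(mask)) stop("radius_mode 'edt' needs the mask")
    edt <- edt_cpp(mask, d, vs)
    radius <- edt[idx]
  } else {
    radius <- intensity / max(intensity) * radius_scale
  }
  nodes <- data.frame(id = seq_along(idx),
                      z = zyx[, 1] - 1L, y = zyx[, 2] - 1L,
                      x = zyx[, 3] - 1L,
                      intensity = as.numeric(intensity),
                      radius = as.numeric(radius))
  # edges between 26-neighbours; enumerate half the offsets to avoid dupes
  node_at <- array(0L, d)
  node_at[idx] <- nodes$id
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  keep <- offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    zz <- zyx[, 1] + o[1]; yy <- zyx[, 2] + o[2]; xx <- zyx[, 3] + o[3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    if (!any(ok)) next
    nb <- node_at[cbind(zz[ok], yy[ok], xx[ok])]
    hit <- nb > 0L
    if (!any(hit)) next
    from <- c(from, nodes$id[ok][hit])
    to <- c(to, nb[hit])
    len <- c(len, rep(sqrt(sum((o * c(vs[1], vs[2], vs[3]))^2)), sum(hit)))
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, length = len),
                 voxel_size = vs),
            class = "skeleton_graph")
}

#' Remove cycles by cutting at the lowest image intensity
#'
#' Computes the maximum-weight spanning tree of the skeleton graph with
#' edge weight = min(intensity of the two endpoints): every cycle is cut at
#' its dimmest point, the natural place for a spurious loop closure.
#' Deterministic Kruskal with ties broken by keeping the shorter edge
#' first, then by lexicographic node ids.
#'
#' @param graph a `skeleton_graph`; must be connected.
#' @return a `skeleton_graph` whose edges form a spanning tree.
#' @export
break_cycles <- function(graph) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = graph$nodes$id))
  if (igraph::components(g)$no > 1L)
    stop("skeleton graph is disconnected")
  if (nrow(e) == n - 1L) return(graph)
  w <- pmin(graph$nodes$intensity[e$from], graph$nodes$intensity[e$to])
  a <- pmin(e$from, e$to)
  b <- pmax(e$from, e$to)
  ord <- order(-w, e$length, a, b)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(e))
  taken <- 0L
  for (r in ord) {
    ra <- find(e$from[r]); rb <- find(e$to[r])
    if (ra != rb) {
      parent[ra] <- rb
      keep[r] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  out <- graph
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Root a spanning tree at the soma
#'
#' The root is the tree node nearest (in physical distance) to the soma
#' marker; parent pointers are oriented away from it by breadth-first
#' traversal.
#'
#' @param tree a `skeleton_graph` whose edges form a tree.
#' @param soma_marker numeric `(z, y, x)` in 0-based voxels, or a 1-row
#'   [marker_set()].
#' @return object of class `neuron_tree`: `nodes` (data frame id, z, y, x
#'   0-based voxels, radius, intensity, parent with root parent = -1),
#'   `voxel_size`, `root`.
#' @export
root_tree <- function(tree, soma_marker) {
  if (inherits(soma_marker, "data.frame"))
    soma_marker <- c(soma_marker$z[1], soma_marker$y[1], soma_marker$x[1])
  nd <- tree$nodes
  e <- tree$edges
  if (nrow(e) != nrow(nd) - 1L)
    stop("edges do not form a spanning tree; run break_cycles() first")
  vs <- tree$voxel_size
  d2 <- ((nd$z - soma_marker[1]) * vs[1])^2 +
        ((nd$y - soma_marker[2]) * vs[2])^2 +
        ((nd$x - soma_marker[3]) * vs[3])^2
  root <- nd$id[which.min(d2)]
  adj <- vector("list", nrow(nd))
  for (r in seq_len(nrow(e))) {
    adj[[e$from[r]]] <- c(adj[[e$from[r]]], e$to[r])
    adj[[e$to[r]]] <- c(adj[[e$to[r]]], e$from[r])
  }
  parent <- rep(NA_integer_, nrow(nd))
  parent[root] <- -1L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (is.na(parent[u])) {
      parent[u] <- v
      queue <- c(queue, u)
    }
  }
  if (anyNA(parent)) stop("tree is disconnected")
  nodes <- data.frame(id = nd$id, z = nd$z, y = nd$y, x = nd$x,
                      radius = nd$radius, intensity = nd$intensity,
                      parent = parent)
  structure(list(nodes = nodes, voxel_size = vs, root = root),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("neuron_tree: %d nodes, root id %d, total cable %.2f um\n",
              nrow(x$nodes), x$root, total_cable_length(x)))
  invisible(x)
}

# physical length of the edge from each non-root node to its parent
parent_edge_lengths <- function(tree) {
  nd <- tree$nodes
  vs <- tree$voxel_size
  nonroot <- nd$parent > 0
  p <- match(nd$parent[nonroot], nd$id)
  i <- which(nonroot)
  sqrt(((nd$z[i] - nd$z[p]) * vs[1])^2 +
       ((nd$y[i] - nd$y[p]) * vs[2])^2 +
       ((nd$x[i] - nd$x[p]) * vs[3])^2)
}

#' Total cable length of a rooted tree (um)
#' @param tree a `neuron_tree`.
#' @return sum of parent-edge lengths in micrometres.
#' @export
total_cable_length <- function(tree) sum(parent_edge_lengths(tree))

#' Write a rooted tree to SWC
#'
#' Standard 7-column whitespace-separated SWC: id, type, x, y, z, radius,
#' parent. Coordinates convert from 0-based voxel indices to micrometres
#' (`x = x_index * dx`, etc.), radii are already in micrometres, the root
#' has parent -1 and type 1 (soma); all other nodes are type 3 (dendrite).
#'
#' @param tree a `neuron_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  nd <- tree$nodes
  vs <- tree$voxel_size
  ord <- order(nd$id)
  nd <- nd[ord, ]
  type <- ifelse(nd$parent == -1L, 1L, 3L)
  lines <- sprintf("%d %d %.8f %.8f %.8f %.8f %d",
                   nd$id, type,
                   nd$x * vs[3], nd$y * vs[2], nd$z * vs[1],
                   nd$radius, nd$parent)
  writeLines(c("# SWC export (coordinates in um, axis order x y z)",
               lines), path)
  invisible(path)
}

#' Read an SWC file
#'
#' @param path SWC path ('#' comment lines ignored).
#' @param voxel_size `(dz, dy, dx)` in um used to convert coordinates back
#'   to voxel indices; default 1 um isotropic keeps coordinates as-is.
#' @return a `neuron_tree` (coordinates in voxel units of `voxel_size`).
#' @export
read_swc <- function(path, voxel_size = c(1, 1, 1)) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  rows <- which(keep)
  if (length(rows) == 0) stop("SWC file has no data rows")
  parts <- strsplit(trimws(raw[rows]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 7L)
  if (length(bad))
    stop("malformed SWC at line ", rows[bad[1]], ": expected 7 columns")
  m <- suppressWarnings(do.call(rbind, lapply(parts, as.numeric)))
  if (anyNA(m)) {
    badl <- rows[which(apply(is.na(m), 1, any))[1]]
    stop("malformed SWC at line ", badl, ": non-numeric field")
  }
  nodes <- data.frame(id = as.integer(m[, 1]),
                      z = m[, 5] / voxel_size[1],
                      y = m[, 4] / voxel_size[2],
                      x = m[, 3] / voxel_size[3],
                      radius = m[, 6],
                      intensity = NA_real_,
                      parent = as.integer(m[, 7]))
  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) != 1L)
    stop("SWC must have exactly one root (found ", length(roots), ")")
  nonroot <- nodes$parent != -1L
  if (!all(nodes$parent[nonroot] %in% nodes$id))
    stop("SWC parent references a missing id")
  structure(list(nodes = nodes, voxel_size = as.numeric(voxel_size),
                 root = roots),
            class = "neuron_tree")
}
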