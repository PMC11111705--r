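# Morphometric validation suite: segment/branch decomposition with
# centripetal Horton-Strahler ordering and its summary table, Sholl
# analysis with AUC, Dice overlap, surface area / volume, and spine
# detection sensitivity/precision.

# ---- segment decomposition --------------------------------------------

#' Decompose a rooted tree into segments and compute Strahler orders
#'
#' Segments are maximal node chains between topological points (root,
#' branch points, terminations). Orders follow the classic centripetal
#' recursion on the segment tree: terminal segments get order 1; at a
#' junction the parent gets `s + 1` when two or more children attain the
#' maximal child order `s`, else `s`. Per-node order is the order of the
#' containing segment (junction nodes take the higher, parent-side order).
#'
#' @param tree a `neuron_tree`.
#' @return object of class `segment_decomposition`: `segments` (data frame
#'   id, parent (segment), SO, length, mean_diameter, n_nodes, head, tail),
#'   `node_SO` (per tree node), `segment_of_node`, `SN` (Strahler number),
#'   `branches` (data frame id, SO, length, mean_diameter, n_segments).
#' @export
strahler_order <- function(tree) {
  nd <- tree$nodes
  n <- nrow(nd)
  id2row <- integer(max(nd$id)); id2row[nd$id] <- seq_len(n)
  parent_row <- ifelse(nd$parent > 0, id2row[pmax(nd$parent, 1)], NA)
  children <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(parent_row[i]))
    children[[parent_row[i]]] <- c(children[[parent_row[i]]], i)
  nchild <- lengths(children)
  root_row <- which(nd$parent == -1L)
  elen <- rep(0, n)  # length of edge to parent
  vs <- tree$voxel_size
  nr <- which(!is.na(parent_row))
  pr <- parent_row[nr]
  elen[nr] <- sqrt(((nd$z[nr] - nd$z[pr]) * vs[1])^2 +
                   ((nd$y[nr] - nd$y[pr]) * vs[2])^2 +
                   ((nd$x[nr] - nd$x[pr]) * vs[3])^2)
  # topological points: root, leaves, branch nodes
  topo <- nchild == 0L | nchild >= 2L
  topo[root_row] <- TRUE
  # walk from each child of a topological point down to the next one
  seg_head <- integer(0); seg_tail <- integer(0)
  seg_parent_node <- integer(0)
  seg_nodes <- list()
  for (tp in which(topo)) {
    for (ch in children[[tp]]) {
      chain <- c(tp, ch)
      cur <- ch
      while (!topo[cur]) {
        cur <- children[[cur]][1]
        chain <- c(chain, cur)
      }
      seg_head <- c(seg_head, tp)
      seg_tail <- c(seg_tail, cur)
      seg_nodes[[length(seg_nodes) + 1L]] <- chain
    }
  }
  ns <- length(seg_nodes)
  # a root with >= 2 stems still merges orders: represent it as a
  # zero-length segment so the centripetal increment applies at the soma
  if (ns > 0L && nchild[root_row] >= 2L) {
    ns <- ns + 1L
    seg_nodes[[ns]] <- root_row
    seg_head <- c(seg_head, root_row)
    seg_tail <- c(seg_tail, root_row)
  }
  if (ns == 0L) {  # single-node tree
    segments <- data.frame(id = 1L, parent = NA_integer_, SO = 1L,
                           length = 0, mean_diameter = 2 * nd$radius[1],
                           n_nodes = 1L, head = root_row, tail = root_row)
    return(structure(list(segments = segments, node_SO = 1L,
                          segment_of_node = 1L, SN = 1L,
                          branches = data.frame(
                            id = 1L, SO = 1L, length = 0,
                            mean_diameter = 2 * nd$radius[1],
                            n_segments = 1L)),
                     class = "segment_decomposition"))
  }
  # segment tree: the parent segment of s is the segment whose tail is
  # s's head (none for segments hanging off the root)
  tail2seg <- integer(n)
  tail2seg[seg_tail] <- seq_len(ns)
  seg_parent <- tail2seg[seg_head]   # 0 iff the head is the bare root
  seg_parent[seg_parent == 0L | seg_parent == seq_len(ns)] <- NA_integer_
  seg_children <- vector("list", ns)
  for (s in seq_len(ns)) if (!is.na(seg_parent[s]))
    seg_children[[seg_parent[s]]] <- c(seg_children[[seg_parent[s]]], s)
  # centripetal recursion, iterative postorder
  SO <- rep(NA_integer_, ns)
  order_stack <- integer(0)
  state <- rep(0L, ns)
  roots <- which(is.na(seg_parent))
  stack <- roots
  while (length(stack)) {
    s <- stack[length(stack)]
    if (state[s] == 0L) {
      state[s] <- 1L
      stack <- c(stack, seg_children[[s]])
    } else if (is.na(SO[s])) {
      stack <- stack[-length(stack)]
      kids <- seg_children[[s]]
      if (length(kids) == 0L) SO[s] <- 1L
      else {
        mx <- max(SO[kids])
        SO[s] <- if (sum(SO[kids] == mx) >= 2L) mx + 1L else mx
      }
    } else stack <- stack[-length(stack)]
  }
  seg_len <- vapply(seq_len(ns), function(s)
    sum(elen[seg_nodes[[s]][-1]]), 0)
  seg_diam <- vapply(seq_len(ns), function(s)
    mean(2 * nd$radius[seg_nodes[[s]]]), 0)
  # node orders: lower (child-side) segments first, higher orders override,
  # so junction nodes take the parent-side order
  node_SO <- rep(NA_integer_, n)
  seg_of <- rep(NA_integer_, n)
  for (s in order(SO)) {
    node_SO[seg_nodes[[s]]] <- SO[s]
    seg_of[seg_nodes[[s]]] <- s
  }
  segments <- data.frame(id = seq_len(ns), parent = seg_parent, SO = SO,
                         length = seg_len, mean_diameter = seg_diam,
                         n_nodes = lengths(seg_nodes),
                         head = seg_head, tail = seg_tail)
  branches <- merge_branches(segments, seg_nodes, nd)
  structure(list(segments = segments, node_SO = node_SO,
                 segment_of_node = seg_of, SN = max(SO),
                 branches = branches, seg_nodes = seg_nodes,
                 seg_children = seg_children),
            class = "segment_decomposition")
}

# branches: maximal unions of consecutive same-SO segments along
# parent-child chains
merge_branches <- function(segments, seg_nodes, nd) {
  ns <- nrow(segments)
  bparent <- seq_len(ns)
  find <- function(i) {
    while (bparent[i] != i) {
      bparent[i] <<- bparent[bparent[i]]
      i <- bparent[i]
    }
    i
  }
  for (s in seq_len(ns)) {
    p <- segments$parent[s]
    if (!is.na(p) && segments$SO[p] == segments$SO[s])
      bparent[find(s)] <- find(p)
  }
  grp <- vapply(seq_len(ns), find, 1L)
  ids <- unique(grp)
  out <- lapply(seq_along(ids), function(i) {
    mem <- which(grp == ids[i])
    nodes <- unique(unlist(seg_nodes[mem]))
    data.frame(id = i, SO = segments$SO[mem[1]],
               length = sum(segments$length[mem]),
               mean_diameter = mean(2 * nd$radius[nodes]),
               n_segments = length(mem))
  })
  do.call(rbind, out)
}

#' Strahler summary table
#'
#' The full per-order parameter set: segment and branch counts (raw and
#' normalized), branch bifurcation ratios, mean topological subtree size,
#' mean segment/branch diameters and lengths, total and per-order
#' normalized dendritic length, and the least-squares coefficients of
#' `log10(normalized count) ~ SO` for segments (`PSnum`) and branches
#' (`PBnum`). With a single order the fits are undefined and reported as
#' `NA` with `fit_defined = FALSE`.
#'
#' @param decomp a `segment_decomposition` from [strahler_order()], or a
#'   `neuron_tree` (decomposed on the fly).
#' @param fit_scale `"log10"` (default), `"natural"` or `"linear"` scale
#'   for the count-decay fits.
#' @return object of class `strahler_table` (a list; one element per
#'   quantity, per-order vectors indexed by SO 1..SN).
#' @export
strahler_stats <- function(decomp, fit_scale = c("log10", "natural",
                                                 "linear")) {
  fit_scale <- match.arg(fit_scale)
  if (inherits(decomp, "neuron_tree")) decomp <- strahler_order(decomp)
  seg <- decomp$segments
  br <- decomp$branches
  SN <- decomp$SN
  so <- seq_len(SN)
  numSegSO <- vapply(so, function(s) sum(seg$SO == s), 0L)
  numBrSO <- vapply(so, function(s) sum(br$SO == s), 0L)
  numSegSOnorm <- numSegSO / sum(numSegSO)
  numBrSOnorm <- numBrSO / sum(numBrSO)
  bifurcation_ratio <- if (SN >= 2)
    numBrSO[1:(SN - 1)] / numBrSO[2:SN] else numeric(0)
  # topological subtree size: number of segments in the subtree hanging
  # from each segment (itself included), averaged per order, normalized by
  # the total segment count
  ns <- nrow(seg)
  sub_sz <- rep(1L, ns)
  depth <- rep(0L, ns)
  for (s in seq_len(ns)) {
    p <- seg$parent[s]
    cur <- s
    while (!is.na(seg$parent[cur])) {
      depth[s] <- depth[s] + 1L
      cur <- seg$parent[cur]
    }
  }
  for (s in order(depth, decreasing = TRUE)) {
    p <- seg$parent[s]
    if (!is.na(p)) sub_sz[p] <- sub_sz[p] + sub_sz[s]
  }
  TopoSubLAve <- vapply(so, function(s)
    mean(sub_sz[seg$SO == s]) / ns, 0)
  segDAve <- vapply(so, function(s) mean(seg$mean_diameter[seg$SO == s]), 0)
  brDAve <- vapply(so, function(s) mean(br$mean_diameter[br$SO == s]), 0)
  segLAve <- vapply(so, function(s) mean(seg$length[seg$SO == s]), 0)
  brLAve <- vapply(so, function(s) mean(br$length[br$SO == s]), 0)
  TOTL <- sum(seg$length)
  normTotL <- vapply(so, function(s) sum(seg$length[seg$SO == s]), 0) /
    max(TOTL, .Machine$double.eps)
  fit_counts <- function(y) {
    nz <- y > 0
    if (sum(nz) < 2) return(c(slope = NA_real_, intercept = NA_real_))
    yy <- switch(fit_scale, log10 = log10(y[nz]), natural = log(y[nz]),
                 linear = y[nz])
    f <- coef(lm(yy ~ so[nz]))
    c(slope = unname(f[2]), intercept = unname(f[1]))
  }
  PSnum <- fit_counts(numSegSOnorm)
  PBnum <- fit_counts(numBrSOnorm)
  structure(list(SN = SN, numSegSO = numSegSO,
                 numSegSOnorm = numSegSOnorm, numBrSO = numBrSO,
                 numBrSOnorm = numBrSOnorm,
                 bifurcation_ratio = bifurcation_ratio,
                 TopoSubLAve = TopoSubLAve, segDAve = segDAve,
                 brDAve = brDAve, segLAve = segLAve, brLAve = brLAve,
                 TOTL = TOTL, normTotL = normTotL,
                 PSnum = PSnum, PBnum = PBnum,
                 fit_defined = !anyNA(PSnum), fit_scale = fit_scale),
            class = "strahler_table")
}

#' @export
print.strahler_table <- function(x, ...) {
  cat(sprintf("strahler_table: SN = %d, TOTL = %.2f um\n", x$SN, x$TOTL))
  df <- data.frame(SO = seq_len(x$SN), numSeg = x$numSegSO,
                   numBr = x$numBrSO,
                   segL = round(x$segLAve, 2), brL = round(x$brLAve, 2),
                   normTotL = round(x$normTotL, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- Sholl -------------------------------------------------------------

#' Sholl analysis of a rooted tree
#'
#' Counts, for each radius, the tree edges crossing the sphere of that
#' radius centred on the root (the soma centroid): an edge crosses iff its
#' endpoint distances `d` to the root satisfy `min(d) <= r < max(d)`.
#' The profile is summarized by its trapezoidal area under the curve.
#'
#' @param tree a `neuron_tree`.
#' @param radii strictly increasing radii in micrometres, first `> 0`.
#' @return object of class `sholl_profile`: `radii`, `crossings`, `AUC`.
#' @export
sholl <- function(tree, radii) {
  if (any(diff(radii) <= 0) || radii[1] <= 0)
    stop("radii must be strictly increasing and start > 0")
  nd <- tree$nodes
  vs <- tree$voxel_size
  r_row <- which(nd$parent == -1L)
  dist <- sqrt(((nd$z - nd$z[r_row]) * vs[1])^2 +
               ((nd$y - nd$y[r_row]) * vs[2])^2 +
               ((nd$x - nd$x[r_row]) * vs[3])^2)
  id2row <- integer(max(nd$id)); id2row[nd$id] <- seq_len(nrow(nd))
  nonroot <- which(nd$parent > 0)
  dchild <- dist[nonroot]
  dparent <- dist[id2row[nd$parent[nonroot]]]
  lo <- pmin(dchild, dparent)
  hi <- pmax(dchild, dparent)
  crossings <- vapply(radii, function(r) sum(lo <= r & r < hi), 0L)
  auc <- if (length(radii) >= 2)
    sum(diff(radii) * (head(crossings, -1) + tail(crossings, -1)) / 2)
  else 0
  structure(list(radii = radii, crossings = crossings, AUC = auc),
            class = "sholl_profile")
}

# ---- mask metrics ------------------------------------------------------

#' Dice overlap coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined as Dice 1 with a
#' warning.
#'
#' @param maskA,maskB logical arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    stop("mask shapes differ: ", paste(dim(maskA), collapse = "x"),
         " vs ", paste(dim(maskB), collapse = "x"))
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(maskA & maskB) / (a + b)
}

#' Surface area, volume and their ratio of a voxel mask
#'
#' Volume = voxel count x `dz dy dx`; surface area counts exposed voxel
#' faces (faces adjacent to background or the volume border), each weighted
#' by its physical face area (`dy dz` for x-faces, etc.).
#'
#' @param mask logical 3-D array, non-empty.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return list `area` (um^2), `volume` (um^3), `ratio` (1/um).
#' @export
area_volume <- function(mask, voxel_size = c(1, 1, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask is empty")
  vs <- as.numeric(voxel_size)
  volume <- sum(mask) * prod(vs)
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2]) # z-, y-, x-
  shift_pad <- function(a, axis, by) {
    d <- dim(a)
    out <- array(FALSE, d)
    n <- d[axis]
    if (axis == 1) {
      if (by > 0) out[2:n, , ] <- a[1:(n - 1), , ]
      else out[1:(n - 1), , ] <- a[2:n, , ]
    } else if (axis == 2) {
      if (by > 0) out[, 2:n, ] <- a[, 1:(n - 1), ]
      else out[, 1:(n - 1), ] <- a[, 2:n, ]
    } else {
      if (by > 0) out[, , 2:n] <- a[, , 1:(n - 1)]
      else out[, , 1:(n - 1)] <- a[, , 2:n]
    }
    out
  }
  area <- 0
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    exposed <- mask & !shift_pad(mask, axis, by)
    area <- area + sum(exposed) * face_area[axis]
  }
  list(area = area, volume = volume, ratio = area / volume)
}

#' Spine detection sensitivity and precision
#'
#' A ground-truth spine counts as a true positive iff some predicted spine
#' cluster contains its centre AND that cluster was assigned to the same
#' parent core; a predicted cluster can match at most one truth centre
#' (the one nearest the cluster centroid wins). Unmatched truth centres
#' are false negatives; predicted clusters matching no truth centre are
#' false positives. Correct detection with the wrong core assignment
#' counts as both a FN and a FP.
#'
#' @param spine_clusters integer 3-D array: predicted spine-cluster ids
#'   (0 elsewhere).
#' @param cluster_cores data frame with columns `cluster`, `core`: the
#'   core label each predicted cluster was assigned to.
#' @param truth a [marker_set()] of spine centres with an extra `core`
#'   column carrying the true parent-dendrite label.
#' @return list `TP`, `FN`, `FP`, `sensitivity_pct`, `precision_pct`,
#'   `matches` (data frame truth label -> cluster).
#' @export
spine_metrics <- function(spine_clusters, cluster_cores, truth) {
  stopifnot(length(dim(spine_clusters)) == 3L)
  if (!"core" %in% names(truth))
    stop("truth markers need a 'core' column (true parent label)")
  d <- dim(spine_clusters)
  check_markers_in_bounds(truth, d)
  core_of <- setNames(cluster_cores$core, cluster_cores$cluster)
  nt <- nrow(truth)
  at_cluster <- integer(nt)
  for (i in seq_len(nt))
    at_cluster[i] <- spine_clusters[truth$z[i] + 1L, truth$y[i] + 1L,
                                    truth$x[i] + 1L]
  # candidate = centre inside a cluster with matching core
  cand <- which(at_cluster > 0L &
                  core_of[as.character(at_cluster)] == truth$core)
  # a cluster matches at most one truth centre: nearest to its centroid
  matched_truth <- integer(0)
  matched_cluster <- integer(0)
  for (cl in unique(at_cluster[cand])) {
    cands <- cand[at_cluster[cand] == cl]
    if (length(cands) > 1L) {
      vox <- which(spine_clusters == cl)
      cen <- colMeans(arrayInd(vox, d))
      dd <- (truth$z[cands] + 1 - cen[1])^2 +
            (truth$y[cands] + 1 - cen[2])^2 +
            (truth$x[cands] + 1 - cen[3])^2
      cands <- cands[which.min(dd)]
    }
    matched_truth <- c(matched_truth, cands)
    matched_cluster <- c(matched_cluster, cl)
  }
  TP <- length(matched_truth)
  FN <- nt - TP
  all_clusters <- sort(unique(spine_clusters[spine_clusters > 0L]))
  FP <- length(setdiff(all_clusters, matched_cluster))
  list(TP = TP, FN = FN, FP = FP,
       sensitivity_pct = if (TP + FN > 0) 100 * TP / (TP + FN) else NA,
       precision_pct = if (TP + FP > 0) 100 * TP / (TP + FP) else NA,
       matches = data.frame(truth = truth$label[matched_truth],
                            cluster = matched_cluster))
}
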