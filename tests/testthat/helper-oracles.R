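# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and separate from the package's implementation paths.

rand_volume <- function(dims, seed, lo = 0, hi = 100) {
  withr::with_seed(seed, array(runif(prod(dims), lo, hi), dims))
}

# BFS flood fill of the background from the volume border, 6-connectivity;
# returns the logical "outside" set (oracle for fill_holes)
flood_outside_oracle <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  queue <- list()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (z %in% c(1, d[1]) || y %in% c(1, d[2]) || x %in% c(1, d[3])) {
      if (!mask[z, y, x]) queue[[length(queue) + 1]] <- c(z, y, x)
    }
  }
  for (q in queue) outside[q[1], q[2], q[3]] <- TRUE
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (r in 1:6) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      if (!mask[q[1], q[2], q[3]] && !outside[q[1], q[2], q[3]]) {
        outside[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  outside
}

# connected-component labelling in plain R (oracle for cc-based ops)
label_components_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    nxt <- nxt + 1L
    stack <- list(arrayInd(i, d)[1, ])
    lab[i] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  lab
}

# mask with 26-connected components of exactly the given sizes, mutually
# separated: size-k component = k voxels in a row along x
components_mask <- function(sizes, gap = 2L) {
  ny <- length(sizes)
  nx <- max(sizes) + 2L
  m <- array(FALSE, c(3L, ny * (1L + gap), nx))
  for (i in seq_along(sizes))
    m[2L, (i - 1L) * (1L + gap) + 1L, seq_len(sizes[i]) + 1L] <- TRUE
  m
}

# recursive node-level Horton-Strahler oracle: leaves are 1; a node whose
# children attain maximum order m gets m + 1 iff >= 2 children attain m
strahler_node_oracle <- function(parent) {
  n <- length(parent)
  children <- vector("list", n)
  for (i in seq_len(n)) if (parent[i] > 0)
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  so <- rep(NA_integer_, n)
  rec <- function(v) {
    ch <- children[[v]]
    if (length(ch) == 0) { so[v] <<- 1L; return(1L) }
    os <- vapply(ch, rec, 1L)
    m <- max(os)
    so[v] <<- if (sum(os == m) >= 2L) m + 1L else m
    so[v]
  }
  root <- which(parent == -1L)
  rec(root)
  so
}

# random rooted tree on n nodes (node 1 = root), returned as a neuron_tree
random_tree <- function(n, seed) {
  stopifnot(n >= 2)
  withr::with_seed(seed, {
    parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
    nodes <- data.frame(id = 1:n,
                        z = runif(n, 0, 20), y = runif(n, 0, 20),
                        x = runif(n, 0, 20),
                        radius = runif(n, 0.2, 2),
                        intensity = runif(n, 1, 100), parent = parent)
    structure(list(nodes = nodes, voxel_size = c(1, 1, 1), root = 1L),
              class = "neuron_tree")
  })
}

# perfect binary tree of edge-depth d as a neuron_tree
perfect_binary_tree <- function(depth) {
  n <- 2^(depth + 1) - 1
  parent <- c(-1L, floor((2:n) / 2))
  nodes <- data.frame(id = 1:n, z = 0, y = seq_len(n), x = seq_len(n),
                      radius = 1, intensity = 1, parent = as.integer(parent))
  structure(list(nodes = nodes, voxel_size = c(1, 1, 1), root = 1L),
            class = "neuron_tree")
}

# exhaustive maximum-weight spanning tree value: weight of edge = min of
# endpoint intensities; enumerate all edge subsets of size V-1
max_spanning_weight_oracle <- function(n, edges, intensity) {
  w <- pmin(intensity[edges$from], intensity[edges$to])
  best <- -Inf
  for (pick in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    g <- igraph::graph_from_data_frame(edges[pick, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = 1:n))
    if (igraph::components(g)$no == 1L) best <- max(best, sum(w[pick]))
  }
  best
}

# small random connected graph with node intensities: a random spanning
# tree plus a few chords, so cycles exist but exhaustive spanning-tree
# enumeration stays cheap
random_intensity_graph <- function(n, seed) {
  withr::with_seed(seed, {
    tree_e <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                                1L))
    extra <- t(utils::combn(n, 2))
    extra <- extra[sample(nrow(extra), 3L), , drop = FALSE]
    e <- unique(rbind(tree_e, extra))
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
    intensity <- sample(seq(10, 200, by = 5), n)
    nodes <- data.frame(id = 1:n, z = seq_len(n), y = 0, x = 0,
                        intensity = intensity, radius = 1)
    list(graph = structure(list(
           nodes = nodes,
           edges = data.frame(from = e[, 1], to = e[, 2],
                              length = rep(1, nrow(e))),
           voxel_size = c(1, 1, 1)), class = "skeleton_graph"),
         intensity = intensity)
  })
}

# two parallel dendrites, each decorated with detached spine heads; truth
# parent recorded per spine (separation + assignment scenario)
two_dendrite_spines_spec <- function(seed = 0L) {
  mk_sp <- function(z, y, x, nrn)
    list(center = c(z, y, x), head_radius = 2, neuron = nrn)
  phantom_spec(
    shape = c(20, 44, 48),
    voxel_size = c(0.3, 0.15, 0.15),
    neurons = list(
      list(polylines = list(rbind(c(10, 12, 4), c(10, 12, 43))),
           radius = 3),
      list(polylines = list(rbind(c(10, 32, 4), c(10, 32, 43))),
           radius = 3)),
    spines = list(
      mk_sp(10, 5, 8, 1), mk_sp(10, 19, 14, 1), mk_sp(10, 5, 22, 1),
      mk_sp(10, 19, 30, 1), mk_sp(10, 5, 38, 1),
      mk_sp(10, 39, 10, 2), mk_sp(10, 25, 18, 2), mk_sp(10, 39, 26, 2),
      mk_sp(10, 25, 34, 2), mk_sp(10, 39, 40, 2)),
    seed = seed)
}
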