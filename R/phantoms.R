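# Seeded synthetic phantoms with exact ground truth: tube-like dendrites,
# ellipsoidal somata, spine heads with faint or absent necks, anisotropic
# Gaussian PSF blur and mixed Poisson-Gaussian noise. Every pipeline stage
# is testable against the pre-noise geometry.

#' Specify a synthetic phantom
#'
#' Geometry is given in 0-based voxel coordinates `(z, y, x)`; radii are in
#' voxels. Intensities emulate a fluorescence stack: bright dendritic
#' trunks, brighter somata, spine heads with necks dimmed by
#' `neck_factor` (or absent, the super-resolution regime where neck signal
#' drops below noise). The PSF default is axially elongated
#' (`sigma_z > sigma_xy`), mirroring confocal axial blur; noise is a
#' Poisson photon term plus Gaussian read noise. The seed fully determines
#' the rendered stack.
#'
#' @param shape integer `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param neurons list; each neuron is a list of polylines (n x 3 matrices
#'   of `(z, y, x)` vertices) with a `radius` attribute in voxels, plus an
#'   optional `radius` element used for all its polylines.
#' @param somata list of `list(center, axes, neuron)` ellipsoids
#'   (axes in voxels, semi-axis order `(z, y, x)`).
#' @param spines list of `list(center, head_radius, neck_to = NULL,
#'   neck_radius = NULL, neuron)`; `neck_to` is the attachment point on the
#'   dendrite, `NULL` leaves the head detached.
#' @param psf_sigma `(sz, sy, sx)` Gaussian PSF std-dev in voxels.
#' @param noise `list(photon_scale, read_sd)`.
#' @param background,intensity background level and structure intensities
#'   (`dendrite`, `soma`, `spine_head`, `neck_factor`).
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size = c(1, 1, 1),
                         neurons = list(), somata = list(),
                         spines = list(),
                         psf_sigma = c(1.2, 0.8, 0.8),
                         noise = list(photon_scale = 1, read_sd = 15),
                         background = 10,
                         intensity = list(dendrite = 180, soma = 220,
                                          spine_head = 160,
                                          neck_factor = 0.3),
                         seed = 0L) {
  stopifnot(length(shape) == 3L, all(shape >= 3))
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 neurons = neurons, somata = somata, spines = spines,
                 psf_sigma = as.numeric(psf_sigma), noise = noise,
                 background = background, intensity = intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# 0-based voxel coordinate grids of a volume
coord_grids <- function(shape) {
  v <- array(0, shape)
  list(z = slice.index(v, 1) - 1, y = slice.index(v, 2) - 1,
       x = slice.index(v, 3) - 1)
}

# voxels within `radius` of segment AB (voxel space)
rasterize_segment <- function(grids, A, B, radius) {
  AB <- B - A
  len2 <- sum(AB^2)
  pz <- grids$z - A[1]; py <- grids$y - A[2]; px <- grids$x - A[3]
  t <- if (len2 == 0) array(0, dim(grids$z))
       else (pz * AB[1] + py * AB[2] + px * AB[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dz <- pz - t * AB[1]; dy <- py - t * AB[2]; dx <- px - t * AB[3]
  array(dz^2 + dy^2 + dx^2 <= radius^2, dim(grids$z))
}

rasterize_polyline <- function(grids, pts, radius) {
  m <- array(FALSE, dim(grids$z))
  for (i in seq_len(nrow(pts) - 1))
    m <- m | rasterize_segment(grids, pts[i, ], pts[i + 1, ], radius)
  if (nrow(pts) == 1)
    m <- m | rasterize_segment(grids, pts[1, ], pts[1, ], radius)
  m
}

rasterize_ellipsoid <- function(grids, center, axes) {
  array(((grids$z - center[1]) / axes[1])^2 +
        ((grids$y - center[2]) / axes[2])^2 +
        ((grids$x - center[3]) / axes[3])^2 <= 1, dim(grids$z))
}

#' Render a phantom
#'
#' Rasterizes all structures at their stated intensities, records per-neuron
#' ground-truth masks from the pre-noise geometry, then applies the
#' anisotropic Gaussian PSF and Poisson + Gaussian noise. Overlaps between
#' different neurons are allowed and recorded in the contact map (needed by
#' the separation tests).
#'
#' @param spec a [phantom_spec()].
#' @return list: `stack` ([image_stack]), `truth` (list of per-neuron
#'   logical masks), `truth_union`, `somata` ([marker_set] of soma
#'   centres, label = neuron id), `spines` ([marker_set] of spine centres
#'   with `core` column = parent neuron id), `swc` (list of ground-truth
#'   `neuron_tree`s), `contact_map` (data frame of overlapping neuron
#'   pairs), `clean` (noise-free blurred stack).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  grids <- coord_grids(shape)
  img <- array(spec$background, shape)
  nn <- length(spec$neurons)
  truth <- lapply(seq_len(max(nn, 1)), function(i) array(FALSE, shape))
  paint <- function(img, m, value) {
    img[m] <- pmax(img[m], value)
    img
  }
  for (i in seq_len(nn)) {
    nrn <- spec$neurons[[i]]
    radius <- if (!is.null(nrn$radius)) nrn$radius else 2
    polys <- nrn$polylines
    for (pl in polys) {
      r <- attr(pl, "radius")
      if (is.null(r)) r <- radius
      m <- rasterize_polyline(grids, pl, r)
      truth[[i]] <- truth[[i]] | m
      img <- paint(img, m, spec$intensity$dendrite)
    }
  }
  soma_markers <- NULL
  for (s in spec$somata) {
    m <- rasterize_ellipsoid(grids, s$center, s$axes)
    truth[[s$neuron]] <- truth[[s$neuron]] | m
    img <- paint(img, m, spec$intensity$soma)
    soma_markers <- rbind(soma_markers,
                          data.frame(label = s$neuron, z = s$center[1],
                                     y = s$center[2], x = s$center[3]))
  }
  spine_markers <- NULL
  for (sp in spec$spines) {
    m <- rasterize_ellipsoid(grids, sp$center, rep(sp$head_radius, 3))
    truth[[sp$neuron]] <- truth[[sp$neuron]] | m
    img <- paint(img, m, spec$intensity$spine_head)
    if (!is.null(sp$neck_to)) {
      nr <- if (!is.null(sp$neck_radius)) sp$neck_radius else 1
      mn <- rasterize_segment(grids, sp$center, sp$neck_to, nr)
      truth[[sp$neuron]] <- truth[[sp$neuron]] | mn
      img <- paint(img, mn,
                   spec$intensity$spine_head * spec$intensity$neck_factor)
    }
    spine_markers <- rbind(spine_markers,
                           data.frame(label = length(spine_markers$label) + 1L,
                                      z = sp$center[1], y = sp$center[2],
                                      x = sp$center[3], core = sp$neuron))
  }
  # contact map between neurons
  contact <- NULL
  if (nn >= 2) for (i in 1:(nn - 1)) for (j in (i + 1):nn)
    if (any(truth[[i]] & truth[[j]]))
      contact <- rbind(contact, data.frame(a = i, b = j))
  # PSF + noise
  clean <- if (any(spec$psf_sigma > 0))
    array(gaussian_smooth_cpp(as.numeric(img), shape, spec$psf_sigma),
          shape)
  else img
  noisy <- withr::with_seed(spec$seed, {
    ps <- spec$noise$photon_scale
    photon <- if (!is.null(ps) && ps > 0)
      rpois(length(clean), pmax(clean, 0) * ps) / ps
    else as.numeric(clean)
    photon + rnorm(length(clean), 0, spec$noise$read_sd)
  })
  noisy <- pmin(pmax(round(noisy), 0), 65535)
  stack <- image_stack(array(noisy, shape), spec$voxel_size, c(0, 65535))
  swc <- lapply(seq_len(nn), function(i)
    ground_truth_tree(spec$neurons[[i]], spec$voxel_size))
  som <- if (is.null(soma_markers))
    marker_set(data.frame(label = integer(0), z = integer(0),
                          y = integer(0), x = integer(0)), "soma")
  else marker_set(soma_markers, "soma")
  spn <- if (is.null(spine_markers)) NULL else {
    ms <- marker_set(spine_markers[, c("label", "z", "y", "x")],
                     "spine_center")
    ms$core <- spine_markers$core
    ms
  }
  list(stack = stack, truth = truth[seq_len(nn)],
       truth_union = Reduce(`|`, truth[seq_len(max(nn, 1))]),
       somata = som, spines = spn, swc = swc, contact_map = contact,
       clean = clean)
}

# ground-truth tree from a neuron's polylines: nodes at vertices, later
# polylines attach to the nearest already-placed node of the same neuron
ground_truth_tree <- function(nrn, voxel_size) {
  radius <- if (!is.null(nrn$radius)) nrn$radius else 2
  nodes <- NULL
  next_id <- 1L
  for (pl in nrn$polylines) {
    r <- attr(pl, "radius"); if (is.null(r)) r <- radius
    prev <- NA_integer_
    if (!is.null(nodes) && nrow(nodes) > 0) {
      d2 <- (nodes$z - pl[1, 1])^2 + (nodes$y - pl[1, 2])^2 +
            (nodes$x - pl[1, 3])^2
      prev <- nodes$id[which.min(d2)]
    }
    for (i in seq_len(nrow(pl))) {
      parent <- if (i == 1 && is.na(prev)) -1L
                else if (i == 1) prev
                else next_id - 1L
      nodes <- rbind(nodes, data.frame(
        id = next_id, z = pl[i, 1], y = pl[i, 2], x = pl[i, 3],
        radius = r * mean(voxel_size[2:3]), intensity = NA_real_,
        parent = parent))
      next_id <- next_id + 1L
    }
  }
  structure(list(nodes = nodes, voxel_size = as.numeric(voxel_size),
                 root = nodes$id[nodes$parent == -1L][1]),
            class = "neuron_tree")
}

#' The standard phantom battery
#'
#' A fixed collection of named phantoms covering every stage:
#' `sphere` (one bright blob), `tube` (straight dendrite along x),
#' `ytree` (one bifurcation), `pair` (two touching neurons with somata,
#' the separation scenario), `spines` (a dendrite plus detached spine
#' heads without necks, the assignment scenario), `loop` (a closed cycle
#' with an intensity dip, the cycle-breaking scenario) and `two_scale`
#' (thick trunk plus thin processes, the multi-scale scenario).
#'
#' @param seed integer; offsets every member's noise seed.
#' @return named list of [phantom_spec()]s.
#' @export
standard_suite <- function(seed = 0L) {
  seed <- as.integer(seed)
  suite <- list()
  suite$sphere <- phantom_spec(
    shape = c(24, 32, 32),
    neurons = list(list(polylines = list(), radius = 2)),
    somata = list(list(center = c(12, 16, 16), axes = c(6, 7, 7),
                       neuron = 1)),
    seed = seed)
  suite$tube <- phantom_spec(
    shape = c(16, 24, 48),
    neurons = list(list(polylines = list(
      rbind(c(8, 12, 4), c(8, 12, 43))), radius = 3)),
    seed = seed + 1L)
  suite$ytree <- phantom_spec(
    shape = c(20, 40, 40),
    neurons = list(list(polylines = list(
      rbind(c(10, 34, 20), c(10, 20, 20)),
      rbind(c(10, 20, 20), c(10, 6, 8)),
      rbind(c(10, 20, 20), c(10, 6, 32))), radius = 2)),
    seed = seed + 2L)
  suite$pair <- phantom_spec(
    shape = c(24, 40, 56),
    neurons = list(
      list(polylines = list(rbind(c(12, 14, 6), c(12, 14, 50))),
           radius = 2),
      list(polylines = list(rbind(c(12, 26, 6), c(12, 20, 28),
                                  c(12, 26, 50))), radius = 2)),
    somata = list(list(center = c(12, 12, 10), axes = c(4, 5, 5),
                       neuron = 1),
                  list(center = c(12, 30, 44), axes = c(4, 5, 5),
                       neuron = 2)),
    seed = seed + 3L)
  suite$spines <- phantom_spec(
    shape = c(20, 36, 48),
    voxel_size = c(0.3, 0.15, 0.15),
    neurons = list(list(polylines = list(
      rbind(c(10, 18, 4), c(10, 18, 43))), radius = 3)),
    spines = list(
      list(center = c(10, 10, 8), head_radius = 2, neuron = 1),
      list(center = c(10, 26, 12), head_radius = 2, neuron = 1),
      list(center = c(10, 10, 18), head_radius = 2, neuron = 1),
      list(center = c(10, 26, 24), head_radius = 2, neuron = 1),
      list(center = c(10, 10, 30), head_radius = 2, neuron = 1),
      list(center = c(10, 26, 36), head_radius = 2, neuron = 1)),
    seed = seed + 4L)
  suite$loop <- phantom_spec(
    shape = c(16, 36, 36),
    neurons = list(list(polylines = list(
      rbind(c(8, 8, 8), c(8, 8, 28), c(8, 28, 28), c(8, 28, 8),
            c(8, 8, 8))), radius = 2)),
    seed = seed + 5L)
  suite$two_scale <- phantom_spec(
    shape = c(20, 36, 48),
    neurons = list(list(polylines = list(
      structure(rbind(c(10, 18, 4), c(10, 18, 43)), radius = 5),
      structure(rbind(c(10, 18, 14), c(10, 6, 14)), radius = 1),
      structure(rbind(c(10, 18, 32), c(10, 30, 32)), radius = 1)))),
    seed = seed + 6L)
  suite
}

#' Seeded two-neuron phantom for separation studies
#'
#' Two tube-like neurons with somata at opposite corners, geometry jittered
#' deterministically by the seed so repeated draws give a family of related
#' but distinct scenarios. The neurons approach each other mid-volume, so
#' after PSF blur their segmentations touch and only the watershed
#' parcellation separates them.
#'
#' @param seed integer; determines both the geometry jitter and the noise.
#' @return a [phantom_spec()].
#' @export
phantom_neuron_pair <- function(seed = 0L) {
  seed <- as.integer(seed)
  jit <- withr::with_seed(seed + 1000L, round(runif(8, -2, 2)))
  phantom_spec(
    shape = c(24, 40, 56),
    neurons = list(
      list(polylines = list(rbind(
        c(12 + jit[1], 13 + jit[2], 5),
        c(12 + jit[3], 16 + jit[4], 28),
        c(12 + jit[1], 13 + jit[2], 51))), radius = 2),
      list(polylines = list(rbind(
        c(12 + jit[5], 27 + jit[6], 5),
        c(12 + jit[7], 23 + jit[8], 28),
        c(12 + jit[5], 27 + jit[6], 51))), radius = 2)),
    somata = list(
      list(center = c(12 + jit[1], 10 + jit[2], 9), axes = c(4, 5, 5),
           neuron = 1),
      list(center = c(12 + jit[5], 30 + jit[6], 47), axes = c(4, 5, 5),
           neuron = 2)),
    seed = seed)
}

#' Measured signal-to-noise ratio of a rendered phantom
#'
#' `(mean foreground - mean background) / sd(background residual)`,
#' measured on the rendered stack with the ground-truth mask.
#'
#' @param phantom result of [render_phantom()].
#' @return scalar SNR.
#' @export
phantom_snr <- function(phantom) {
  img <- phantom$stack$data
  fg <- phantom$truth_union
  bg <- !fg
  (mean(img[fg]) - mean(img[bg])) / sd(img[bg])
}
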