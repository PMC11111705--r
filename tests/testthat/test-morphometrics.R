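# Strahler ordering and statistics, Sholl, Dice, area/volume, spine metrics

test_that("strahler order matches the recursive oracle on canonical trees", {
  # path graph: everything order 1
  path <- structure(list(nodes = data.frame(
    id = 1:5, z = 0, y = 0, x = 0:4, radius = 1, intensity = 1,
    parent = c(-1L, 1:4)), voxel_size = c(1, 1, 1), root = 1L),
    class = "neuron_tree")
  dec <- strahler_order(path)
  expect_equal(dec$SN, 1L)
  expect_true(all(dec$node_SO == 1L))
  expect_equal(nrow(dec$segments), 1L)
  # one bifurcation: leaves 1, stem 2
  y <- path
  y$nodes <- data.frame(id = 1:5, z = 0, y = c(0, 0, 1, 2, 2),
                        x = c(0, 1, 1, 0, 2), radius = 1, intensity = 1,
                        parent = c(-1L, 1L, 2L, 3L, 3L))
  decy <- strahler_order(y)
  expect_equal(decy$SN, 2L)
  expect_equal(sort(decy$segments$SO), c(1L, 1L, 2L))
  # perfect binary trees: SN = depth + 1
  for (d in 1:5) {
    tr <- perfect_binary_tree(d)
    expect_equal(strahler_order(tr)$SN, d + 1L)
  }
})

test_that("strahler order equals the node-level recursion on random trees", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(5:200, 1))
    tr <- random_tree(n, seed)
    dec <- strahler_order(tr)
    oracle <- strahler_node_oracle(tr$nodes$parent)
    expect_equal(max(dec$node_SO), max(oracle))
    # non-junction nodes agree exactly with the recursion; junction nodes
    # take the parent-side (higher) order by convention
    children <- table(factor(tr$nodes$parent, levels = 1:n))
    leaf_or_chain <- which(children <= 1)
    expect_equal(dec$node_SO[leaf_or_chain], oracle[leaf_or_chain])
  }
})

test_that("strahler invariances: child permutation and leaf addition", {
  tr <- random_tree(60, 99)
  base <- strahler_order(tr)$SN
  # permuting node ids of siblings must not change SN: relabel by a random
  # permutation (keeping the root) and re-derive parents
  withr::with_seed(100, {
    perm <- c(1L, 1L + sample(59))
  })
  inv <- integer(60); inv[perm] <- 1:60
  nodes2 <- tr$nodes
  nodes2$id <- perm[nodes2$id]
  nodes2$parent <- ifelse(tr$nodes$parent == -1L, -1L,
                          perm[pmax(tr$nodes$parent, 1L)])
  nodes2 <- nodes2[order(nodes2$id), ]
  tr2 <- structure(list(nodes = nodes2, voxel_size = c(1, 1, 1),
                        root = which(nodes2$parent == -1L)),
                   class = "neuron_tree")
  expect_equal(strahler_order(tr2)$SN, base)
  # adding a leaf never decreases SN
  nodes3 <- rbind(tr$nodes,
                  data.frame(id = 61L, z = 1, y = 1, x = 1, radius = 1,
                             intensity = 1, parent = 30L))
  tr3 <- structure(list(nodes = nodes3, voxel_size = c(1, 1, 1),
                        root = 1L), class = "neuron_tree")
  expect_gte(strahler_order(tr3)$SN, base)
  # SN bound by log2 of leaf count
  nl <- sum(!(tr$nodes$id %in% tr$nodes$parent))
  expect_lte(base, floor(log2(nl)) + 1)
})

test_that("strahler table matches hand enumeration on a 7-segment tree", {
  # two nested bifurcations on one side, one on the other:
  #        root - A - junction J1
  #        J1 branches to B (terminal) and C - J2
  #        J2 branches to D and E (both terminal)
  # segments: A(2 edges), B(2), C(2), D(1), E(1) -> 5 segments
  # plus a second tree level: make B itself bifurcate into F, G
  nodes <- data.frame(
    id = 1:13,
    z = 0, y = c(0, 0, 0, 1, 2, 1, 2, 3, 3, 2, 3, 4, 4),
    x = c(0, 1, 2, 3, 3, 4, 5, 5, 6, 6, 7, 6, 8),
    radius = c(3, 3, 2, 2, 1, 2, 2, 1, 1, 1, 1, 1, 1),
    intensity = 1,
    parent = c(-1L, 1L, 2L, 3L, 4L, 4L, 6L, 7L, 7L, 6L, 10L, 11L, 11L))
  tr <- structure(list(nodes = nodes, voxel_size = c(1, 1, 1), root = 1L),
                  class = "neuron_tree")
  dec <- strahler_order(tr)
  # hand enumeration of the segment decomposition:
  #   1-2-3-4 (stem), 4-5, 4-6, 6-7, 7-8, 7-9, 6-10-11, 11-12, 11-13
  # orders: the four terminal segments at 7 and 11 and 4-5 are SO 1;
  # 6-7 and 6-10-11 merge pairs of SO 1 -> SO 2; 4-6 merges two SO 2 ->
  # SO 3; the stem inherits max(1, 3) = 3
  expect_equal(nrow(dec$segments), 9L)
  expect_equal(sort(dec$segments$SO),
               c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  st <- strahler_stats(dec)
  expect_equal(st$SN, 3L)
  expect_equal(st$numSegSO, c(5L, 2L, 2L))
  expect_equal(sum(st$numSegSOnorm), 1, tolerance = 1e-9)
  expect_equal(sum(st$numBrSOnorm), 1, tolerance = 1e-9)
  lens <- with(nodes[-1, ], sqrt((y - nodes$y[parent])^2 +
                                 (x - nodes$x[parent])^2))
  expect_equal(st$TOTL, sum(lens), tolerance = 1e-9)
  # bifurcation ratio: branches per order 2/1 and 2/1
  expect_equal(length(st$bifurcation_ratio), 2L)
  expect_true(all(is.finite(st$bifurcation_ratio)))
  # fits defined for SN >= 2
  expect_true(st$fit_defined)
  expect_equal(unname(st$PSnum["slope"]),
               unname(coef(lm(log10(st$numSegSOnorm) ~ c(1:3)))[2]),
               tolerance = 1e-9)
})

test_that("single-order tree reports undefined fits and full path length", {
  path <- structure(list(
    nodes = data.frame(id = 1:4, z = 0, y = 0, x = c(0, 3, 6, 10),
                       radius = 1, intensity = 1,
                       parent = c(-1L, 1L, 2L, 3L)),
    voxel_size = c(1, 1, 1), root = 1L), class = "neuron_tree")
  st <- strahler_stats(strahler_order(path))
  expect_equal(st$SN, 1L)
  expect_equal(st$numSegSO, 1L)
  expect_equal(st$TOTL, 10)
  expect_false(st$fit_defined)
  expect_true(all(is.na(st$PSnum)))
})

test_that("sholl profile and AUC match hand-computed geometry", {
  # straight 10 um path: crossings 1,...,1,0 -> trapezoidal AUC 8.5
  path <- structure(list(
    nodes = data.frame(id = 1:11, z = 0, y = 0, x = 0:10, radius = 1,
                       intensity = 1, parent = c(-1L, 1:10)),
    voxel_size = c(1, 1, 1), root = 1L), class = "neuron_tree")
  pr <- sholl(path, 1:10)
  expect_equal(pr$crossings, c(rep(1L, 9), 0L))
  expect_equal(pr$AUC, 8.5)
  # Y-tree bifurcating at 5 um, daughters to 10 um: 1 before, 2 after
  ytr <- structure(list(
    nodes = data.frame(id = 1:13,
                       z = 0,
                       y = c(rep(0, 6), 1:4, -(1:3)) * 0.0 +
                         c(rep(0, 6), rep(0, 7)),
                       x = c(0:5, 6:9, 6:8),
                       radius = 1, intensity = 1,
                       parent = c(-1L, 1:5, 6L, 7:9, 6L, 11:12)),
    voxel_size = c(1, 1, 1), root = 1L), class = "neuron_tree")
  # distances: branch point at 5, daughters extend along x to 9 and 8
  pry <- sholl(ytr, c(2, 4, 6, 8))
  expect_equal(pry$crossings[1:2], c(1L, 1L))
  expect_equal(pry$crossings[3], 2L)
  # radii beyond the arbor give trailing zeros
  prz <- sholl(path, c(5, 20, 30))
  expect_equal(prz$crossings, c(1L, 0L, 0L))
  expect_error(sholl(path, c(3, 2)), "increasing")
})

test_that("sholl AUC is additive over disjoint root-attached subtrees", {
  a <- structure(list(
    nodes = data.frame(id = 1:6, z = 0, y = 0, x = c(0, 2, 4, 6, 8, 10),
                       radius = 1, intensity = 1,
                       parent = c(-1L, 1:5)),
    voxel_size = c(1, 1, 1), root = 1L), class = "neuron_tree")
  b <- a
  b$nodes$x <- -b$nodes$x    # mirror arm on the other side
  both <- a
  both$nodes <- rbind(a$nodes,
                      transform(b$nodes[-1, ], id = id + 5L,
                                parent = ifelse(parent == 1L, 1L,
                                                parent + 5L)))
  radii <- seq(0.5, 12, by = 0.5)
  expect_equal(sholl(both, radii)$AUC,
               sholl(a, radii)$AUC + sholl(b, radii)$AUC)
})

test_that("dice satisfies its axioms and the half-overlap case", {
  a <- array(FALSE, c(6, 6, 6)); a[1:4, 1:4, 1:4] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[1:4, 1:4, 3:6] <- TRUE
  expect_equal(dice(a, b), 0.5)     # 2*32 / (64 + 64)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), dice(b, a))
  empty <- array(FALSE, c(6, 6, 6))
  expect_equal(dice(a, empty), 0)
  expect_warning(expect_equal(dice(empty, empty), 1), "empty")
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "shapes differ")
})

test_that("area and volume follow closed forms on cubes and anisotropic voxels", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  av <- area_volume(one, c(1, 1, 1))
  expect_equal(av$volume, 1)
  expect_equal(av$area, 6)
  for (N in c(2, 4, 6)) {
    cube <- array(FALSE, c(N + 2, N + 2, N + 2))
    cube[2:(N + 1), 2:(N + 1), 2:(N + 1)] <- TRUE
    avc <- area_volume(cube, c(1, 1, 1))
    expect_equal(avc$volume, N^3)
    expect_equal(avc$area, 6 * N^2)
  }
  # surface-to-volume ratio decreases with edge length
  ratios <- vapply(c(2, 4, 6), function(N) {
    cube <- array(FALSE, c(N + 2, N + 2, N + 2))
    cube[2:(N + 1), 2:(N + 1), 2:(N + 1)] <- TRUE
    area_volume(cube, c(1, 1, 1))$ratio
  }, 0)
  expect_true(all(diff(ratios) < 0))
  # anisotropic single voxel: 2 z-faces of dy*dx + 4 side faces
  av2 <- area_volume(one, c(0.5, 0.1, 0.1))
  expect_equal(av2$volume, 0.005)
  expect_equal(av2$area, 2 * 0.01 + 4 * 0.05)
  expect_error(area_volume(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("spine metrics implement the matching and the S/P formulas", {
  d <- c(4, 10, 40)
  clusters <- array(0L, d)
  # 10 clusters of 2x2 voxels along x
  for (k in 1:10) clusters[2, 2:3, (4 * k - 2):(4 * k - 1)] <- k
  cores <- data.frame(cluster = 1:10,
                      core = c(rep(1L, 8), 2L, 2L))
  truth <- marker_set(data.frame(label = 1:10, z = 1,
                                 y = 1, x = seq(2, 38, by = 4)))
  truth$core <- rep(1L, 10)
  # clusters 9, 10 carry the wrong core -> their truth centres are FN and
  # the clusters themselves FP: TP 8, FN 2, FP 2
  sm <- spine_metrics(clusters, cores, truth)
  expect_equal(sm$TP, 8L)
  expect_equal(sm$FN, 2L)
  expect_equal(sm$FP, 2L)
  expect_equal(sm$sensitivity_pct, 80)
  expect_equal(sm$precision_pct, 80)
  # perfect detection and assignment
  cores2 <- data.frame(cluster = 1:10, core = rep(1L, 10))
  sm2 <- spine_metrics(clusters, cores2, truth)
  expect_equal(c(sm2$sensitivity_pct, sm2$precision_pct), c(100, 100))
  # one cluster can match only one truth centre
  truth3 <- truth[1:2, ]; truth3$x <- c(2, 3); truth3$core <- c(1L, 1L)
  sm3 <- spine_metrics(clusters, cores2, truth3)
  expect_equal(sm3$TP, 1L)
  expect_equal(sm3$FN, 1L)
})
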