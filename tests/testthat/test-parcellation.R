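# Core definition, minima imposition, watershed, cluster assignment

test_that("automatic cores split components by size threshold", {
  ph <- render_phantom(two_dendrite_spines_spec(1))
  m <- ph$truth_union
  cs <- define_cores_auto(m, 500)
  expect_equal(cs$n_cores, 2L)
  expect_equal(nrow(cs$spine_clusters), 10L)
  expect_true(all(cs$spine_clusters$size < 500))
  # threshold 1: everything is a core
  cs1 <- define_cores_auto(m, 1)
  expect_equal(cs1$n_cores, 12L)
  expect_equal(nrow(cs1$spine_clusters), 0L)
  # threshold above the largest component
  expect_error(define_cores_auto(m, sum(m) + 1), "no core")
})

test_that("manual cores validate markers and report overlap", {
  m <- array(TRUE, c(10, 10, 10))
  mk <- marker_set(data.frame(label = c(1, 2), z = c(2, 7), y = c(5, 5),
                              x = c(5, 5)))
  cs <- define_cores_manual(m, mk, radius = 2)
  expect_equal(cs$n_cores, 2L)
  expect_equal(sort(unique(cs$cores[cs$cores > 0])), c(1L, 2L))
  # marker outside mask but inside volume warns
  m2 <- array(FALSE, c(10, 10, 10)); m2[1:3, , ] <- TRUE
  mk2 <- marker_set(data.frame(label = 1, z = 8, y = 5, x = 5))
  expect_warning(define_cores_manual(m2, mk2, radius = 1), "outside")
  # overlapping seed balls are an error
  mk3 <- marker_set(data.frame(label = c(1, 2), z = c(5, 5), y = c(5, 6),
                               x = c(5, 5)))
  expect_error(define_cores_manual(m, mk3, radius = 2), "overlap")
})

test_that("minima imposition leaves regional minima exactly at the cores", {
  withr::with_seed(31, v <- array(sample(0:200, 14 * 14 * 14, TRUE),
                                  c(14, 14, 14)))
  cores <- array(0L, dim(v))
  cores[3:4, 3:4, 3:4] <- 1L
  cores[10:11, 10:11, 10:11] <- 2L
  imp <- impose_minima(v, cores)
  # exhaustive regional-minimum scan: label equal-valued plateaus
  # (26-connectivity), then a plateau is a regional minimum iff no member
  # voxel has a strictly lower neighbour
  d <- dim(v)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  plat <- array(0L, d)
  nxt <- 0L
  for (i in seq_len(prod(d))) {
    if (plat[i] > 0L) next
    nxt <- nxt + 1L
    val <- imp[i]
    stack <- list(arrayInd(i, d)[1, ])
    plat[i] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (imp[q[1], q[2], q[3]] == val && plat[q[1], q[2], q[3]] == 0L) {
          plat[q[1], q[2], q[3]] <- nxt
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  # minimum neighbour value around every voxel
  lower_exists <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    zi <- pmin(pmax(slice.index(v, 1) + offs[r, 1], 1), d[1])
    yi <- pmin(pmax(slice.index(v, 2) + offs[r, 2], 1), d[2])
    xi <- pmin(pmax(slice.index(v, 3) + offs[r, 3], 1), d[3])
    nb <- array(imp[cbind(as.vector(zi), as.vector(yi), as.vector(xi))], d)
    inside <- slice.index(v, 1) + offs[r, 1] >= 1 &
      slice.index(v, 1) + offs[r, 1] <= d[1] &
      slice.index(v, 2) + offs[r, 2] >= 1 &
      slice.index(v, 2) + offs[r, 2] <= d[2] &
      slice.index(v, 3) + offs[r, 3] >= 1 &
      slice.index(v, 3) + offs[r, 3] <= d[3]
    lower_exists <- lower_exists | (inside & nb < imp)
  }
  is_regional_min <- vapply(seq_len(nxt), function(k)
    !any(lower_exists[plat == k]), TRUE)
  min_plateaus <- which(is_regional_min)
  # every regional minimum contains a core, and every core sits in a
  # regional minimum
  for (k in min_plateaus)
    expect_true(any(cores[plat == k] > 0))
  expect_true(all(plat[cores > 0] %in% min_plateaus))
})

test_that("watershed splits two gaussian blobs at the intensity minimum", {
  shape <- c(12, 20, 40)
  g <- list(z = slice.index(array(0, shape), 1) - 1,
            y = slice.index(array(0, shape), 2) - 1,
            x = slice.index(array(0, shape), 3) - 1)
  img <- 200 * exp(-((g$z - 6)^2 + (g$y - 10)^2 + (g$x - 12)^2) / 50) +
         200 * exp(-((g$z - 6)^2 + (g$y - 10)^2 + (g$x - 27)^2) / 50) + 10
  st <- image_stack(array(round(img), shape))
  mask <- st$data > 40
  mk <- marker_set(data.frame(label = 1:2, z = 6, y = 10, x = c(12, 27)))
  parc <- parcellate(st, mask, define_cores_manual(mask, mk, 2))
  # 1-D argmin of the summed intensity profile between the cores
  prof <- vapply(13:27, function(x) sum(st$data[, , x + 1]), 0)
  xmin <- (13:27)[which.min(prof)]
  b1 <- max(g$x[parc$labels == 1])
  b2 <- min(g$x[parc$labels == 2])
  expect_lte(abs(b1 - xmin), 1)
  expect_equal(b2, b1 + 1)
  # partition invariants
  expect_true(all(parc$basins > 0))
  expect_equal(sort(unique(as.vector(parc$basins))), c(1L, 2L))
  expect_true(all((parc$labels > 0) == mask))
})

test_that("single core gives every mask voxel that label", {
  ph <- render_phantom(standard_suite(6)$sphere)
  m <- ph$truth_union
  parc <- parcellate(ph$stack, m, define_cores_manual(m, ph$somata, 2))
  expect_equal(unique(parc$labels[m]), 1L)
  expect_equal(unique(as.vector(parc$basins)), 1L)
})

test_that("watershed agrees with brute-force steepest descent on separable blobs", {
  shape <- c(8, 16, 30)
  g <- list(z = slice.index(array(0, shape), 1) - 1,
            y = slice.index(array(0, shape), 2) - 1,
            x = slice.index(array(0, shape), 3) - 1)
  img <- 220 * exp(-((g$z - 4)^2 + (g$y - 8)^2 + (g$x - 8)^2) / 40) +
         180 * exp(-((g$z - 4)^2 + (g$y - 8)^2 + (g$x - 21)^2) / 40) + 10
  st <- image_stack(array(round(img), shape))
  mask <- st$data > 30
  mk <- marker_set(data.frame(label = 1:2, z = 4, y = 8, x = c(8, 21)))
  parc <- parcellate(st, mask, define_cores_manual(mask, mk, 2))
  # oracle: steepest ascent on raw intensity towards one of the two peaks
  peak_of <- function(z, y, x) {
    repeat {
      best <- c(z, y, x); bi <- st$data[z + 1, y + 1, x + 1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        q <- c(z + dz, y + dy, x + dx)
        if (any(q < 0) || any(q >= shape)) next
        vi <- st$data[q[1] + 1, q[2] + 1, q[3] + 1]
        if (vi > bi) { bi <- vi; best <- q }
      }
      if (all(best == c(z, y, x))) return(if (x <= 14) 1L else 2L)
      z <- best[1]; y <- best[2]; x <- best[3]
    }
  }
  idx <- which(mask)
  zyx <- arrayInd(idx, shape) - 1
  oracle <- vapply(seq_along(idx), function(i)
    peak_of(zyx[i, 1], zyx[i, 2], zyx[i, 3]), 1L)
  agree <- mean(parc$labels[idx] == oracle)
  expect_gte(agree, 0.99)
})

test_that("cluster assignment follows majority with centroid tie-break", {
  # synthetic basins: half/half split along x
  d <- c(5, 10, 10)
  basins <- array(1L, d); basins[, , 6:10] <- 2L
  cores <- array(0L, d); cores[3, 5, 1] <- 1L; cores[3, 5, 10] <- 2L
  # cluster wholly inside basin 2
  cl <- array(0L, d); cl[2, 2, 7:9] <- 1L
  a <- assign_clusters(cl, basins, cores)
  expect_equal(a$core, 2L)
  expect_equal(a$rule, "majority")
  # 60/40 split favours the majority basin
  cl2 <- array(0L, d); cl2[2, 2, 3:7] <- 1L   # 3 voxels basin1, 2 basin2
  a2 <- assign_clusters(cl2, basins, cores)
  expect_equal(a2$core, 1L)
  # exact 50/50: centroid decides, tie flagged
  cl3 <- array(0L, d); cl3[2, 2, 4:7] <- 1L   # 2 and 2
  a3 <- assign_clusters(cl3, basins, cores)
  expect_true(a3$tie)
  expect_equal(a3$rule, "centroid_tie")
})

test_that("detached spines all reach the sole dendrite core", {
  ph <- render_phantom(standard_suite(7)$spines)
  seg <- suppressWarnings(segment(ph$stack,
    pipeline_config(sigmas = c(1, 2), K = "auto", random_seed = 7)))
  cs <- define_cores_auto(seg$mask, 500)
  expect_equal(cs$n_cores, 1L)
  parc <- parcellate(ph$stack, seg$mask, cs)
  spines <- parc$assignments[parc$assignments$rule != "own_core", ]
  expect_gt(nrow(spines), 0)
  expect_true(all(spines$core == 1L))
})

test_that("parcellation correction re-labels a stray branch and is identity without markers", {
  # two parallel tubes, only one soma marked: both get label 1; adding a
  # marker on the second tube re-assigns it
  sp <- phantom_spec(
    shape = c(16, 30, 40),
    neurons = list(
      list(polylines = list(rbind(c(8, 10, 4), c(8, 10, 35))), radius = 2),
      list(polylines = list(rbind(c(8, 20, 4), c(8, 20, 35))), radius = 2)),
    somata = list(list(center = c(8, 10, 6), axes = c(3, 4, 4),
                       neuron = 1)),
    seed = 41)
  ph <- render_phantom(sp)
  m <- ph$truth_union
  mk1 <- marker_set(data.frame(label = 1, z = 8, y = 10, x = 6))
  parc1 <- parcellate(ph$stack, m, define_cores_manual(m, mk1, 2))
  expect_identical(correct_parcellation(parc1, ph$stack, m, NULL), parc1)
  branch2 <- ph$truth[[2]] & m
  expect_equal(unique(parc1$labels[branch2]), 1L)
  mk_extra <- marker_set(data.frame(label = 2, z = 8, y = 20, x = 20))
  parc2 <- correct_parcellation(parc1, ph$stack, m, mk_extra)
  expect_equal(parc2$cores$n_cores, parc1$cores$n_cores + 1L)
  lab2 <- parc2$labels[branch2]
  expect_equal(as.integer(names(which.max(table(lab2)))), 2L)
  # voxels of tube 1 keep their old label
  tube1 <- ph$truth[[1]] & m
  expect_equal(unique(parc2$labels[tube1 & parc2$labels > 0]), 1L)
})
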