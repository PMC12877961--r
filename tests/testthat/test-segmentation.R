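# Thresholding, connected components, volume filtering, seeded selection
# and eraser edits.

test_that("thresholding follows polarity and nests monotonically", {
  vals <- c(100, 219, 220, 250)
  vol <- volume3d(array(vals, c(1, 1, 4)), c(1, 1, 1))
  m <- threshold_volume(vol, 220)
  expect_equal(as.vector(m$grid), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(threshold_volume(vol, 0)$grid))
  md <- threshold_volume(vol, 220, polarity = "dark")
  expect_equal(as.vector(md$grid), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(threshold_volume(vol, 300), "dynamic range")

  # nestedness across the standard sweep on random volumes
  set.seed(42)
  for (rep in 1:5) {
    g <- array(sample(0:255, 6^3, replace = TRUE), c(6, 6, 6))
    v <- volume3d(g, c(1, 1, 1))
    m160 <- threshold_volume(v, 160)$grid
    m220 <- threshold_volume(v, 220)$grid
    m250 <- threshold_volume(v, 250)$grid
    expect_true(all(m250 <= m220))
    expect_true(all(m220 <= m160))
  }
})

test_that("connectivity semantics: diagonal pairs join at 26 but not 6", {
  g <- array(FALSE, c(3, 3, 3))
  g[1, 1, 1] <- TRUE
  g[2, 2, 2] <- TRUE
  m <- voxel_mask(g, c(1, 1, 1))
  expect_equal(nrow(label_components(m, 26)$components), 1L)
  expect_equal(nrow(label_components(m, 6)$components), 2L)

  g2 <- array(FALSE, c(1, 3, 3))
  g2[1, 1, 1] <- TRUE
  g2[1, 3, 3] <- TRUE
  m2 <- voxel_mask(g2, c(1, 1, 1))
  lab <- label_components(m2)
  expect_equal(lab$components$voxel_count, c(1L, 1L))
})

test_that("labeling agrees with breadth-first flood fill on random masks", {
  set.seed(99)
  for (rep in 1:12) {
    dims <- sample(3:12, 3, replace = TRUE)
    dens <- runif(1, 0.2, 0.7)
    g <- array(runif(prod(dims)) < dens, dims)
    conn <- sample(c(6L, 18L, 26L), 1)
    m <- voxel_mask(g, runif(3, 0.5, 3))
    lab <- label_components(m, conn)
    oracle <- flood_fill_labels(g, conn)
    expect_identical(canon_labels(lab$label_grid), canon_labels(oracle))
    # components table is consistent with the grid
    expect_equal(sort(unique(as.vector(lab$label_grid[lab$label_grid > 0]))),
                 lab$components$label)
    expect_equal(sum(lab$components$voxel_count), sum(g))
    expect_equal(lab$components$physical_volume_um3,
                 lab$components$voxel_count * prod(m$spacing))
  }
})

test_that("volume filter removes components below the physical threshold", {
  # fMOST-like spacing: 2.5 um^3 per voxel; 300 voxels = 750 um^3 removed,
  # 500 voxels = 1250 um^3 kept under the 1000 um^3 rule
  sp <- c(2.5, 1, 1)
  g <- array(FALSE, c(4, 40, 40))
  g[1, 1:10, 1:30] <- TRUE            # 300 voxels
  g[3:4, 15:39, 31:40] <- TRUE        # 500 voxels
  m <- voxel_mask(g, sp)
  lab <- label_components(m)
  expect_equal(sort(lab$components$physical_volume_um3), c(750, 1250))
  kept <- filter_small_components(lab, 1000)
  expect_equal(sum(kept$grid), 500L)
  # min_volume 0 is the identity
  expect_identical(filter_small_components(lab, 0)$grid, g)

  # micro-CT spacing: 0.65^3 um^3 per voxel -> >= 3642 voxels for 1000 um^3
  expect_equal(ceiling(1000 / 0.65^3), 3642)
  spc <- c(0.65, 0.65, 0.65)
  g2 <- array(FALSE, c(20, 30, 30))
  g2[1:5, 1:27, 1:27] <- TRUE  # 3645 voxels, just over
  g2[10, 1, 1] <- TRUE         # isolated voxel
  lab2 <- label_components(voxel_mask(g2, spc))
  kept2 <- filter_small_components(lab2, 1000)
  expect_equal(sum(kept2$grid), 3645L)

  # survivors all satisfy the bound; survivor count non-increasing in V
  set.seed(12)
  g3 <- array(runif(10^3) < 0.4, c(10, 10, 10))
  lab3 <- label_components(voxel_mask(g3, c(1, 1, 1)))
  prev <- Inf
  for (V in c(0, 2, 5, 10, 50)) {
    surv <- filter_small_components(lab3, V)
    relab <- label_components(surv)
    if (nrow(relab$components))
      expect_true(all(relab$components$physical_volume_um3 >= V))
    expect_lte(sum(surv$grid), prev)
    prev <- sum(surv$grid)
  }
})

test_that("seeded selection returns exactly the component nearest the seed", {
  g <- array(FALSE, c(5, 20, 20))
  g[2:4, 2:6, 2:6] <- TRUE      # blob A (75 voxels)
  g[2:3, 12:15, 12:15] <- TRUE  # blob B (32 voxels)
  g[5, 19, 19] <- TRUE          # single voxel C
  m <- voxel_mask(g, c(1, 1, 1))
  lab <- label_components(m)
  expect_equal(nrow(lab$components), 3L)

  insideA <- select_neuron(lab, c(3, 3, 2))  # (x, y, z) inside blob A
  expect_equal(sum(insideA$grid), 75L)
  expect_equal(nrow(label_components(insideA)$components), 1L)

  # seed 2 um off blob B with a 5 um snap radius
  offB <- select_neuron(lab, c(13, 9, 2), snap_radius = 5)
  expect_equal(sum(offB$grid), 32L)

  expect_error(select_neuron(lab, c(10, 9, 4), snap_radius = 0), "soma seed")
})

test_that("eraser edits only remove voxels and respect geometry", {
  g <- array(TRUE, c(9, 9, 9))
  m <- voxel_mask(g, c(1, 1, 1))
  # empty eraser set: identity
  none <- marker_set(data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), kind = character(0),
                                param = numeric(0)))
  expect_identical(apply_edits(m, none)$grid, g)

  # sphere radius 2 at isotropic 1 um spacing removes the 33-voxel ball
  ball <- marker_set(data.frame(x = 4, y = 4, z = 4, kind = "eraser_sphere",
                                param = 2))
  out <- apply_edits(m, ball)
  expect_equal(sum(g) - sum(out$grid), 33L)
  expect_true(all(out$grid <= g))

  # sphere covering the whole volume empties the mask
  all_gone <- apply_edits(m, marker_set(data.frame(
    x = 4, y = 4, z = 4, kind = "eraser_sphere", param = 20)))
  expect_equal(sum(all_gone$grid), 0L)

  # box with half-extent 1 removes a 3x3x3 block
  box <- apply_edits(m, marker_set(data.frame(
    x = 4, y = 4, z = 4, kind = "eraser_box", param = 1)))
  expect_equal(sum(g) - sum(box$grid), 27L)
})

test_that("threshold sweep reports monotone foreground on both regimes", {
  set.seed(8)
  spec <- small_phantom_spec(seed = 31)
  ph <- make_phantom(spec)
  rep <- evaluate_thresholds(ph$volume, c(160, 190, 220, 250))
  expect_equal(nrow(rep), 4L)
  expect_true(all(diff(rep$foreground_fraction) <= 0))
  expect_true(all(rep$largest_volume_um3 >= 0))

  spec2 <- phantom_spec(mode = "microct", shape = c(64L, 64L, 64L),
                        n_bifurcations = 0L, segment_length = c(10, 14),
                        gap_length = c(3, 6), seed = 32)
  ph2 <- make_phantom(spec2)
  rep2 <- evaluate_thresholds(ph2$volume, c(20, 40, 60, 80))
  expect_equal(nrow(rep2), 4L)
  expect_true(all(diff(rep2$foreground_fraction) <= 0))

  # single candidate at the maximum intensity keeps only maximal voxels
  vmax <- max(ph$volume$grid)
  r1 <- evaluate_thresholds(ph$volume, vmax)
  expect_equal(r1$foreground_fraction * length(ph$volume$grid),
               sum(ph$volume$grid == vmax))
  expect_error(evaluate_thresholds(ph$volume, c(200, 150)), "increasing")
  expect_error(evaluate_thresholds(ph$volume, numeric(0)), "nonempty")
})
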