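# Synthetic phantom generator: determinism, tree structure, corruption
# bookkeeping, distractor behavior.

test_that("phantom generation is deterministic per seed", {
  spec <- small_phantom_spec(seed = 5, gap_fraction = 0.15)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(as.data.frame(a$truth$tree), as.data.frame(b$truth$tree))
  expect_identical(a$truth$gaps, b$truth$gaps)
  expect_identical(a$truth$distractor_mask$grid, b$truth$distractor_mask$grid)
  # a different seed gives a different phantom
  c <- make_phantom(small_phantom_spec(seed = 6, gap_fraction = 0.15))
  expect_false(identical(a$volume$grid, c$volume$grid))
})

test_that("generated trees honor the requested structure and fit the volume", {
  spec <- small_phantom_spec(seed = 17)
  tree <- generate_tree(spec)
  expect_length(branch_segments(tree), 2L * spec$n_bifurcations + 1L)
  expect_identical(as.data.frame(generate_tree(spec)), as.data.frame(tree))
  ext <- rev((spec$shape - 1) * spec$spacing)
  expect_true(all(tree$x >= 0 & tree$x <= ext[1]))
  expect_true(all(tree$y >= 0 & tree$y <= ext[2]))
  expect_true(all(tree$z >= 0 & tree$z <= ext[3]))
  # unbranched request gives a single path
  spec0 <- small_phantom_spec(seed = 18, n_bifurcations = 0L)
  expect_length(branch_segments(generate_tree(spec0)), 1L)
  # an impossible request errors rather than looping
  tiny <- phantom_spec(shape = c(10L, 12L, 12L), segment_length = c(25, 45),
                       gap_length = c(5, 10), seed = 1)
  expect_error(generate_tree(tiny), "too small|generation failed")
})

test_that("rendering separates neurite from background at the threshold", {
  spec <- small_phantom_spec(seed = 23, noise_sd = 0)
  # noiseless straight tube: thresholding at the midpoint intensity
  # recovers a mask whose skeleton length is within 5% of the tree length
  tube <- straight_tube_volume(length_um = 90)
  midpoint <- (240 + 120) / 2
  mask <- threshold_volume(tube$volume, midpoint)
  skel <- skeletonize_to_swc(mask, tube$volume, tube$start,
                             intensity_threshold = midpoint)
  expect_equal(total_length(skel), total_length(tube$tree),
               tolerance = 0.05)
  # background-only rendering is empty at the neurite threshold
  empty <- voxelize_tree(NULL, spec)
  expect_equal(sum(threshold_volume(empty, spec$neurite_mean)$grid), 0L)
  # zero-noise rendering is deterministic
  tree <- generate_tree(spec)
  expect_identical(voxelize_tree(tree, spec)$grid,
                   voxelize_tree(tree, spec)$grid)
})

test_that("corruption bookkeeping matches the carved volume", {
  spec <- small_phantom_spec(seed = 29, gap_fraction = 0.15)
  ph <- make_phantom(spec)
  L <- total_length(ph$truth$tree)
  gaps <- ph$truth$gaps
  glen <- sum(gaps$arc_end - gaps$arc_start)
  expect_gt(nrow(gaps), 0L)
  expect_equal(glen / L, 0.15, tolerance = 0.35)
  expect_true(all(gaps$arc_start >= 0))
  expect_true(all(gaps$arc_end > gaps$arc_start))
  expect_true(all(gaps$type %in% c("interruption", "undetected_branch")))

  # no corruption requested: identical volume, empty gap table
  spec0 <- small_phantom_spec(seed = 29, gaps_per_100um = 0, n_vessels = 0L,
                              n_glia = 0L, n_puncta = 0L)
  tree0 <- generate_tree(spec0)
  vol0 <- voxelize_tree(tree0, spec0)
  out0 <- corrupt_volume(vol0, tree0, spec0)
  expect_identical(out0$volume$grid, vol0$grid)
  expect_equal(nrow(out0$truth$gaps), 0L)
  expect_equal(nrow(terminal_positions(out0$truth$terminal_markers)), 0L)

  # one interior gap on an unbranched tube yields exactly 2 components
  spec1 <- phantom_spec(shape = c(32L, 96L, 96L), n_bifurcations = 0L,
                        segment_length = c(60, 70), gap_fraction = 0.1,
                        n_vessels = 0L, n_glia = 0L, n_puncta = 0L,
                        seed = 41)
  ph1 <- make_phantom(spec1)
  if (nrow(ph1$truth$gaps) == 1L &&
      ph1$truth$gaps$type[1] == "interruption") {
    lab <- label_components(threshold_volume(ph1$volume, 220))
    big <- lab$components$voxel_count > 5  # ignore stray noise voxels
    expect_equal(sum(big), 2L)
  }
})

test_that("distractors are disjoint from the neurite and behave as designed", {
  spec <- small_phantom_spec(seed = 37, gaps_per_100um = 0,
                             n_vessels = 2L, n_glia = 3L, n_puncta = 15L)
  ph <- make_phantom(spec)
  # disjoint from the true tube
  smp <- neurostitch:::tree_tube_samples(ph$truth$tree, 1)
  dims <- dim(ph$volume$grid)
  vx <- physical_to_index(smp$points, ph$volume$spacing, dims, clamp = TRUE)
  tube <- neurostitch:::stamp_spheres(array(FALSE, dims), ph$volume$spacing,
                                      vx, smp$radii)
  expect_equal(sum(tube & ph$truth$distractor_mask$grid), 0L)

  # puncta-only corruption is eliminated by the 1000 um^3 volume filter
  specp <- small_phantom_spec(seed = 38, gaps_per_100um = 0, n_vessels = 0L,
                              n_glia = 0L, n_puncta = 20L)
  php <- make_phantom(specp)
  mask <- threshold_volume(php$volume, 220)
  filtered <- filter_small_components(label_components(mask), 1000)
  expect_equal(sum(filtered$grid & php$truth$distractor_mask$grid), 0L)

  # vessels are bright enough to survive thresholding (they must be removed
  # by connectivity, not intensity)
  specv <- small_phantom_spec(seed = 39, gaps_per_100um = 0, n_vessels = 2L,
                              n_glia = 0L, n_puncta = 0L)
  phv <- make_phantom(specv)
  if (any(phv$truth$distractor_mask$grid)) {
    maskv <- threshold_volume(phv$volume, 220)
    frac <- sum(maskv$grid & phv$truth$distractor_mask$grid) /
      sum(phv$truth$distractor_mask$grid)
    expect_gt(frac, 0.5)
  }
})

test_that("thresholded foreground arc accounts for the carved gaps", {
  spec <- small_phantom_spec(seed = 43, gap_fraction = 0.15, n_vessels = 0L,
                             n_glia = 0L, n_puncta = 0L)
  ph <- make_phantom(spec)
  L <- total_length(ph$truth$tree)
  glen <- sum(ph$truth$gaps$arc_end - ph$truth$gaps$arc_start)
  # walk the truth centerline and measure how much survives thresholding
  mask <- threshold_volume(ph$volume, 220)
  dims <- dim(mask$grid)
  geos <- neurostitch:::branch_geometry(ph$truth$tree)
  surv <- 0; tot <- 0
  for (geo in geos) {
    ss <- seq(0, geo$length, by = 0.5)
    for (s in ss) {
      at <- neurostitch:::branch_at(geo, s)
      vx <- physical_to_index(at$point, mask$spacing, dims, clamp = TRUE)
      tot <- tot + 0.5
      if (mask$grid[vx[1], vx[2], vx[3]]) surv <- surv + 0.5
    }
  }
  expect_equal(surv, L - glen, tolerance = 0.1)
})
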