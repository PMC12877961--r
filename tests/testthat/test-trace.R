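# Geodesic tracing: cost field, shortest paths vs an exhaustive oracle,
# marker attachment, radius estimation.

test_that("cost field follows the exponential intensity law", {
  vol <- volume3d(array(c(0, 128, 255), c(1, 1, 3)), c(1, 1, 1))
  p <- trace_cost_params(lambda = 10, gamma = 2, i_max = 255)
  cf <- build_cost_field(vol, p)
  expect_equal(cf[1, 1, 3], 1)           # I = i_max
  expect_equal(cf[1, 1, 1], exp(10))     # I = 0
  # I = i_max / 2 -> exp(lambda / 4) for gamma = 2
  vol2 <- volume3d(array(127.5, c(1, 1, 1)), c(1, 1, 1))
  cf2 <- build_cost_field(vol2, trace_cost_params(10, 2, i_max = 255))
  expect_equal(cf2[1, 1, 1], exp(10 * 0.25))
  expect_true(all(cf >= 1 & cf <= exp(10)))
  expect_error(trace_cost_params(lambda = 0), "lambda")
  expect_error(trace_cost_params(gamma = 0.5), "gamma")
  expect_error(trace_cost_params(i_max = 0), "i_max")
})

test_that("uniform volumes trace straight axis paths with physical lengths", {
  vol <- volume3d(array(100, c(5, 5, 9)), c(2.5, 1, 1))
  cf <- build_cost_field(vol)
  p <- trace_path(vol, cf, c(3, 3, 1), c(3, 3, 9))
  expect_equal(p$length_um, 8)   # 8 unit steps along x
  expect_equal(nrow(p$voxels), 9L)
  expect_true(all(p$voxels[, 1] == 3 & p$voxels[, 2] == 3))
  # along z the same path costs its physical length
  pz <- trace_path(vol, cf, c(1, 3, 3), c(5, 3, 3))
  expect_equal(pz$length_um, 4 * 2.5)
  expect_error(trace_path(vol, cf, c(1, 1, 1), c(1, 1, 1)), "differ")
  expect_error(trace_path(vol, cf, c(1, 1, 1), c(9, 1, 1)), "bounds")
})

test_that("trace cost matches exhaustive Dijkstra on random small volumes", {
  set.seed(1234)
  for (rep in 1:25) {
    dims <- c(sample(3:5, 1), sample(3:5, 1), sample(3:6, 1))
    g <- array(sample(0:255, prod(dims), replace = TRUE), dims)
    sp <- runif(3, 0.5, 2.5)
    vol <- volume3d(g, sp)
    cf <- build_cost_field(vol, trace_cost_params(lambda = 5))
    start <- c(1, 1, 1)
    goal <- dims
    p <- trace_path(vol, cf, start, goal, trace_cost_params(lambda = 5),
                    cost_cap = Inf)
    oracle <- oracle_dijkstra_cost(cf, sp, start, goal)
    expect_equal(p$cost, oracle, tolerance = 1e-10)
    # path is 26-connected, no repeats, length >= straight-line distance
    steps <- abs(diff(p$voxels))
    expect_true(all(steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
    expect_false(any(duplicated(p$voxels)))
    expect_gte(p$length_um + 1e-9, sqrt(sum(((start - goal) * sp)^2)))
  }
})

test_that("paths are deterministic and prefer bright tubes", {
  # L-shaped bright tube in a dark volume
  g <- array(10, c(3, 20, 20))
  g[2, 3, 3:15] <- 240
  g[2, 3:15, 15] <- 240
  vol <- volume3d(g, c(1, 1, 1))
  cf <- build_cost_field(vol)
  p1 <- trace_path(vol, cf, c(2, 3, 3), c(2, 15, 15))
  p2 <- trace_path(vol, cf, c(2, 3, 3), c(2, 15, 15))
  expect_identical(p1$voxels, p2$voxels)
  vals <- apply(p1$voxels, 1, function(v) g[v[1], v[2], v[3]])
  expect_true(all(vals == 240))  # stays inside the tube

  # cost cap abort reports the frontier
  tiny <- volume3d(array(0, c(1, 1, 30)), c(1, 1, 1))
  cft <- build_cost_field(tiny, trace_cost_params(i_max = 255))
  expect_error(trace_path(tiny, cft, c(1, 1, 1), c(1, 1, 30),
                          cost_cap = 1e-3), "frontier")
})

test_that("attach_marker matches a brute-force nearest-voxel scan", {
  set.seed(77)
  for (rep in 1:10) {
    dims <- sample(4:8, 3, replace = TRUE)
    g <- array(runif(prod(dims)) < 0.3, dims)
    if (!any(g)) g[1, 1, 1] <- TRUE
    sp <- runif(3, 0.5, 2.5)
    m <- voxel_mask(g, sp)
    marker <- c(runif(1, 0, (dims[3] - 1) * sp[3]),
                runif(1, 0, (dims[2] - 1) * sp[2]),
                runif(1, 0, (dims[1] - 1) * sp[1]))
    hit <- attach_marker(m, marker)
    # brute force over all foreground voxels
    best <- Inf; best_idx <- NULL
    for (ix in seq_len(dims[3])) for (iy in seq_len(dims[2]))
      for (iz in seq_len(dims[1])) {
        if (!g[iz, iy, ix]) next
        d <- sqrt(sum((c((ix - 1) * sp[3], (iy - 1) * sp[2],
                         (iz - 1) * sp[1]) - marker)^2))
        if (d < best - 1e-12) { best <- d; best_idx <- c(iz, iy, ix) }
      }
    expect_equal(unname(hit), best_idx)
  }

  # marker on a structure voxel returns that voxel
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE; g[3, 3, 3] <- TRUE
  m <- voxel_mask(g, c(1, 1, 1))
  expect_equal(unname(attach_marker(m, c(1, 1, 1))), c(2L, 2L, 2L))
  # equidistant tie resolves to the lexicographically smaller (z, y, x)
  g2 <- array(FALSE, c(1, 1, 3)); g2[1, 1, 1] <- TRUE; g2[1, 1, 3] <- TRUE
  m2 <- voxel_mask(g2, c(1, 1, 1))
  expect_equal(unname(attach_marker(m2, c(1, 0, 0))), c(1L, 1L, 1L))
  # empty structure / distance bound
  expect_error(attach_marker(voxel_mask(array(FALSE, c(2, 2, 2)),
                                        c(1, 1, 1)), c(0, 0, 0)), "empty")
  expect_error(attach_marker(m2, c(10, 10, 10), max_radius = 1), "within")
})

test_that("radius estimation recovers cylinder radii and floors in background", {
  # bright cylinder of radius 3 um along z at isotropic 1 um
  dims <- c(21, 21, 21)
  g <- array(50, dims)
  for (iy in 1:21) for (ix in 1:21) {
    if ((iy - 11)^2 + (ix - 11)^2 <= 9) g[, iy, ix] <- 240
  }
  vol <- volume3d(g, c(1, 1, 1))
  r <- estimate_radii(vol, matrix(c(11, 11, 11), 1), T = 200)
  expect_gte(r, 2.5)
  expect_lte(r, 3.5)
  # background node floors at half the minimum spacing
  rb <- estimate_radii(vol, matrix(c(2, 2, 2), 1), T = 200)
  expect_equal(rb, 0.5)
  # lowering T never decreases a radius
  set.seed(31)
  gn <- array(sample(0:255, 9^3, replace = TRUE), c(9, 9, 9))
  vn <- volume3d(gn, c(1, 1, 1))
  nodes <- matrix(c(5, 5, 5, 4, 6, 3), 2, byrow = TRUE)
  r_hi <- estimate_radii(vn, nodes, T = 200)
  r_lo <- estimate_radii(vn, nodes, T = 100)
  expect_true(all(r_lo >= r_hi))
})
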