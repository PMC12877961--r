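# Volume, SWC and marker I/O plus coordinate conventions.

test_that("TIFF volumes round-trip voxel-identically, multi-page and slice dir", {
  set.seed(11)
  grid <- array(sample(0:255, 3 * 4 * 4, replace = TRUE), c(3, 4, 4))
  vol <- volume3d(grid, spacing = c(2.5, 1, 1))
  f <- tempfile(fileext = ".tif")
  write_volume(vol, f)
  back <- read_volume(f, c(2.5, 1, 1))
  expect_equal(dim(back$grid), c(3L, 4L, 4L))
  expect_equal(back$bit_depth, 8L)
  expect_identical(back$grid, vol$grid)

  # directory of slices, lexicographic z order
  d <- tempfile()
  dir.create(d)
  for (i in 1:3) {
    page <- volume3d(grid[i, , , drop = FALSE], c(2.5, 1, 1))
    write_volume(page, file.path(d, sprintf("slice_%02d.tif", i)))
  }
  back2 <- read_volume(d, c(2.5, 1, 1))
  expect_identical(back2$grid, vol$grid)
})

test_that("16-bit volumes are recognized and round-trip", {
  grid <- array(c(0, 500, 32768, 65535), c(1, 2, 2))
  vol <- volume3d(grid, c(1, 1, 1), bit_depth = 16L)
  f <- tempfile(fileext = ".tif")
  write_volume(vol, f)
  back <- read_volume(f, c(1, 1, 1))
  expect_equal(back$bit_depth, 16L)
  expect_identical(back$grid, vol$grid)
})

test_that("mask round-trips through 0/255 TIFF", {
  set.seed(3)
  m <- voxel_mask(array(runif(60) > 0.5, c(3, 4, 5)), c(1, 1, 1))
  f <- tempfile(fileext = ".tif")
  write_mask(m, f)
  expect_identical(read_mask(f, c(1, 1, 1))$grid, m$grid)
})

test_that("volume constructor rejects invalid grids", {
  expect_error(volume3d(array(0, c(0, 2, 2)), c(1, 1, 1)), "dimensions")
  expect_error(volume3d(array(-1, c(2, 2, 2)), c(1, 1, 1)), "intensities")
  expect_error(volume3d(array(300, c(2, 2, 2)), c(1, 1, 1), 8L), "intensities")
  expect_error(volume3d(array(0, c(2, 2, 2)), c(0, 1, 1)), "spacing")
  expect_error(read_volume(tempfile(), c(1, 1, 1)), "does not exist")
})

test_that("convert_to_8bit maps windows linearly with round-half-up", {
  v16 <- function(vals) volume3d(array(vals, c(1, 1, length(vals))),
                                 c(1, 1, 1), bit_depth = 16L)
  # degenerate range maps to all zero
  expect_true(all(convert_to_8bit(v16(rep(500, 4)))$grid == 0))
  # full range maps to {0, 255}
  expect_equal(as.vector(convert_to_8bit(v16(c(0, 65535)))$grid), c(0, 255))
  # midpoint of a fixed window: round(32768 / 65535 * 255) = 128
  out <- convert_to_8bit(v16(c(0, 32768, 65535)), mode = "fixed",
                         lo = 0, hi = 65535)
  expect_equal(as.vector(out$grid), c(0, 128, 255))
  expect_equal(out$bit_depth, 8L)
  expect_error(convert_to_8bit(v16(c(0, 1)), mode = "fixed", lo = 5, hi = 5),
               "lo must be <")
  expect_error(convert_to_8bit(flat_volume(1)), "16-bit")
})

test_that("SWC files round-trip to 4 decimals and enforce structure", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 5 -1", "2 3 10 0 0 1 1"), f)
  tr <- read_swc(f)
  expect_s3_class(tr, "swc_tree")
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$stype, c(1L, 3L))
  expect_equal(tr$parent, c(-1L, 1L))

  # missing parent reference names the record
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 99"), f)
  expect_error(read_swc(f), "missing parent 99")
  # cycle
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 3", "3 3 2 0 0 1 2"), f)
  expect_error(read_swc(f), "cycle")
  # duplicate id / multiple roots
  writeLines(c("1 1 0 0 0 5 -1", "1 3 1 0 0 1 1"), f)
  expect_error(read_swc(f), "duplicate")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 -1"), f)
  expect_error(read_swc(f), "exactly one root")

  # random phantom tree round-trips field-identically at 4 decimals
  spec <- small_phantom_spec(seed = 21)
  tree <- generate_tree(spec)
  g <- tempfile(fileext = ".swc")
  write_swc(tree, g)
  back <- read_swc(g)
  expect_equal(back$id, tree$id)
  expect_equal(back$parent, tree$parent)
  expect_equal(back$stype, tree$stype)
  expect_equal(back$x, tree$x, tolerance = 1e-4)
  expect_equal(back$y, tree$y, tolerance = 1e-4)
  expect_equal(back$z, tree$z, tolerance = 1e-4)
  expect_equal(back$radius, tree$radius, tolerance = 1e-4)
})

test_that("marker CSV round-trips and rejects malformed content", {
  m <- marker_set(data.frame(
    x = c(1, 2, 3, 4), y = 0:3, z = c(5, 5, 5, 5),
    kind = c("soma_seed", "branch_terminal", "branch_terminal",
             "branch_terminal")))
  expect_equal(nrow(m), 4L)
  f <- tempfile(fileext = ".csv")
  write_markers(m, f)
  back <- read_markers(f, require_soma = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(m))

  expect_error(marker_set(data.frame(x = 1, y = 1, z = 1, kind = "blob")),
               "unknown marker kind")
  expect_error(marker_set(data.frame(x = 1, y = 1, z = 1,
                                     kind = "eraser_sphere")),
               "positive param")
  # soma count enforcement
  no_soma <- marker_set(data.frame(x = 1, y = 1, z = 1,
                                   kind = "branch_terminal"))
  write_markers(no_soma, f)
  expect_error(read_markers(f, require_soma = TRUE), "exactly one soma_seed")
})

test_that("physical coordinates are voxel centers with anisotropic spacing", {
  sp <- c(2.5, 1, 1)
  # third slice (1-based index 3) sits at z = 5 um for dz = 2.5
  expect_equal(index_to_physical(c(3, 1, 1), sp)[1, ],
               c(x = 0, y = 0, z = 5))
  expect_equal(index_to_physical(c(1, 1, 1), sp)[1, ],
               c(x = 0, y = 0, z = 0))
  expect_equal(physical_to_index(c(0, 0, 5), sp, c(10, 10, 10))[1, ],
               c(iz = 3L, iy = 1L, ix = 1L))
  expect_error(physical_to_index(c(0, 0, 50), sp, c(10, 10, 10)),
               "outside grid")

  # inverse identity on voxel centers for arbitrary anisotropic spacings
  set.seed(5)
  for (rep in 1:20) {
    sp <- runif(3, 0.3, 3)
    dims <- sample(2:9, 3, replace = TRUE)
    idx <- cbind(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    pt <- index_to_physical(idx, sp)
    expect_equal(unname(physical_to_index(pt, sp, dims)), unname(idx))
  }
})
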