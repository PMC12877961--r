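#' Construct a 3D volume
#'
#' A volume is a 3D scalar grid indexed `(z, y, x)` together with the physical
#' voxel spacing in micrometres and an intensity polarity. All physical
#' lengths and volumes in the package are computed from the spacing, so
#' anisotropic data (e.g. 1 x 1 x 2.5 um block-face stacks) are handled
#' correctly throughout.
#'
#' @param grid 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in um; all
#'   components must be positive.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @param polarity `"bright"` (signal brighter than background, the default
#'   for Golgi-type data) or `"dark"`.
#' @return An object of class `"volume3d"`: a list with elements `grid`,
#'   `spacing`, `bit_depth`, `polarity`.
#' @examples
#' v <- volume3d(array(0, c(3, 4, 4)), spacing = c(2.5, 1, 1))
#' dim(v$grid)
#' @export
volume3d <- function(grid, spacing, bit_depth = 8L, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array indexed (z, y, x)")
  if (any(dim(grid) < 1L)) stop("all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx) in um")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  imax <- 2^bit_depth - 1
  rng <- range(grid)
  if (rng[1] < 0 || rng[2] > imax)
    stop(sprintf("intensities must lie in [0, %d] for bit_depth %d", imax, bit_depth))
  storage.mode(grid) <- "double"
  structure(list(grid = grid, spacing = spacing, bit_depth = bit_depth,
                 polarity = polarity),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um, %d-bit, %s-foreground\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$bit_depth, x$polarity))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' Construct a binary voxel mask
#'
#' @param grid 3D logical array, dimensions `(nz, ny, nx)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um, inherited from the
#'   source volume.
#' @return An object of class `"voxel_mask"` with elements `grid`, `spacing`.
#' @export
voxel_mask <- function(grid, spacing) {
  if (!is.array(grid) || length(dim(grid)) != 3L || !is.logical(grid))
    stop("grid must be a 3D logical array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(grid = grid, spacing = spacing), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  n <- sum(x$grid)
  cat(sprintf("<voxel_mask> %d x %d x %d, %d foreground voxels (%.2f%%), %.4g um^3 each\n",
              d[1], d[2], d[3], n, 100 * n / prod(d), prod(x$spacing)))
  invisible(x)
}

# ---- TIFF I/O ---------------------------------------------------------------

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Read a 3D volume from TIFF
#'
#' Reads either a multi-page TIFF stack or a directory of equally sized 2D
#' TIFF slices (sorted lexicographically as z). Sample depth (8- or 16-bit)
#' is inferred from the file; mismatched slice shapes or unsupported sample
#' types are errors rather than silent truncation.
#'
#' @param path multi-page TIFF file or directory of single-page TIFF slices.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param polarity passed to [volume3d()].
#' @return A [volume3d()] with grid dimensions `(nz, ny, nx)`.
#' @export
read_volume <- function(path, spacing, polarity = "bright") {
  if (length(path) != 1L || !file.exists(path))
    stop("volume path does not exist: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no TIFF slices found in directory: ", path)
    files <- files[order(basename(files))]
    pages <- lapply(files, function(f) {
      p <- read_tiff_pages(f)
      if (length(p) != 1L)
        stop("slice file has ", length(p), " pages, expected 1: ", f)
      p[[1]]
    })
  } else {
    pages <- read_tiff_pages(path)
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("TIFF slices have unequal shapes; refusing to assemble volume")
  if (any(vapply(pages, function(p) length(dim(p)) > 2 && dim(p)[3] > 1, logical(1))))
    stop("multi-channel TIFF not supported; expected single-channel grayscale")
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  vmax <- max(vapply(pages, max, numeric(1)))
  if (any(vapply(pages, function(p) any(p != floor(p)) || min(p) < 0, logical(1))))
    stop("unsupported TIFF sample type: expected unsigned integer samples")
  bit_depth <- if (vmax > 255) 16L else 8L
  if (vmax > 65535) stop("unsupported TIFF sample type: values exceed 16-bit range")
  nz <- length(pages)
  ny <- dim(pages[[1]])[1]
  nx <- dim(pages[[1]])[2]
  grid <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) grid[i, , ] <- pages[[i]]
  volume3d(grid, spacing, bit_depth = bit_depth, polarity = polarity)
}

#' Write a 3D volume as a multi-page TIFF
#'
#' The file round-trips: [read_volume()] on the result reproduces the grid
#' voxel-for-voxel.
#'
#' @param vol a [volume3d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  imax <- 2^vol$bit_depth - 1
  nz <- dim(vol$grid)[1]
  pages <- lapply(seq_len(nz), function(i) vol$grid[i, , ] / imax)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = vol$bit_depth)
  if (!isTRUE(ok > 0)) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask a [voxel_mask()].
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- volume3d(array(ifelse(mask$grid, 255, 0), dim(mask$grid)),
                  mask$spacing, bit_depth = 8L)
  write_volume(vol, path)
}

#' Read an 8-bit 0/255 TIFF as a binary mask
#'
#' @param path TIFF file written by [write_mask()] (nonzero = foreground).
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @export
read_mask <- function(path, spacing) {
  vol <- read_volume(path, spacing)
  voxel_mask(vol$grid > 0, spacing)
}

#' Convert a 16-bit volume to 8-bit
#'
#' Linearly maps an intensity window onto `[0, 255]` with clipping and
#' round-half-up, as done when preparing 16-bit acquisitions for
#' threshold-based processing. `mode = "minmax"` uses the global intensity
#' range; `mode = "fixed"` uses the window `[lo, hi]` for reproducible
#' conversion across stacks. A constant volume (degenerate range) maps to
#' all zero, signalling absent contrast.
#'
#' @param vol a 16-bit [volume3d()].
#' @param mode `"minmax"` or `"fixed"`.
#' @param lo,hi window bounds for `mode = "fixed"`; `lo < hi` required.
#' @return An 8-bit [volume3d()].
#' @export
convert_to_8bit <- function(vol, mode = c("minmax", "fixed"), lo = NULL, hi = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  mode <- match.arg(mode)
  if (vol$bit_depth != 16L) stop("convert_to_8bit expects a 16-bit volume")
  if (mode == "minmax") {
    lo <- min(vol$grid)
    hi <- max(vol$grid)
    if (lo == hi) {
      return(volume3d(array(0, dim(vol$grid)), vol$spacing, 8L, vol$polarity))
    }
  } else {
    if (is.null(lo) || is.null(hi)) stop("fixed mode requires lo and hi")
    if (lo >= hi) stop("invalid window: lo must be < hi")
  }
  scaled <- (vol$grid - lo) / (hi - lo) * 255
  scaled <- pmin(pmax(scaled, 0), 255)
  out <- floor(scaled + 0.5)  # round half-up
  volume3d(array(out, dim(vol$grid)), vol$spacing, 8L, vol$polarity)
}

# ---- coordinate conventions -------------------------------------------------

#' Convert grid indices to physical coordinates
#'
#' Grid indices are 1-based `(iz, iy, ix)`; physical coordinates are voxel
#' centers in um with the center of voxel `(1, 1, 1)` at the origin, so
#' `z = (iz - 1) * dz` etc. Physical points are always `(x, y, z)`, matching
#' SWC column order; grid indices are always `(z, y, x)`, matching array
#' storage.
#'
#' @param idx integer matrix (n x 3) or length-3 vector of `(iz, iy, ix)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @return Numeric matrix (n x 3) of `(x, y, z)` in um.
#' @export
index_to_physical <- function(idx, spacing) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  cbind(x = (idx[, 3] - 1) * spacing[3],
        y = (idx[, 2] - 1) * spacing[2],
        z = (idx[, 1] - 1) * spacing[1])
}

#' Convert physical coordinates to grid indices
#'
#' Inverse of [index_to_physical()], rounding to the nearest voxel center.
#' Points outside the grid are a range error unless `clamp = TRUE`.
#'
#' @param pt numeric matrix (n x 3) or length-3 vector of `(x, y, z)` um.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param dim grid dimensions `(nz, ny, nx)`.
#' @param clamp clip out-of-range indices to the grid instead of erroring.
#' @return Integer matrix (n x 3) of 1-based `(iz, iy, ix)`.
#' @export
physical_to_index <- function(pt, spacing, dim, clamp = FALSE) {
  if (is.null(dim(pt))) pt <- matrix(pt, nrow = 1)
  idx <- cbind(iz = round(pt[, 3] / spacing[1]) + 1,
               iy = round(pt[, 2] / spacing[2]) + 1,
               ix = round(pt[, 1] / spacing[3]) + 1)
  if (clamp) {
    for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), dim[k])
  } else if (any(idx < 1) || any(idx[, 1] > dim[1]) || any(idx[, 2] > dim[2]) ||
             any(idx[, 3] > dim[3])) {
    stop("physical point outside grid bounds")
  }
  storage.mode(idx) <- "integer"
  idx
}

# linear (0-based) <-> (z,y,x) index helpers shared with the C++ layer
lin_to_idx <- function(lin, dims) {
  z <- lin %% dims[1]
  r <- lin %/% dims[1]
  y <- r %% dims[2]
  x <- r %/% dims[2]
  cbind(iz = z + 1L, iy = y + 1L, ix = x + 1L)
}

idx_to_lin <- function(idx, dims) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  as.integer(((idx[, 3] - 1L) * dims[2] + (idx[, 2] - 1L)) * dims[1] + (idx[, 1] - 1L))
}
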