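#' Background denoising by global intensity thresholding
#'
#' Golgi-type contrast puts neurites well above the tissue background, so a
#' single global threshold removes most background while preserving neuronal
#' structure. With `polarity = "bright"` (keep-above) a voxel is foreground
#' iff its intensity is `>= T`; with `"dark"` iff `<= T`. Raising `T` under
#' keep-above polarity can only shrink the mask (nestedness), which is the
#' basis of threshold sweeps.
#'
#' @param vol a [volume3d()].
#' @param T intensity threshold, within the volume's dynamic range
#'   `[0, 2^bit_depth - 1]`.
#' @param polarity `"bright"` (default: taken from the volume) or `"dark"`.
#' @return A [voxel_mask()].
#' @export
threshold_volume <- function(vol, T, polarity = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  if (is.null(polarity)) polarity <- vol$polarity
  imax <- 2^vol$bit_depth - 1
  if (!is.finite(T) || T < 0 || T > imax)
    stop(sprintf("threshold %g outside dynamic range [0, %d]", T, imax))
  g <- if (polarity == "bright") vol$grid >= T else vol$grid <= T
  voxel_mask(array(g, dim(vol$grid)), vol$spacing)
}

#' Label connected components of a binary mask
#'
#' Two foreground voxels share a label iff they are connected under the
#' chosen 3D adjacency (6 = faces, 18 = faces+edges, 26 = full neighborhood).
#' The default 26 preserves thin diagonal neurites. Labels are 1..K in scan
#' order; the components table records voxel counts, physical volumes
#' (`voxel_count * dz*dy*dx` um^3) and bounding boxes.
#'
#' @param mask a [voxel_mask()].
#' @param connectivity 6, 18 or 26.
#' @return An object of class `"cc_labeling"`: list with `label_grid`
#'   (integer array, 0 = background), `components` (data frame), `spacing`,
#'   `connectivity`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "voxel_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  dims <- dim(mask$grid)
  labels <- cc_label3d(as.logical(mask$grid), dims, connectivity)
  k <- attr(labels, "n_labels")
  label_grid <- array(labels, dims)
  voxvol <- prod(mask$spacing)
  if (k > 0L) {
    fg <- which(labels > 0L)
    lab <- labels[fg]
    counts <- tabulate(lab, nbins = k)
    idx <- lin_to_idx(fg - 1L, dims)
    comp <- data.frame(
      label = seq_len(k),
      voxel_count = counts,
      physical_volume_um3 = counts * voxvol,
      z0 = as.integer(tapply(idx[, 1], lab, min)),
      z1 = as.integer(tapply(idx[, 1], lab, max)),
      y0 = as.integer(tapply(idx[, 2], lab, min)),
      y1 = as.integer(tapply(idx[, 2], lab, max)),
      x0 = as.integer(tapply(idx[, 3], lab, min)),
      x1 = as.integer(tapply(idx[, 3], lab, max)))
  } else {
    comp <- data.frame(label = integer(0), voxel_count = integer(0),
                       physical_volume_um3 = numeric(0),
                       z0 = integer(0), z1 = integer(0), y0 = integer(0),
                       y1 = integer(0), x0 = integer(0), x1 = integer(0))
  }
  structure(list(label_grid = label_grid, components = comp,
                 spacing = mask$spacing, connectivity = connectivity),
            class = "cc_labeling")
}

#' @export
print.cc_labeling <- function(x, ...) {
  cat(sprintf("<cc_labeling> %d components (%d-connectivity), largest %.4g um^3\n",
              nrow(x$components), x$connectivity,
              if (nrow(x$components)) max(x$components$physical_volume_um3) else 0))
  invisible(x)
}

#' Remove components below a physical-volume threshold
#'
#' Keeps exactly the components whose physical volume is `>= min_volume`
#' um^3 (strictly smaller are removed). Stated in physical units so the same
#' rule (e.g. 1000 um^3 for punctate staining artefacts) applies across
#' voxel sizes.
#'
#' @param lab a [label_components()] result.
#' @param min_volume minimum physical volume in um^3 (>= 0).
#' @return A [voxel_mask()] of the surviving components.
#' @export
filter_small_components <- function(lab, min_volume = 1000) {
  stopifnot(inherits(lab, "cc_labeling"))
  if (min_volume < 0) stop("min_volume must be >= 0")
  keep <- lab$components$label[lab$components$physical_volume_um3 >= min_volume]
  g <- array(lab$label_grid %in% keep & lab$label_grid > 0L, dim(lab$label_grid))
  voxel_mask(g, lab$spacing)
}

#' Select the neuron component containing (or nearest) a soma seed
#'
#' Manual soma clicks rarely land exactly on the segmented structure, so the
#' seed snaps to the nearest foreground voxel within `snap_radius` um; the
#' component containing that voxel is returned alone.
#'
#' @param lab a [label_components()] result.
#' @param soma_seed physical `(x, y, z)` position in um.
#' @param snap_radius maximum snap distance in um (default 5).
#' @return A [voxel_mask()] containing a single connected component.
#' @export
select_neuron <- function(lab, soma_seed, snap_radius = 5) {
  stopifnot(inherits(lab, "cc_labeling"))
  dims <- dim(lab$label_grid)
  fg_mask <- voxel_mask(array(lab$label_grid > 0L, dims), lab$spacing)
  hit <- tryCatch(attach_marker(fg_mask, soma_seed, max_radius = snap_radius),
                  error = function(e) NULL)
  if (is.null(hit))
    stop(sprintf("no foreground voxel within %g um of soma seed (%.4g, %.4g, %.4g)",
                 snap_radius, soma_seed[1], soma_seed[2], soma_seed[3]))
  target <- lab$label_grid[hit[1], hit[2], hit[3]]
  voxel_mask(array(lab$label_grid == target, dims), lab$spacing)
}

#' Erase marked regions from a mask
#'
#' Applies the eraser markers (spheres and axis-aligned cubes): foreground
#' voxels whose centers fall inside any eraser are cleared; nothing is ever
#' added. Used to remove residual interfering branches and vessels that
#' survive volume filtering by being connected to nothing else.
#'
#' @param mask a [voxel_mask()].
#' @param erasers a [marker_set()]; only eraser kinds are used.
#' @return The edited [voxel_mask()].
#' @export
apply_edits <- function(mask, erasers) {
  stopifnot(inherits(mask, "voxel_mask"))
  er <- erasers[erasers$kind %in% c("eraser_sphere", "eraser_box"), , drop = FALSE]
  if (nrow(er) == 0L) return(mask)
  g <- mask$grid
  dims <- dim(g)
  sp <- mask$spacing
  for (i in seq_len(nrow(er))) {
    ctr <- c(er$x[i], er$y[i], er$z[i])
    r <- er$param[i]
    # bounding box in index space
    lo <- physical_to_index(pmax(ctr - r, 0), sp, dims, clamp = TRUE)
    hi <- physical_to_index(ctr + r, sp, dims, clamp = TRUE)
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    zc <- (zi - 1) * sp[1] - ctr[3]
    yc <- (yi - 1) * sp[2] - ctr[2]
    xc <- (xi - 1) * sp[3] - ctr[1]
    if (er$kind[i] == "eraser_sphere") {
      d2 <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`)
      inside <- d2 <= r^2
    } else {
      inz <- abs(zc) <= r; iny <- abs(yc) <= r; inx <- abs(xc) <= r
      inside <- outer(outer(inz, iny, `&`), inx, `&`)
    }
    sub <- g[zi, yi, xi, drop = FALSE]
    sub[inside] <- FALSE
    g[zi, yi, xi] <- sub
  }
  voxel_mask(g, sp)
}

#' Sweep candidate thresholds and report objective proxies
#'
#' Computes, for each candidate threshold, the foreground voxel fraction,
#' the number of connected components and the largest component's physical
#' volume. These proxies support choosing a denoising threshold (the
#' keep-above foreground fraction is non-increasing in `T`), but the
#' function deliberately does not auto-select one: the balance between
#' background removal and structure preservation is a judgement call.
#'
#' @param vol a [volume3d()].
#' @param candidates strictly increasing candidate thresholds (e.g.
#'   `c(160, 190, 220, 250)` for 8-bit fluorescence-type contrast, or
#'   `c(20, 40, 60, 80)` for micro-CT-type contrast).
#' @param connectivity passed to [label_components()].
#' @return An object of class `"threshold_report"`: data frame with columns
#'   `threshold, foreground_fraction, n_components, largest_volume_um3`.
#' @export
evaluate_thresholds <- function(vol, candidates, connectivity = 26L) {
  stopifnot(inherits(vol, "volume3d"))
  if (length(candidates) == 0L) stop("candidates must be nonempty")
  if (is.unsorted(candidates, strictly = TRUE))
    stop("candidates must be strictly increasing")
  rows <- lapply(candidates, function(T) {
    m <- threshold_volume(vol, T)
    lab <- label_components(m, connectivity)
    data.frame(threshold = T,
               foreground_fraction = mean(m$grid),
               n_components = nrow(lab$components),
               largest_volume_um3 = if (nrow(lab$components))
                 max(lab$components$physical_volume_um3) else 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_report", "data.frame")
  out
}
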