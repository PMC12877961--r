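#' Cost parameters for intensity-weighted geodesic tracing
#'
#' The tracing cost at a voxel with intensity `I` is
#' `c(v) = exp(lambda * (1 - I / i_max)^gamma)`, the de-facto standard
#' neurite-tracing weighting: bright voxels cost ~1, background voxels cost
#' up to `exp(lambda)`, so shortest paths hug the neurite signal and bridge
#' gaps along faint residual staining rather than cutting across dark
#' background.
#'
#' @param lambda cost steepness (> 0, default 10).
#' @param gamma exponent (>= 1, default 2).
#' @param i_max normalizing intensity; defaults to the volume maximum at use.
#' @return An object of class `"trace_cost_params"`.
#' @export
trace_cost_params <- function(lambda = 10, gamma = 2, i_max = NULL) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(gamma) || gamma < 1) stop("gamma must be >= 1")
  if (!is.null(i_max) && (!is.finite(i_max) || i_max <= 0))
    stop("i_max must be > 0")
  structure(list(lambda = lambda, gamma = gamma, i_max = i_max),
            class = "trace_cost_params")
}

#' Build the per-voxel tracing cost field
#'
#' Applies `c(v) = exp(lambda * (1 - I(v)/i_max)^gamma)` voxel-wise; values
#' lie in `[1, exp(lambda)]` and decrease with intensity. The volume must be
#' bright-foreground (invert first otherwise).
#'
#' @param vol a bright-foreground [volume3d()].
#' @param params a [trace_cost_params()].
#' @return Numeric 3D array of costs, same dimensions as the volume.
#' @export
build_cost_field <- function(vol, params = trace_cost_params()) {
  stopifnot(inherits(vol, "volume3d"), inherits(params, "trace_cost_params"))
  if (vol$polarity != "bright")
    stop("cost field expects bright-foreground polarity; invert the volume first")
  i_max <- if (is.null(params$i_max)) max(vol$grid) else params$i_max
  if (i_max <= 0) stop("i_max must be > 0 (volume has no signal?)")
  frac <- pmin(vol$grid / i_max, 1)
  array(exp(params$lambda * (1 - frac)^params$gamma), dim(vol$grid))
}

#' Trace a minimal-cost path between two voxels
#'
#' Runs Dijkstra's algorithm on the 26-neighbor voxel graph with edge weight
#' `physical_step_length * (c(a) + c(b)) / 2`. Ties are broken toward the
#' lexicographically smaller `(z, y, x)` voxel so identical inputs always
#' yield the identical path. The search aborts when the accumulated cost
#' exceeds `cost_cap` (default `exp(lambda) * 10 * straight-line distance`),
#' which bounds runaway searches across pure background; a capped trace is
#' an error reporting the most promising frontier voxel.
#'
#' @param vol a [volume3d()] (supplies spacing and the cap's default scale).
#' @param cost_field array from [build_cost_field()].
#' @param start,goal 1-based grid indices `(iz, iy, ix)`.
#' @param params the [trace_cost_params()] used to build the field (for the
#'   default cap).
#' @param cost_cap override for the accumulated-cost cap.
#' @return An object of class `"trace_path"`: list with `voxels` (n x 3
#'   matrix of grid indices), `cost`, `length_um`, and `points` (n x 3
#'   physical `(x, y, z)`).
#' @export
trace_path <- function(vol, cost_field, start, goal,
                       params = trace_cost_params(), cost_cap = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  dims <- dim(vol$grid)
  start <- as.integer(start); goal <- as.integer(goal)
  check_idx <- function(i, nm) {
    if (length(i) != 3L || any(i < 1L) || any(i > dims))
      stop(nm, " index out of grid bounds")
  }
  check_idx(start, "start"); check_idx(goal, "goal")
  if (all(start == goal)) stop("start and goal must differ")
  sp <- vol$spacing
  d_straight <- sqrt(sum(((start - goal) * sp)^2))
  if (is.null(cost_cap))
    cost_cap <- exp(params$lambda) * 10 * d_straight
  goal_mask <- logical(prod(dims))
  glin <- idx_to_lin(goal, dims)
  goal_mask[glin + 1L] <- TRUE
  res <- dijkstra_voxel(as.numeric(cost_field), dims, sp,
                        idx_to_lin(start, dims), goal_mask, glin, cost_cap)
  if (!res$reached) {
    fr <- lin_to_idx(res$frontier, dims)
    stop(sprintf(paste0("trace failed: cost cap %.4g exceeded before reaching goal; ",
                        "best frontier voxel (iz=%d, iy=%d, ix=%d)"),
                 cost_cap, fr[1], fr[2], fr[3]))
  }
  path_from_linear(res$path, res$cost, sp, dims)
}

path_from_linear <- function(lin, cost, spacing, dims) {
  vox <- lin_to_idx(lin, dims)
  pts <- index_to_physical(vox, spacing)
  steps <- if (nrow(pts) > 1) sqrt(rowSums((pts[-1, , drop = FALSE] -
                                            pts[-nrow(pts), , drop = FALSE])^2))
           else numeric(0)
  structure(list(voxels = vox, points = pts, cost = cost,
                 length_um = sum(steps)),
            class = "trace_path")
}

#' @export
print.trace_path <- function(x, ...) {
  cat(sprintf("<trace_path> %d voxels, length %.2f um, cost %.4g\n",
              nrow(x$voxels), x$length_um, x$cost))
  invisible(x)
}

#' Snap a physical marker to the nearest structure voxel
#'
#' Returns the foreground voxel whose center minimizes the physical distance
#' to the marker; exact ties resolve to the smallest `(z, y, x)`
#' lexicographic index. With a finite `max_radius`, markers farther than
#' that from any structure are an error.
#'
#' @param structure a nonempty [voxel_mask()].
#' @param marker physical `(x, y, z)` in um.
#' @param max_radius maximum snap distance in um (default `Inf`).
#' @return 1-based grid index `(iz, iy, ix)` of the nearest structure voxel.
#' @export
attach_marker <- function(structure, marker, max_radius = Inf) {
  stopifnot(inherits(structure, "voxel_mask"))
  fg <- which(structure$grid)
  if (length(fg) == 0L) stop("structure mask is empty")
  dims <- dim(structure$grid)
  idx <- lin_to_idx(fg - 1L, dims)
  pts <- index_to_physical(idx, structure$spacing)
  d2 <- (pts[, 1] - marker[1])^2 + (pts[, 2] - marker[2])^2 +
        (pts[, 3] - marker[3])^2
  best <- min(d2)
  if (sqrt(best) > max_radius)
    stop(sprintf("no structure voxel within %g um of marker", max_radius))
  cand <- which(d2 == best)
  # fg is in ascending linear order == lexicographic (z,y,x) order
  idx[cand[1], ]
}

#' Estimate per-node tube radii from the raw volume
#'
#' For each path node, the radius of the largest ball (physical metric)
#' whose voxel centers all have raw intensity `>= T`, capped at `cap` um and
#' floored at half the minimum spacing (the resolution limit). Radii feed
#' the SWC radius column and the repair-tube rasterization.
#'
#' @param raw a [volume3d()].
#' @param path a [trace_path()] or an n x 3 matrix of grid indices.
#' @param T intensity threshold defining the tube interior.
#' @param cap maximum radius in um (default 10).
#' @return Numeric vector of radii in um, one per node.
#' @export
estimate_radii <- function(raw, path, T, cap = 10) {
  stopifnot(inherits(raw, "volume3d"))
  imax <- 2^raw$bit_depth - 1
  if (T < 0 || T > imax) stop("threshold outside dynamic range")
  vox <- if (inherits(path, "trace_path")) path$voxels else path
  if (is.null(dim(vox))) vox <- matrix(vox, nrow = 1)
  sp <- raw$spacing
  dims <- dim(raw$grid)
  rmin <- min(sp) / 2
  steps <- seq(rmin, cap, by = rmin)
  vapply(seq_len(nrow(vox)), function(i) {
    ctr <- vox[i, ]
    r_ok <- rmin
    for (r in steps) {
      nhalf <- ceiling(r / sp)
      zi <- max(1, ctr[1] - nhalf[1]):min(dims[1], ctr[1] + nhalf[1])
      yi <- max(1, ctr[2] - nhalf[2]):min(dims[2], ctr[2] + nhalf[2])
      xi <- max(1, ctr[3] - nhalf[3]):min(dims[3], ctr[3] + nhalf[3])
      d2 <- outer(outer(((zi - ctr[1]) * sp[1])^2, ((yi - ctr[2]) * sp[2])^2, `+`),
                  ((xi - ctr[3]) * sp[3])^2, `+`)
      ball <- d2 <= r^2
      vals <- raw$grid[zi, yi, xi, drop = FALSE]
      # a ball reaching outside the grid counts as failing at this radius
      full_z <- (ctr[1] - nhalf[1]) >= 1 && (ctr[1] + nhalf[1]) <= dims[1]
      full_y <- (ctr[2] - nhalf[2]) >= 1 && (ctr[2] + nhalf[2]) <= dims[2]
      full_x <- (ctr[3] - nhalf[3]) >= 1 && (ctr[3] + nhalf[3]) <= dims[3]
      if (all(vals[ball] >= T) && full_z && full_y && full_x) r_ok <- r
      else break
    }
    r_ok
  }, numeric(1))
}

# Noise-tolerant local tube radius: largest ball around a voxel in which at
# least `frac` of voxel centers are at/above T (the strict all-voxels rule of
# estimate_radii is brittle to isolated sub-threshold noise voxels inside
# genuine structure). Internal: used by skeleton spur pruning.
robust_radius <- function(raw, vox, T, cap = 10, frac = 0.9) {
  sp <- raw$spacing
  dims <- dim(raw$grid)
  rmin <- min(sp) / 2
  r_ok <- rmin
  for (r in seq(rmin, cap, by = rmin)) {
    nhalf <- ceiling(r / sp)
    zi <- max(1, vox[1] - nhalf[1]):min(dims[1], vox[1] + nhalf[1])
    yi <- max(1, vox[2] - nhalf[2]):min(dims[2], vox[2] + nhalf[2])
    xi <- max(1, vox[3] - nhalf[3]):min(dims[3], vox[3] + nhalf[3])
    d2 <- outer(outer(((zi - vox[1]) * sp[1])^2, ((yi - vox[2]) * sp[2])^2, `+`),
                ((xi - vox[3]) * sp[3])^2, `+`)
    ball <- d2 <= r^2
    vals <- raw$grid[zi, yi, xi, drop = FALSE]
    inside <- (vox[1] - nhalf[1]) >= 1 && (vox[1] + nhalf[1]) <= dims[1] &&
      (vox[2] - nhalf[2]) >= 1 && (vox[2] + nhalf[2]) <= dims[2] &&
      (vox[3] - nhalf[3]) >= 1 && (vox[3] + nhalf[3]) <= dims[3]
    if (inside && mean(vals[ball] >= T) >= frac) r_ok <- r else break
  }
  r_ok
}
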