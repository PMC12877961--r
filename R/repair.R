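# Marker-guided branch repair: bridge staining gaps by tracing
# intensity-weighted geodesics from marked branch termini back to the
# soma-connected structure, then rasterize the traced centerlines as tubes.

# stamp spheres of given physical radii (um) centered at grid indices into a
# logical array; returns the updated array. Minimum radius one voxel so
# consecutive path spheres always overlap into a 26-connected tube.
stamp_spheres <- function(grid, spacing, centers, radii) {
  dims <- dim(grid)
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  radii <- pmax(radii, min(spacing))
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    r <- radii[i]
    nhalf <- ceiling(r / spacing)
    zi <- max(1, ctr[1] - nhalf[1]):min(dims[1], ctr[1] + nhalf[1])
    yi <- max(1, ctr[2] - nhalf[2]):min(dims[2], ctr[2] + nhalf[2])
    xi <- max(1, ctr[3] - nhalf[3]):min(dims[3], ctr[3] + nhalf[3])
    d2 <- outer(outer(((zi - ctr[1]) * spacing[1])^2,
                      ((yi - ctr[2]) * spacing[2])^2, `+`),
                ((xi - ctr[3]) * spacing[3])^2, `+`)
    sub <- grid[zi, yi, xi, drop = FALSE]
    sub[d2 <= r^2] <- TRUE
    grid[zi, yi, xi] <- array(sub, dim(sub))
  }
  grid
}

#' Repair interrupted branches from marked termini
#'
#' For every `branch_terminal` marker not already inside the soma-connected
#' mask, traces a minimal-cost geodesic through the raw volume from the
#' marker's voxel to the nearest (in path cost) voxel of the current neuron
#' mask, then rasterizes the path as a tube of its locally estimated radii.
#' Both discontinuity classes are handled by the same trace: a mid-branch
#' interruption reconnects a detached bright fragment (absorbed by
#' re-labelling against `foreground` after each repair, so fragments
#' reconnected earlier can serve as targets for later termini), while an
#' undetected terminal branch is reconstructed directly since the trace
#' starts at the marked tip itself.
#'
#' Failed traces (cost cap exceeded) are recorded in the report and the mask
#' is still returned with all successful repairs applied.
#'
#' @param neuron_mask the soma-connected component ([voxel_mask()]).
#' @param raw the raw [volume3d()] the traces run through.
#' @param markers a [marker_set()] with `branch_terminal` entries (and the
#'   soma seed, used to identify the base component during re-labelling).
#' @param params a [trace_cost_params()].
#' @param intensity_threshold threshold used for radius estimation along the
#'   repaired tubes (defaults to the denoising threshold 220).
#' @param foreground optional [voxel_mask()] of all thresholded foreground;
#'   when given, fragments touching a repair are absorbed by re-labelling.
#' @param connectivity adjacency for re-labelling (default 26).
#' @return A list of class `"repair_result"`: `mask` (repaired
#'   [voxel_mask()], a superset of the input), `paths` (list of
#'   [trace_path()]), `report` (data frame: terminal coordinates, status,
#'   path length, path cost).
#' @export
repair_neuron <- function(neuron_mask, raw, markers,
                          params = trace_cost_params(),
                          intensity_threshold = 220,
                          foreground = NULL, connectivity = 26L) {
  stopifnot(inherits(neuron_mask, "voxel_mask"), inherits(raw, "volume3d"))
  dims <- dim(neuron_mask$grid)
  if (!all(dims == dim(raw$grid)))
    stop("neuron_mask and raw volume dimensions differ")
  sp <- neuron_mask$spacing
  term <- terminal_positions(markers)
  soma <- tryCatch(soma_position(markers), error = function(e) NULL)
  cost_field <- build_cost_field(raw, params)
  mask <- neuron_mask$grid
  paths <- list()
  rows <- list()
  if (nrow(term) > 0) for (i in seq_len(nrow(term))) {
    pos <- term[i, ]
    vox <- physical_to_index(pos, sp, dims, clamp = TRUE)[1, ]
    if (mask[vox[1], vox[2], vox[3]]) {
      rows[[i]] <- data.frame(terminal_x = pos[1], terminal_y = pos[2],
                              terminal_z = pos[3], status = "already_connected",
                              path_length_um = 0, path_cost = 0)
      next
    }
    glin <- which(mask) - 1L
    goal_mask <- logical(prod(dims))
    goal_mask[glin + 1L] <- TRUE
    # nearest mask voxel (Euclid) supplies the cap scale and frontier reference
    idxg <- lin_to_idx(glin, dims)
    d2 <- ((idxg[, 1] - vox[1]) * sp[1])^2 + ((idxg[, 2] - vox[2]) * sp[2])^2 +
          ((idxg[, 3] - vox[3]) * sp[3])^2
    jn <- which.min(d2)
    cap <- exp(params$lambda) * 10 * max(sqrt(d2[jn]), min(sp))
    res <- dijkstra_voxel(as.numeric(cost_field), dims, sp,
                          idx_to_lin(vox, dims), goal_mask, glin[jn], cap)
    if (!res$reached) {
      fr <- lin_to_idx(res$frontier, dims)
      rows[[i]] <- data.frame(terminal_x = pos[1], terminal_y = pos[2],
                              terminal_z = pos[3],
                              status = sprintf("failed_frontier_%d_%d_%d",
                                               fr[1], fr[2], fr[3]),
                              path_length_um = NA_real_, path_cost = NA_real_)
      next
    }
    pth <- path_from_linear(res$path, res$cost, sp, dims)
    radii <- estimate_radii(raw, pth$voxels, intensity_threshold)
    mask <- stamp_spheres(mask, sp, pth$voxels, radii)
    # absorb bright fragments now touching the repaired structure
    if (!is.null(foreground)) {
      union <- mask | foreground$grid
      lab <- label_components(voxel_mask(array(union, dims), sp), connectivity)
      base_vox <- if (!is.null(soma))
        physical_to_index(soma, sp, dims, clamp = TRUE)[1, ] else vox
      base_lab <- lab$label_grid[base_vox[1], base_vox[2], base_vox[3]]
      if (base_lab == 0L) {
        fgm <- voxel_mask(array(union, dims), sp)
        hit <- attach_marker(fgm, if (!is.null(soma)) soma else pos)
        base_lab <- lab$label_grid[hit[1], hit[2], hit[3]]
      }
      mask <- array(lab$label_grid == base_lab, dims)
    }
    paths[[length(paths) + 1L]] <- pth
    rows[[i]] <- data.frame(terminal_x = pos[1], terminal_y = pos[2],
                            terminal_z = pos[3], status = "repaired",
                            path_length_um = pth$length_um,
                            path_cost = pth$cost)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(terminal_x = numeric(0), terminal_y = numeric(0),
               terminal_z = numeric(0), status = character(0),
               path_length_um = numeric(0), path_cost = numeric(0))
  structure(list(mask = voxel_mask(array(mask, dims), sp),
                 paths = paths, report = report),
            class = "repair_result")
}

#' @export
print.repair_result <- function(x, ...) {
  ok <- sum(x$report$status == "repaired")
  cat(sprintf("<repair_result> %d terminals: %d repaired, %d already connected, %d failed\n",
              nrow(x$report), ok,
              sum(x$report$status == "already_connected"),
              sum(!x$report$status %in% c("repaired", "already_connected"))))
  if (length(x$paths))
    cat(sprintf("  added path length %.2f um\n",
                sum(vapply(x$paths, function(p) p$length_um, numeric(1)))))
  invisible(x)
}
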