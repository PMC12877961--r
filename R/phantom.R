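# Synthetic Golgi-like phantoms: a random neuron tree rendered as bright
# tubes over a dimmer noisy background, corrupted with staining gaps
# (mid-branch interruptions and undetected terminal branches) and with the
# characteristic distractors of Golgi material - vessel-like tubes bright
# enough to survive thresholding, glia-like blobs, and punctate artefacts
# small enough to fall under the 1000 um^3 volume filter. Every phantom
# carries full ground truth so each pipeline stage can be scored.

#' Phantom specification
#'
#' Defaults emulate an 8-bit block-face fluorescence acquisition at
#' anisotropic (2.5, 1, 1) um spacing: neurite mean 240 over background mean
#' 120 with Gaussian noise sd 10, so the standard denoising threshold 220
#' separates signal from background. `mode = "microct"` switches to 0.65 um
#' isotropic spacing with the dimmer contrast regime where threshold 40
#' applies (neurite mean 60 over background 20, noise sd 5).
#'
#' @param mode `"fmost"` (default) or `"microct"` preset.
#' @param shape grid dimensions `(nz, ny, nx)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param n_bifurcations number of binary bifurcations in the ground-truth
#'   tree (branch count is `2 * n_bifurcations + 1`).
#' @param segment_length `(min, max)` critical-node-to-critical-node segment
#'   length in um.
#' @param branch_angle `(min, max)` bifurcation half-angle range, degrees.
#' @param root_radius neurite radius at the soma, um; tapers distally to a
#'   1.5 um floor (thinner tubes are not resolvable at the supported voxel
#'   samplings).
#' @param soma_radius soma ball radius in um (default 6, a typical mouse
#'   cortical pyramidal soma).
#' @param taper radius loss per um of arc distance.
#' @param neurite_mean,background_mean,noise_sd 8-bit intensity model.
#' @param gaps_per_100um expected staining-gap count per 100 um of cable.
#' @param gap_length `(min, max)` gap length in um (must fit inside
#'   segments).
#' @param gap_fraction optional target: total gap length as a fraction of
#'   total tree length; overrides the rate model when set.
#' @param n_vessels,n_glia,n_puncta distractor counts.
#' @param seed RNG seed; phantoms are bit-reproducible given the spec.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(mode = c("fmost", "microct"),
                         shape = NULL, spacing = NULL,
                         n_bifurcations = 5L,
                         segment_length = c(25, 45),
                         branch_angle = c(20, 60),
                         root_radius = 2, soma_radius = 6, taper = 0.004,
                         neurite_mean = NULL, background_mean = NULL,
                         noise_sd = NULL,
                         gaps_per_100um = 2, gap_length = c(5, 10),
                         gap_fraction = NULL,
                         n_vessels = 2L, n_glia = 3L, n_puncta = 20L,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fmost") {
    if (is.null(shape)) shape <- c(56L, 224L, 224L)
    if (is.null(spacing)) spacing <- c(2.5, 1, 1)
    if (is.null(neurite_mean)) neurite_mean <- 240
    if (is.null(background_mean)) background_mean <- 120
    if (is.null(noise_sd)) noise_sd <- 10
  } else {
    if (is.null(shape)) shape <- c(160L, 160L, 160L)
    if (is.null(spacing)) spacing <- c(0.65, 0.65, 0.65)
    if (is.null(neurite_mean)) neurite_mean <- 60
    if (is.null(background_mean)) background_mean <- 20
    if (is.null(noise_sd)) noise_sd <- 5
    segment_length <- pmin(segment_length, 35)
  }
  stopifnot(length(shape) == 3L, all(shape >= 8),
            length(spacing) == 3L, all(spacing > 0),
            n_bifurcations >= 0, length(segment_length) == 2L,
            segment_length[1] > 0, diff(segment_length) >= 0,
            neurite_mean > background_mean,
            noise_sd >= 0, gaps_per_100um >= 0,
            gap_length[1] > 0, gap_length[2] < segment_length[1],
            n_vessels >= 0, n_glia >= 0, n_puncta >= 0)
  if (!is.null(gap_fraction))
    stopifnot(gap_fraction >= 0, gap_fraction < 0.5)
  if (seed >= 2^31 - 10) stop("seed too large")
  structure(list(mode = mode, shape = as.integer(shape), spacing = spacing,
                 n_bifurcations = as.integer(n_bifurcations),
                 segment_length = segment_length, branch_angle = branch_angle,
                 root_radius = root_radius, soma_radius = soma_radius,
                 taper = taper,
                 neurite_mean = neurite_mean, background_mean = background_mean,
                 noise_sd = noise_sd, gaps_per_100um = gaps_per_100um,
                 gap_length = gap_length, gap_fraction = gap_fraction,
                 n_vessels = as.integer(n_vessels), n_glia = as.integer(n_glia),
                 n_puncta = as.integer(n_puncta), seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical extent (x, y, z) of the grid in um
phys_extent <- function(spec) {
  rev((spec$shape - 1) * spec$spacing)  # (x, y, z)
}

# random unit vector
runit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# rotate unit vector v by angle theta (radians) around a random axis
# perpendicular to v
tilt <- function(v, theta) {
  repeat {
    r <- rnorm(3)
    u <- r - sum(r * v) * v
    n <- sqrt(sum(u^2))
    if (n > 1e-8) { u <- u / n; break }
  }
  v * cos(theta) + u * sin(theta)
}

#' Generate a random ground-truth neuron tree
#'
#' Grows a rooted binary tree with exactly `n_bifurcations` bifurcations
#' from a soma at the volume center. Segments are gently curved polylines
#' (5 um sub-steps with small angular jitter) whose end-to-end lengths are
#' drawn from `segment_length`; bifurcation angles from `branch_angle`.
#' Direction proposals that would leave the volume (with a margin) are
#' redrawn; if a segment cannot be placed after bounded retries the whole
#' tree is regrown, and repeated failure is a generation error.
#'
#' Seeds the RNG from `spec$seed`, so the same spec always yields the
#' identical tree.
#'
#' @param spec a [phantom_spec()].
#' @return An [swc_tree()] in um, soma node stype 1, neurites stype 3.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  ext <- phys_extent(spec)
  margin <- spec$root_radius + 2 * max(spec$spacing)
  lo <- rep(margin, 3)
  hi <- ext - margin
  if (any(hi <= lo)) stop("phantom volume too small for the requested tree")
  inside <- function(p) all(p >= lo) && all(p <= hi)
  substep <- 5
  jitter_deg <- 4

  min_sep <- 7  # centerline self-avoidance separation, um
  for (attempt in 1:40) {
    soma <- ext / 2
    nodes <- data.frame(id = 1L, stype = 1L, x = soma[1], y = soma[2],
                        z = soma[3], radius = spec$soma_radius,
                        parent = -1L)
    arc_from_soma <- c(0)
    # FIFO of growing ends: (node row, direction) -> balanced tree
    queue <- list(list(row = 1L, dir = runit()))
    bif_left <- spec$n_bifurcations
    ok <- TRUE
    next_id <- 2L
    grow_segment <- function(row, dir) {
      # returns list(row, dir) of the new end, or NULL on failure
      L <- runif(1, spec$segment_length[1], spec$segment_length[2])
      origin <- c(nodes$x[row], nodes$y[row], nodes$z[row])
      exist <- cbind(nodes$x, nodes$y, nodes$z)
      # self-avoidance ignores structure near the growth origin (the parent
      # branch and, around a bifurcation, the sibling's first few steps)
      d_orig <- sqrt(rowSums((exist - matrix(origin, nrow(exist), 3,
                                             byrow = TRUE))^2))
      far <- exist[d_orig > 1.8 * substep, , drop = FALSE]
      for (try in 1:60) {
        p <- origin
        d <- dir
        nsub <- max(2L, ceiling(L / substep))
        pts <- matrix(0, nsub, 3)
        good <- TRUE
        for (s in seq_len(nsub)) {
          d <- tilt(d, runif(1, 0, jitter_deg * pi / 180))
          p <- p + d * (L / nsub)
          if (!inside(p)) { good <- FALSE; break }
          if (nrow(far) && min(sqrt(rowSums((far - matrix(p, nrow(far), 3,
                                                          byrow = TRUE))^2))) < min_sep) {
            good <- FALSE; break
          }
          pts[s, ] <- p
        }
        if (good) {
          base_arc <- arc_from_soma[row]
          ids <- next_id:(next_id + nsub - 1L)
          radii <- pmax(1.5, spec$root_radius -
                          spec$taper * (base_arc + seq_len(nsub) * L / nsub))
          nodes <<- rbind(nodes, data.frame(
            id = ids, stype = 3L, x = pts[, 1], y = pts[, 2], z = pts[, 3],
            radius = radii, parent = c(nodes$id[row], head(ids, -1))))
          arc_from_soma <<- c(arc_from_soma,
                              base_arc + seq_len(nsub) * L / nsub)
          next_id <<- next_id + nsub
          return(list(row = nrow(nodes), dir = d))
        }
        # redraw the whole segment with a fresh inward-biased direction
        ctr <- ext / 2 - c(nodes$x[row], nodes$y[row], nodes$z[row])
        nctr <- sqrt(sum(ctr^2))
        dir <- if (nctr > 1e-8) tilt(ctr / nctr, runif(1, 0, pi / 4)) else runit()
      }
      NULL
    }
    while (length(queue) && ok) {
      end <- queue[[1]]; queue <- queue[-1]
      res <- grow_segment(end$row, end$dir)
      if (is.null(res)) { ok <- FALSE; break }
      if (bif_left > 0L) {
        bif_left <- bif_left - 1L
        half <- runif(2, spec$branch_angle[1], spec$branch_angle[2]) * pi / 180
        d1 <- tilt(res$dir, half[1])
        # opposite side: reflect the first child's tilt about the parent dir
        d2 <- tilt(res$dir, half[2])
        for (try in 1:20) {
          if (sum(d1 * d2) < cos(sum(half) * 0.8)) break
          d2 <- tilt(res$dir, half[2])
        }
        queue <- c(queue, list(list(row = res$row, dir = d1)),
                   list(list(row = res$row, dir = d2)))
      }
    }
    if (ok && bif_left == 0L) return(swc_tree(nodes))
  }
  stop("phantom tree generation failed: volume too small for the requested tree")
}

# resample the tree's edges into (points, radii) at fine arc steps, for tube
# rendering and gap carving
tree_tube_samples <- function(tree, step) {
  pos <- swc_parent_pos(tree)
  has <- which(!is.na(pos))
  pts <- list(); rad <- list()
  for (i in has) {
    a <- c(tree$x[pos[i]], tree$y[pos[i]], tree$z[pos[i]])
    b <- c(tree$x[i], tree$y[i], tree$z[i])
    L <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(L / step))
    t <- seq(0, 1, length.out = k + 1L)
    pts[[length(pts) + 1L]] <- outer(t, b - a) + matrix(a, k + 1L, 3,
                                                       byrow = TRUE)
    rad[[length(rad) + 1L]] <- tree$radius[pos[i]] * (1 - t) +
      tree$radius[i] * t
  }
  list(points = do.call(rbind, pts), radii = unlist(rad))
}

#' Render a ground-truth tree as a noisy volume
#'
#' Stamps the tree as tubes of its per-node radii at `neurite_mean` over
#' `background_mean`, adds Gaussian noise of sd `noise_sd`, clips to the
#' 8-bit range and rounds. Seeds the RNG from `spec$seed + 1` so rendering
#' is reproducible independently of tree generation.
#'
#' @param tree an [swc_tree()] (um).
#' @param spec the [phantom_spec()].
#' @return An 8-bit [volume3d()].
#' @export
voxelize_tree <- function(tree, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed + 1L)
  dims <- spec$shape
  sp <- spec$spacing
  mask <- array(FALSE, dims)
  if (!is.null(tree)) {
    smp <- tree_tube_samples(tree, min(sp) / 2)
    vox <- physical_to_index(smp$points, sp, dims, clamp = TRUE)
    mask <- stamp_spheres(mask, sp, vox, smp$radii)
  }
  g <- array(spec$background_mean, dims)
  g[mask] <- spec$neurite_mean
  if (spec$noise_sd > 0) g <- g + rnorm(length(g), 0, spec$noise_sd)
  g <- floor(pmin(pmax(g, 0), 255) + 0.5)
  volume3d(array(g, dims), sp, bit_depth = 8L)
}

# ---- corruption -------------------------------------------------------------

# per-branch arc geometry of a truth tree
branch_geometry <- function(tree) {
  segs <- branch_segments(tree)
  rowpos <- seq_len(nrow(tree)); names(rowpos) <- tree$id
  pos <- swc_parent_pos(tree)
  nch <- tabulate(pos[!is.na(pos)], nbins = nrow(tree))
  lapply(segs, function(ids) {
    rows <- rowpos[as.character(ids)]
    P <- cbind(tree$x[rows], tree$y[rows], tree$z[rows])
    R <- tree$radius[rows]
    seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    list(rows = rows, points = P, radii = R, arc = c(0, cumsum(seg)),
         length = sum(seg), tip_end = nch[rows[length(rows)]] == 0L)
  })
}

# point/radius at arc position s along a branch geometry
branch_at <- function(geo, s) {
  arc <- geo$arc
  j <- findInterval(s, arc, rightmost.closed = TRUE)
  j <- min(max(j, 1L), length(arc) - 1L)
  w <- if (arc[j + 1] > arc[j]) (s - arc[j]) / (arc[j + 1] - arc[j]) else 0
  list(point = geo$points[j, ] * (1 - w) + geo$points[j + 1, ] * w,
       radius = geo$radii[j] * (1 - w) + geo$radii[j + 1] * w)
}

#' Corrupt a rendered phantom with staining gaps and distractors
#'
#' Erases the neurite signal (back to noisy background) along sampled arc
#' intervals of the ground-truth branches - interior intervals produce
#' mid-branch interruptions, intervals abutting a tip produce undetected
#' terminal branches - and adds the three distractor classes: vessel-like
#' random-walk tubes rendered at neurite intensity (they survive
#' thresholding and must be removed by connectivity or manual edits),
#' glia-like ellipsoidal blobs (each under 1000 um^3, removed by the volume
#' filter), and 1-3 voxel bright puncta. Distractors are placed disjoint
#' from the neurite tube, with bounded retries.
#'
#' The returned truth carries the ground-truth tree, the gap table, the
#' distractor mask, and a marker set with the soma seed at the root plus
#' one `branch_terminal` at every ground-truth tip lying distal to a gap.
#' Seeds the RNG from `spec$seed + 2`.
#'
#' @param vol the rendered [volume3d()] from [voxelize_tree()].
#' @param tree the ground-truth [swc_tree()].
#' @param spec the [phantom_spec()].
#' @return List `(volume, truth)` where `truth` has class `"phantom_truth"`.
#' @export
corrupt_volume <- function(vol, tree, spec) {
  stopifnot(inherits(vol, "volume3d"), inherits(spec, "phantom_spec"))
  set.seed(spec$seed + 2L)
  dims <- dim(vol$grid)
  sp <- vol$spacing
  g <- vol$grid

  # guard mask: neurite tube dilated by 2 um, for distractor disjointness
  guard <- array(FALSE, dims)
  if (!is.null(tree)) {
    smp <- tree_tube_samples(tree, min(sp))
    vox <- physical_to_index(smp$points, sp, dims, clamp = TRUE)
    guard <- stamp_spheres(guard, sp, vox, smp$radii + 2)
  }

  # ---- gaps -----------------------------------------------------------------
  gaps <- data.frame(branch = integer(0), arc_start = numeric(0),
                     arc_end = numeric(0), type = character(0))
  gapped_branch_rows <- integer(0)
  if (!is.null(tree)) {
    geos <- branch_geometry(tree)
    total_L <- sum(vapply(geos, `[[`, numeric(1), "length"))
    target <- if (!is.null(spec$gap_fraction)) spec$gap_fraction * total_L
              else NA_real_
    placed <- vector("list", length(geos))
    total_gap <- 0
    draw_gap <- function() {
      # pick a branch weighted by length, then an interval on it
      w <- vapply(geos, `[[`, numeric(1), "length")
      bi <- sample.int(length(geos), 1, prob = w)
      geo <- geos[[bi]]
      glen <- runif(1, spec$gap_length[1], min(spec$gap_length[2],
                                               geo$length * 0.6))
      # keep gaps clear of critical nodes; the proximal stem keeps a wider
      # clear zone so the soma fragment always survives extraction
      root_row <- which(tree$parent == -1L)
      buffer <- if (geo$rows[1] == root_row) 15 else 5
      if (geo$length < glen + buffer + 2) return(NULL)
      tip_type <- geo$tip_end && runif(1) < 0.5
      if (tip_type) {
        s0 <- geo$length - glen
        s1 <- geo$length
      } else {
        s0 <- runif(1, buffer, geo$length - glen - 2)
        s1 <- s0 + glen
      }
      for (iv in placed[[bi]]) {
        if (s0 < iv[2] + 2 && s1 > iv[1] - 2) return(NULL)  # overlap
      }
      list(branch = bi, s0 = s0, s1 = s1,
           type = if (tip_type) "undetected_branch" else "interruption")
    }
    n_draws <- if (!is.null(spec$gap_fraction)) 10000L
               else rpois(1, spec$gaps_per_100um * total_L / 100)
    drawn <- 0L
    while (drawn < n_draws) {
      if (!is.null(spec$gap_fraction) && total_gap >= target) break
      gp <- draw_gap()
      drawn <- drawn + 1L
      if (is.null(gp)) next
      placed[[gp$branch]] <- c(placed[[gp$branch]], list(c(gp$s0, gp$s1)))
      gaps <- rbind(gaps, data.frame(branch = gp$branch, arc_start = gp$s0,
                                     arc_end = gp$s1, type = gp$type))
      total_gap <- total_gap + (gp$s1 - gp$s0)
    }
    # carve the gaps as clipped capsules: a voxel is erased when it is within
    # the tube radius (plus a quantization margin) of the gap interval AND
    # closer to the gap interval than to the intact remainder of the branch,
    # so the erased arc length matches the nominal gap length
    for (i in seq_len(nrow(gaps))) {
      geo <- geos[[gaps$branch[i]]]
      step <- min(sp) / 2
      sg <- seq(gaps$arc_start[i], gaps$arc_end[i], by = step)
      ss_all <- seq(0, geo$length, by = step)
      sk <- ss_all[ss_all < gaps$arc_start[i] - step / 2 |
                   ss_all > gaps$arc_end[i] + step / 2]
      gap_pts <- t(vapply(sg, function(s) branch_at(geo, s)$point, numeric(3)))
      gap_rad <- vapply(sg, function(s) branch_at(geo, s)$radius, numeric(1))
      keep_pts <- t(vapply(sk, function(s) branch_at(geo, s)$point, numeric(3)))
      # bounding box around the gap
      rmax <- max(gap_rad) + 2 * max(sp)
      lo <- physical_to_index(pmax(apply(gap_pts, 2, min) - rmax, 0), sp, dims,
                              clamp = TRUE)
      hi <- physical_to_index(apply(gap_pts, 2, max) + rmax, sp, dims,
                              clamp = TRUE)
      zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
      coords <- as.matrix(expand.grid(iz = zi, iy = yi, ix = xi))
      pp <- index_to_physical(coords, sp)
      d_gap <- rep(Inf, nrow(pp)); r_at <- rep(0, nrow(pp))
      for (k in seq_len(nrow(gap_pts))) {
        dd <- (pp[, 1] - gap_pts[k, 1])^2 + (pp[, 2] - gap_pts[k, 2])^2 +
              (pp[, 3] - gap_pts[k, 3])^2
        upd <- dd < d_gap
        d_gap[upd] <- dd[upd]; r_at[upd] <- gap_rad[k]
      }
      d_keep <- rep(Inf, nrow(pp))
      for (k in seq_len(nrow(keep_pts))) {
        dd <- (pp[, 1] - keep_pts[k, 1])^2 + (pp[, 2] - keep_pts[k, 2])^2 +
              (pp[, 3] - keep_pts[k, 3])^2
        d_keep <- pmin(d_keep, dd)
      }
      sel <- d_gap <= (r_at + min(sp))^2 & d_gap < d_keep
      if (any(sel)) {
        lin <- idx_to_lin(coords[sel, , drop = FALSE], dims) + 1L
        g[lin] <- floor(pmin(pmax(spec$background_mean +
                                    rnorm(sum(sel), 0, spec$noise_sd), 0),
                             255) + 0.5)
      }
    }
    gapped_branch_rows <- unique(vapply(
      seq_len(nrow(gaps)),
      function(i) {
        rows <- geos[[gaps$branch[i]]]$rows
        rows[length(rows)]  # distal critical node of the gapped branch
      }, numeric(1)))
  }

  # ---- distractors ----------------------------------------------------------
  dmask <- array(FALSE, dims)
  ext <- phys_extent(spec)
  place_disjoint <- function(stamper) {
    for (try in 1:25) {
      cand <- array(FALSE, dims)
      cand <- stamper(cand)
      if (!any(cand & guard)) return(cand)
    }
    NULL
  }
  rand_point <- function(margin) {
    c(runif(1, margin, ext[1] - margin),
      runif(1, margin, ext[2] - margin),
      runif(1, margin, ext[3] - margin))
  }
  add_intensity <- function(sel, mean_i) {
    n <- sum(sel)
    g[sel] <<- floor(pmin(pmax(mean_i + rnorm(n, 0, spec$noise_sd), 0), 255) + 0.5)
  }
  if (spec$n_vessels > 0) for (v in seq_len(spec$n_vessels)) {
    cand <- place_disjoint(function(cand) {
      p <- rand_point(5)
      d <- runit()
      nstep <- sample(25:40, 1)
      for (s in seq_len(nstep)) {
        d <- tilt(d, runif(1, 0, 12 * pi / 180))
        p2 <- p + d * 4
        p2 <- pmin(pmax(p2, 2), ext - 2)
        vx <- physical_to_index(rbind(p, p2), sp, dims, clamp = TRUE)
        mid <- (p + p2) / 2
        vm <- physical_to_index(mid, sp, dims, clamp = TRUE)
        cand <- stamp_spheres(cand, sp, rbind(vx, vm), rep(2, 3))
        p <- p2
      }
      cand
    })
    if (!is.null(cand)) { add_intensity(cand, spec$neurite_mean); dmask <- dmask | cand }
  }
  if (spec$n_glia > 0) for (b in seq_len(spec$n_glia)) {
    cand <- place_disjoint(function(cand) {
      ctr <- rand_point(8)
      ax <- runif(3, 3, 6)
      # keep each blob under the 1000 um^3 artefact threshold
      while (4 / 3 * pi * prod(ax) >= 950) ax <- ax * 0.9
      vx <- physical_to_index(ctr, sp, dims, clamp = TRUE)
      nhalf <- ceiling(ax / rev(sp))  # (x,y,z) half-extents -> index space
      zi <- max(1, vx[1] - nhalf[3]):min(dims[1], vx[1] + nhalf[3])
      yi <- max(1, vx[2] - nhalf[2]):min(dims[2], vx[2] + nhalf[2])
      xi <- max(1, vx[3] - nhalf[1]):min(dims[3], vx[3] + nhalf[1])
      zc <- ((zi - 1) * sp[1] - ctr[3]) / ax[3]
      yc <- ((yi - 1) * sp[2] - ctr[2]) / ax[2]
      xc <- ((xi - 1) * sp[3] - ctr[1]) / ax[1]
      ell <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) <= 1
      sub <- cand[zi, yi, xi, drop = FALSE]
      sub[ell] <- TRUE
      cand[zi, yi, xi] <- array(sub, dim(sub))
      cand
    })
    if (!is.null(cand)) { add_intensity(cand, 230); dmask <- dmask | cand }
  }
  if (spec$n_puncta > 0) for (pn in seq_len(spec$n_puncta)) {
    cand <- place_disjoint(function(cand) {
      vx <- physical_to_index(rand_point(2), sp, dims, clamp = TRUE)
      nvox <- sample(1:3, 1)
      cand[vx[1], vx[2], vx[3]] <- TRUE
      if (nvox >= 2 && vx[3] < dims[3]) cand[vx[1], vx[2], vx[3] + 1] <- TRUE
      if (nvox >= 3 && vx[2] < dims[2]) cand[vx[1], vx[2] + 1, vx[3]] <- TRUE
      cand
    })
    if (!is.null(cand)) { add_intensity(cand, 255); dmask <- dmask | cand }
  }

  # ---- terminal markers -----------------------------------------------------
  markers <- NULL
  if (!is.null(tree)) {
    root <- which(tree$parent == -1L)
    mk <- data.frame(x = tree$x[root], y = tree$y[root], z = tree$z[root],
                     kind = "soma_seed", param = NA_real_)
    if (length(gapped_branch_rows)) {
      pos <- swc_parent_pos(tree)
      nch <- tabulate(pos[!is.na(pos)], nbins = nrow(tree))
      children <- split(seq_len(nrow(tree))[!is.na(pos)], pos[!is.na(pos)])
      affected <- logical(nrow(tree))
      for (b in gapped_branch_rows) {
        queue <- b
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          affected[v] <- TRUE
          queue <- c(queue, children[[as.character(v)]])
        }
      }
      tips <- which(nch == 0L & affected)
      if (length(tips))
        mk <- rbind(mk, data.frame(x = tree$x[tips], y = tree$y[tips],
                                   z = tree$z[tips], kind = "branch_terminal",
                                   param = NA_real_))
    }
    markers <- marker_set(mk)
  }

  out_vol <- volume3d(array(g, dims), sp, bit_depth = 8L)
  truth <- structure(list(tree = tree, gaps = gaps,
                          distractor_mask = voxel_mask(dmask, sp),
                          terminal_markers = markers),
                     class = "phantom_truth")
  list(volume = out_vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> tree: %s, %d gaps, %d distractor voxels, %d markers\n",
              if (is.null(x$tree)) "none"
              else sprintf("%d nodes / %.1f um", nrow(x$tree),
                           total_length(x$tree)),
              nrow(x$gaps), sum(x$distractor_mask$grid),
              if (is.null(x$terminal_markers)) 0 else nrow(x$terminal_markers)))
  invisible(x)
}

#' Generate a complete phantom
#'
#' Composition `generate_tree` -> `voxelize_tree` -> `corrupt_volume`,
#' fully deterministic per `spec$seed` (each stage seeds its own offset
#' stream, so the composition is bit-reproducible and the stages remain
#' individually reproducible).
#'
#' @param spec a [phantom_spec()].
#' @return List `(volume, truth)` as in [corrupt_volume()].
#' @export
make_phantom <- function(spec = phantom_spec()) {
  tree <- generate_tree(spec)
  vol <- voxelize_tree(tree, spec)
  corrupt_volume(vol, tree, spec)
}
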