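# Independent oracles used across the suite. These are deliberately naive
# implementations (breadth-first flood fill, O(n^2) Dijkstra, quadratic
# sphere-segment intersection) kept separate from the package's optimized
# code paths.

neighbor_offsets <- function(connectivity) {
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  nn <- abs(off$dz) + abs(off$dy) + abs(off$dx)
  if (connectivity == 6) off <- off[nn == 1, ]
  if (connectivity == 18) off <- off[nn <= 2, ]
  as.matrix(off)
}

# breadth-first flood fill labeling; labels in first-encounter scan order
flood_fill_labels <- function(mask, connectivity) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  off <- neighbor_offsets(connectivity)
  nextl <- 0L
  for (ix in seq_len(dims[3])) for (iy in seq_len(dims[2]))
    for (iz in seq_len(dims[1])) {
      if (!mask[iz, iy, ix] || labels[iz, iy, ix] != 0L) next
      nextl <- nextl + 1L
      queue <- list(c(iz, iy, ix))
      labels[iz, iy, ix] <- nextl
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(off))) {
          w <- v + c(off[k, "dz"], off[k, "dy"], off[k, "dx"])
          if (any(w < 1) || any(w > dims)) next
          if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
            labels[w[1], w[2], w[3]] <- nextl
            queue <- c(queue, list(w))
          }
        }
      }
    }
  labels
}

# canonicalize a labeling to first-encounter order so partitions compare
canon_labels <- function(labels) {
  v <- as.integer(labels)
  fg <- v != 0L
  mapping <- integer(max(v) + 1L)
  nxt <- 0L
  out <- v
  for (i in which(fg)) {
    l <- v[i]
    if (mapping[l + 1L] == 0L) { nxt <- nxt + 1L; mapping[l + 1L] <- nxt }
    out[i] <- mapping[l + 1L]
  }
  array(out, dim(labels))
}

# exhaustive O(n^2) Dijkstra over the full 26-neighbor voxel graph with the
# package's edge-weight convention; returns min cost start -> goal
oracle_dijkstra_cost <- function(cost, spacing, start, goal) {
  dims <- dim(cost)
  n <- prod(dims)
  coords <- as.matrix(expand.grid(iz = seq_len(dims[1]), iy = seq_len(dims[2]),
                                  ix = seq_len(dims[3])))
  id_of <- function(v) (v[3] - 1) * dims[2] * dims[1] + (v[2] - 1) * dims[1] + v[1]
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[id_of(start)] <- 0
  off <- neighbor_offsets(26)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) return(Inf)
    if (u == id_of(goal)) return(dist[u])
    done[u] <- TRUE
    vu <- coords[u, ]
    cu <- cost[vu[1], vu[2], vu[3]]
    for (k in seq_len(nrow(off))) {
      w <- vu + c(off[k, "dz"], off[k, "dy"], off[k, "dx"])
      if (any(w < 1) || any(w > dims)) next
      j <- id_of(w)
      if (done[j]) next
      step <- sqrt(sum((c(off[k, "dz"], off[k, "dy"], off[k, "dx"]) * spacing)^2))
      cand <- dist[u] + step * (cu + cost[w[1], w[2], w[3]]) / 2
      if (cand < dist[j]) dist[j] <- cand
    }
  }
}

# analytic count of transversal sphere crossings for one segment
segment_sphere_crossings <- function(p0, p1, center, r) {
  d <- p1 - p0
  f <- p0 - center
  a <- sum(d * d)
  b <- 2 * sum(f * d)
  cc <- sum(f * f) - r^2
  if (a == 0) return(0L)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0L)  # miss or tangency: no sign change
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  sum(c(t1, t2) > 0 & c(t1, t2) < 1)
}

# analytic Sholl profile over all parent-child edges
oracle_sholl <- function(tree, center, radii) {
  pos <- match(tree$parent, tree$id)
  has <- which(!is.na(pos))
  counts <- integer(length(radii))
  for (i in has) {
    p0 <- c(tree$x[pos[i]], tree$y[pos[i]], tree$z[pos[i]])
    p1 <- c(tree$x[i], tree$y[i], tree$z[i])
    for (j in seq_along(radii))
      counts[j] <- counts[j] + segment_sphere_crossings(p0, p1, center, radii[j])
  }
  counts
}

# random swc-like tree with branches radiating from a root, for Sholl tests
random_sholl_tree <- function(n_branches, n_nodes_per_branch = 6,
                              reach = 100) {
  rows <- list(data.frame(id = 1L, stype = 1L, x = 0, y = 0, z = 0,
                          radius = 1, parent = -1L))
  nid <- 1L
  for (b in seq_len(n_branches)) {
    parent <- 1L
    p <- c(0, 0, 0)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    for (k in seq_len(n_nodes_per_branch)) {
      dir <- dir + rnorm(3, 0, 0.3)
      dir <- dir / sqrt(sum(dir^2))
      p <- p + dir * runif(1, 0.3, 1) * reach / n_nodes_per_branch
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <- data.frame(id = nid, stype = 3L,
                                              x = p[1], y = p[2], z = p[3],
                                              radius = 1, parent = parent)
      parent <- nid
    }
  }
  swc_tree(do.call(rbind, rows))
}

# star tree with a given branch count (root + that many 1-edge chains)
star_tree <- function(n_branches, arm = 10) {
  ang <- 2 * pi * seq_len(n_branches) / n_branches
  swc_tree(data.frame(
    id = c(1L, seq_len(n_branches) + 1L),
    stype = c(1L, rep(3L, n_branches)),
    x = c(0, arm * cos(ang)), y = c(0, arm * sin(ang)), z = 0,
    radius = 1, parent = c(-1L, rep(1L, n_branches))))
}
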