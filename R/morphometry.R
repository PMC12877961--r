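# Morphometric readouts on SWC trees: branch decomposition, lengths by
# structure type, 3D Sholl profiles, and raw-versus-revised comparison.

#' Decompose a tree into branches
#'
#' A branch is a maximal path between consecutive critical nodes, where the
#' critical nodes are the root, every bifurcation/multifurcation (>= 2
#' children) and every tip (0 children). For a root of degree 1 with `b`
#' binary bifurcations the branch count is `2b + 1`. This convention is
#' stated explicitly in all outputs because different tools count branches
#' differently.
#'
#' @param tree an [swc_tree()].
#' @return List of integer vectors of node ids, each a path from a critical
#'   node to its critical descendant (both included).
#' @export
branch_segments <- function(tree) {
  stopifnot(inherits(tree, "swc_tree"))
  n <- nrow(tree)
  pos <- swc_parent_pos(tree)
  nch <- tabulate(pos[!is.na(pos)], nbins = n)
  is_root <- is.na(pos)
  critical <- is_root | nch != 1L
  children <- split(seq_len(n)[!is.na(pos)], pos[!is.na(pos)])
  out <- list()
  for (a in which(critical)) {
    for (ch0 in children[[as.character(a)]]) {
      chain <- c(a, ch0)
      v <- ch0
      while (!critical[v]) {
        v <- children[[as.character(v)]][1]
        chain <- c(chain, v)
      }
      out[[length(out) + 1L]] <- tree$id[chain]
    }
  }
  out
}

edge_lengths <- function(tree) {
  pos <- swc_parent_pos(tree)
  has <- !is.na(pos)
  len <- rep(0, nrow(tree))
  len[has] <- sqrt((tree$x[has] - tree$x[pos[has]])^2 +
                   (tree$y[has] - tree$y[pos[has]])^2 +
                   (tree$z[has] - tree$z[pos[has]])^2)
  len
}

#' Total cable length of a tree
#'
#' Sum of Euclidean parent-child distances in um; the root contributes no
#' edge.
#'
#' @param tree an [swc_tree()].
#' @return Length in um.
#' @export
total_length <- function(tree) {
  stopifnot(inherits(tree, "swc_tree"))
  sum(edge_lengths(tree))
}

#' Cable length by structure type
#'
#' Each parent-child edge is attributed to the child's structure type.
#'
#' @param tree an [swc_tree()].
#' @param stype optional single structure type; if given, returns that
#'   type's length as a scalar.
#' @return Named numeric vector of lengths (um) per stype present, or a
#'   scalar if `stype` is given.
#' @export
length_by_type <- function(tree, stype = NULL) {
  stopifnot(inherits(tree, "swc_tree"))
  len <- edge_lengths(tree)
  pos <- swc_parent_pos(tree)
  has <- !is.na(pos)
  agg <- tapply(len[has], tree$stype[has], sum)
  out <- setNames(as.numeric(agg), names(agg))
  if (!is.null(stype)) {
    s <- as.character(stype)
    return(if (s %in% names(out)) out[[s]] else 0)
  }
  out
}

#' Per-branch length distribution
#'
#' @param tree an [swc_tree()].
#' @return Numeric vector, one arc length (um) per branch, in
#'   [branch_segments()] order; sums to [total_length()].
#' @export
branch_length_distribution <- function(tree) {
  stopifnot(inherits(tree, "swc_tree"))
  len <- edge_lengths(tree)
  rowpos <- seq_len(nrow(tree))
  names(rowpos) <- tree$id
  vapply(branch_segments(tree), function(ids) {
    rows <- rowpos[as.character(ids)]
    sum(len[rows[-1]])  # edge above each node except the branch's start
  }, numeric(1))
}

#' Retype a subtree
#'
#' Sets the structure type of a node and all its descendants, e.g. to mark
#' an identified axon (stype 2) so `length_by_type` reports axonal length
#' separately. Typing is manual: there is no reliable automatic
#' axon/dendrite classifier for this material.
#'
#' @param tree an [swc_tree()].
#' @param node_id id of the subtree root.
#' @param stype new structure type.
#' @return The retyped [swc_tree()].
#' @export
retype_subtree <- function(tree, node_id, stype) {
  stopifnot(inherits(tree, "swc_tree"))
  if (!node_id %in% tree$id) stop("unknown node id: ", node_id)
  pos <- swc_parent_pos(tree)
  n <- nrow(tree)
  children <- split(seq_len(n)[!is.na(pos)], pos[!is.na(pos)])
  sel <- logical(n)
  queue <- which(tree$id == node_id)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    sel[v] <- TRUE
    queue <- c(queue, children[[as.character(v)]])
  }
  tree$stype[sel] <- as.integer(stype)
  tree
}

#' 3D Sholl profile
#'
#' Counts intersections of the neurite tree with concentric spheres centered
#' on the soma: each parent-child edge is resampled at <= 1 um steps and an
#' intersection at radius `r` is a sign change of
#' `distance-to-center - r` along the resampled polyline (points exactly on
#' a sphere count with the outgoing step only). Sampling-based counting
#' avoids quadratic root-finding; the resolution is well below any
#' morphological feature of interest.
#'
#' @param tree an [swc_tree()].
#' @param center physical `(x, y, z)` of the soma in um; defaults to the
#'   root node.
#' @param radii strictly increasing sphere radii in um; defaults to 10 um
#'   steps from 10 um out to the farthest tip.
#' @param step resampling step in um (default 1).
#' @return An object of class `"sholl_profile"`: data frame with columns
#'   `radius`, `crossings`, plus attribute `center`.
#' @export
sholl_profile <- function(tree, center = NULL, radii = NULL, step = 1) {
  stopifnot(inherits(tree, "swc_tree"))
  if (is.null(center)) {
    root <- which(tree$parent == -1L)
    center <- c(tree$x[root], tree$y[root], tree$z[root])
  }
  if (is.null(radii)) {
    dmax <- sqrt(max((tree$x - center[1])^2 + (tree$y - center[2])^2 +
                     (tree$z - center[3])^2))
    radii <- seq(10, max(10, ceiling(dmax / 10) * 10), by = 10)
  }
  if (length(radii) == 0L || is.unsorted(radii, strictly = TRUE))
    stop("radii must be nonempty and strictly increasing")
  counts <- numeric(length(radii))
  rowpos <- seq_len(nrow(tree))
  names(rowpos) <- tree$id
  # process whole branch polylines so a crossing landing exactly on an
  # interior node is still seen by the outgoing step
  for (ids in branch_segments(tree)) {
    rows <- rowpos[as.character(ids)]
    poly <- cbind(tree$x[rows], tree$y[rows], tree$z[rows])
    pts <- poly[1, , drop = FALSE]
    for (e in seq_len(nrow(poly) - 1L)) {
      a <- poly[e, ]; b <- poly[e + 1L, ]
      L <- sqrt(sum((b - a)^2))
      k <- max(1L, ceiling(L / step))
      t <- seq(0, 1, length.out = k + 1L)[-1]
      pts <- rbind(pts, outer(t, b - a) + matrix(a, k, 3, byrow = TRUE))
    }
    d <- sqrt(rowSums((pts - matrix(center, nrow(pts), 3, byrow = TRUE))^2))
    for (j in seq_along(radii)) {
      counts[j] <- counts[j] + count_sign_changes(d - radii[j])
    }
  }
  out <- data.frame(radius = radii, crossings = as.integer(counts))
  attr(out, "center") <- center
  class(out) <- c("sholl_profile", "data.frame")
  out
}

# sign changes with zeros attributed to the outgoing step: each zero takes
# the sign of the next nonzero value; trailing zeros drop out
count_sign_changes <- function(f) {
  s <- sign(f)
  nz <- s != 0
  if (!any(nz)) return(0L)
  # propagate the next nonzero sign backwards onto zeros
  filled <- rev(cummaxfill(rev(s)))
  filled <- filled[filled != 0]
  sum(diff(filled) != 0)
}

# carry the last nonzero value forward (helper for outgoing-step convention)
cummaxfill <- function(s) {
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] != 0) last <- s[i] else s[i] <- last
  }
  s
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::plot(x$radius, x$crossings, type = "b", pch = 19,
                 xlab = "radius from soma (um)", ylab = "intersections", ...)
  invisible(x)
}

#' Full morphometry report for one tree
#'
#' @param tree an [swc_tree()].
#' @param sholl_radii passed to [sholl_profile()] (default 10 um steps).
#' @return An object of class `"morphometry_report"`: list with
#'   `branch_count`, `total_length`, `length_by_type`, `branch_lengths`,
#'   `sholl`.
#' @export
morphometry_report <- function(tree, sholl_radii = NULL) {
  stopifnot(inherits(tree, "swc_tree"))
  bl <- branch_length_distribution(tree)
  structure(list(branch_count = length(bl),
                 total_length = total_length(tree),
                 length_by_type = length_by_type(tree),
                 branch_lengths = bl,
                 sholl = sholl_profile(tree, radii = sholl_radii)),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %d branches, total %.2f um\n",
              x$branch_count, x$total_length))
  invisible(x)
}

#' Percent and fold change between two metric values
#'
#' The comparison arithmetic used throughout: percent change is
#' `100 * (revised - raw) / raw` rounded to the nearest integer, fold change
#' is `revised / raw` rounded to one decimal. A zero raw value makes the
#' percent change undefined (`NA`); the fold change is reported alone.
#'
#' @param raw,revised scalar metric values.
#' @return List with `percent_change` and `fold_change`.
#' @export
metric_change <- function(raw, revised) {
  if (!is.finite(raw) || !is.finite(revised)) stop("metric values must be finite")
  if (raw > 0) {
    list(percent_change = round(100 * (revised - raw) / raw),
         fold_change = round(revised / raw, 1))
  } else {
    list(percent_change = NA_real_, fold_change = NA_real_)
  }
}

#' Compare raw and revised reconstructions
#'
#' Computes full morphometry for both trees plus percent and fold changes
#' for branch count, total length and every structure-type length (see
#' [metric_change()] for the rounding conventions).
#'
#' @param raw_tree,revised_tree [swc_tree()] objects for the raw and
#'   repaired reconstruction of the same neuron.
#' @param sholl_radii common Sholl radii (default: 10 um steps covering the
#'   larger tree).
#' @return An object of class `"comparison_report"`: list with `raw`,
#'   `revised` ([morphometry_report()]s) and `changes` (data frame: metric,
#'   raw, revised, percent_change, fold_change).
#' @export
compare_morphometry <- function(raw_tree, revised_tree, sholl_radii = NULL) {
  stopifnot(inherits(raw_tree, "swc_tree"), inherits(revised_tree, "swc_tree"))
  if (is.null(sholl_radii)) {
    dmax <- function(tr) {
      root <- which(tr$parent == -1L)
      sqrt(max((tr$x - tr$x[root])^2 + (tr$y - tr$y[root])^2 +
               (tr$z - tr$z[root])^2))
    }
    top <- max(dmax(raw_tree), dmax(revised_tree), 10)
    sholl_radii <- seq(10, max(10, ceiling(top / 10) * 10), by = 10)
  }
  raw_rep <- morphometry_report(raw_tree, sholl_radii)
  rev_rep <- morphometry_report(revised_tree, sholl_radii)
  types <- sort(unique(c(names(raw_rep$length_by_type),
                         names(rev_rep$length_by_type))))
  metrics <- c("branch_count", "total_length",
               paste0("length_stype_", types))
  raw_vals <- c(raw_rep$branch_count, raw_rep$total_length,
                vapply(types, function(s) length_by_type(raw_tree, s), numeric(1)))
  rev_vals <- c(rev_rep$branch_count, rev_rep$total_length,
                vapply(types, function(s) length_by_type(revised_tree, s),
                       numeric(1)))
  ch <- mapply(metric_change, raw_vals, rev_vals, SIMPLIFY = FALSE)
  changes <- data.frame(metric = metrics, raw = raw_vals, revised = rev_vals,
                        percent_change = vapply(ch, `[[`, numeric(1),
                                                "percent_change"),
                        fold_change = vapply(ch, `[[`, numeric(1),
                                             "fold_change"),
                        row.names = NULL)
  structure(list(raw = raw_rep, revised = rev_rep, changes = changes,
                 sholl_radii = sholl_radii),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Raw vs revised morphometry (branches: maximal paths between\n")
  cat("critical nodes - root, bifurcations, tips):\n")
  df <- x$changes
  for (i in seq_len(nrow(df))) {
    pc <- if (is.na(df$percent_change[i])) "undefined (raw = 0)"
          else sprintf("%+d%%", as.integer(df$percent_change[i]))
    fc <- if (is.na(df$fold_change[i])) "" else sprintf(", %.1f-fold",
                                                        df$fold_change[i])
    cat(sprintf("  %-16s %10.4g -> %10.4g  (%s%s)\n", df$metric[i],
                df$raw[i], df$revised[i], pc, fc))
  }
  invisible(x)
}
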