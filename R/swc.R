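#' SWC neuron trees
#'
#' An SWC tree is stored as a data frame with the standard seven columns:
#' `id` (positive integer), `stype` (structure type: 1 soma, 2 axon, 3 basal
#' dendrite, 4 apical dendrite), `x`, `y`, `z` (um), `radius` (um), and
#' `parent` (`id` of the parent node, or -1 for the single root). The
#' constructor validates the structural invariants: unique ids, exactly one
#' root, all parents present, connected and acyclic, non-negative radii.
#'
#' @param nodes data frame with columns `id, stype, x, y, z, radius, parent`.
#' @return The validated data frame with class `c("swc_tree", "data.frame")`.
#' @export
swc_tree <- function(nodes) {
  need <- c("id", "stype", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) stop("SWC table needs columns: ",
                                         paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes)[need]
  nodes$id <- as.integer(nodes$id)
  nodes$stype <- as.integer(nodes$stype)
  nodes$parent <- as.integer(nodes$parent)
  validate_swc(nodes)
  class(nodes) <- c("swc_tree", "data.frame")
  nodes
}

validate_swc <- function(nodes) {
  if (nrow(nodes) == 0L) stop("SWC tree has no nodes")
  if (any(nodes$id <= 0L)) stop("SWC ids must be positive integers")
  if (anyDuplicated(nodes$id))
    stop("duplicate SWC id: ", nodes$id[duplicated(nodes$id)][1])
  if (any(nodes$radius < 0)) stop("SWC radius must be >= 0")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L)
    stop("SWC tree must have exactly one root (parent = -1), found ",
         length(roots))
  pos <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & is.na(pos))
  if (length(bad))
    stop("SWC record id ", nodes$id[bad[1]], " references missing parent ",
         nodes$parent[bad[1]])
  # cycle / connectivity check: every node must reach the root
  n <- nrow(nodes)
  state <- integer(n)  # 0 unvisited, 1 on path, 2 done
  root <- roots[1]
  state[root] <- 2L
  for (i in seq_len(n)) {
    if (state[i] == 2L) next
    path <- integer(0)
    j <- i
    while (state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- pos[j]
      if (is.na(j)) stop("internal SWC validation error")
      if (state[j] == 1L)
        stop("SWC tree contains a cycle through record id ", nodes$id[j])
    }
    state[path] <- 2L
  }
  invisible(nodes)
}

#' Read an SWC file
#'
#' Whitespace-delimited seven-column records with `#` comment lines, the
#' standard interchange format for neuron morphologies. Structural
#' invariants (single root, parents present, acyclic) are enforced on read;
#' violations are errors naming the offending record.
#'
#' @param path SWC file path.
#' @return An [swc_tree()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file does not exist: ", path)
  tab <- tryCatch(
    read.table(path, comment.char = "#",
               col.names = c("id", "stype", "x", "y", "z", "radius", "parent"),
               colClasses = c("integer", "integer", "numeric", "numeric",
                              "numeric", "numeric", "integer")),
    error = function(e) stop("malformed SWC file ", path, ": ",
                             conditionMessage(e)))
  swc_tree(tab)
}

#' Write an SWC file
#'
#' Coordinates and radii are written with four decimal places, so a
#' write/read round-trip preserves all fields to 1e-4 um.
#'
#' @param tree an [swc_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "swc_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id stype x y z radius parent", con)
  writeLines(sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                     tree$id, tree$stype, tree$x, tree$y, tree$z,
                     tree$radius, tree$parent), con)
  invisible(path)
}

#' @export
print.swc_tree <- function(x, ...) {
  cat(sprintf("<swc_tree> %d nodes, %d branches, total length %.2f um\n",
              nrow(x), length(branch_segments(x)), total_length(x)))
  invisible(x)
}

#' @export
summary.swc_tree <- function(object, ...) {
  lens <- branch_length_distribution(object)
  by_type <- length_by_type(object)
  out <- list(n_nodes = nrow(object), branch_count = length(lens),
              total_length = total_length(object), branch_lengths = lens,
              length_by_type = by_type)
  class(out) <- "summary.swc_tree"
  out
}

#' @export
print.summary.swc_tree <- function(x, ...) {
  cat(sprintf("SWC tree: %d nodes, %d branches\n", x$n_nodes, x$branch_count))
  cat(sprintf("Total length: %.2f um\n", x$total_length))
  tn <- c(`1` = "soma", `2` = "axon", `3` = "basal dendrite",
          `4` = "apical dendrite")
  for (s in names(x$length_by_type)) {
    nm <- if (s %in% names(tn)) tn[[s]] else paste("type", s)
    cat(sprintf("  %-16s %.2f um\n", nm, x$length_by_type[[s]]))
  }
  if (x$branch_count > 0)
    cat(sprintf("Branch lengths: min %.2f, median %.2f, max %.2f um\n",
                min(x$branch_lengths), stats::median(x$branch_lengths),
                max(x$branch_lengths)))
  invisible(x)
}

#' Plot an SWC tree as a 2D projection
#'
#' @param x an [swc_tree()].
#' @param plane `"xy"`, `"xz"` or `"yz"` projection plane.
#' @param ... passed to [graphics::plot()].
#' @export
plot.swc_tree <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  p <- match(x$parent, x$id)
  has_edge <- !is.na(p)
  graphics::plot(x[[ax[1]]], x[[ax[2]]], asp = 1, pch = ".",
                 xlab = paste(ax[1], "(um)"), ylab = paste(ax[2], "(um)"), ...)
  graphics::segments(x[[ax[1]]][has_edge], x[[ax[2]]][has_edge],
                     x[[ax[1]]][p[has_edge]], x[[ax[2]]][p[has_edge]])
  root <- which(x$parent == -1L)
  graphics::points(x[[ax[1]]][root], x[[ax[2]]][root], pch = 19, col = "red")
  invisible(x)
}

# parent row positions (NA for root); used across morphometry
swc_parent_pos <- function(tree) match(tree$parent, tree$id)
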