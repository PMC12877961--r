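#' Marker sets: the semi-automation interface
#'
#' Markers carry the manual annotations the pipeline needs: one `soma_seed`
#' per single-neuron task, any number of `branch_terminal` points placed at
#' the far ends of interrupted branches, and optional eraser regions
#' (`eraser_sphere` with a radius, `eraser_box` with a cubic half-extent)
#' used to delete interfering structures. Positions are physical `(x, y, z)`
#' in um.
#'
#' @param df data frame with columns `x, y, z, kind` and optional `param`
#'   (sphere radius / box half-extent in um, required for erasers).
#' @return The validated data frame with class `c("marker_set", "data.frame")`.
#' @export
marker_set <- function(df) {
  need <- c("x", "y", "z", "kind")
  if (!all(need %in% names(df))) stop("marker table needs columns x, y, z, kind")
  df <- as.data.frame(df)
  if (!"param" %in% names(df)) df$param <- NA_real_
  df$param <- as.numeric(df$param)
  df <- df[c("x", "y", "z", "kind", "param")]
  df$kind <- as.character(df$kind)
  known <- c("soma_seed", "branch_terminal", "eraser_sphere", "eraser_box")
  bad <- setdiff(unique(df$kind), known)
  if (length(bad)) stop("unknown marker kind: ", paste(bad, collapse = ", "))
  er <- df$kind %in% c("eraser_sphere", "eraser_box")
  if (any(er & (is.na(df$param) | df$param <= 0)))
    stop("eraser markers require a positive param (radius / half-extent in um)")
  class(df) <- c("marker_set", "data.frame")
  df
}

#' Read markers from CSV
#'
#' Expects a header `x,y,z,kind[,param]`. Unknown kinds are rejected. When
#' `require_soma = TRUE` (the single-neuron task contract) the file must
#' contain exactly one `soma_seed` row.
#'
#' @param path CSV file path.
#' @param require_soma enforce exactly one soma seed.
#' @return A [marker_set()].
#' @export
read_markers <- function(path, require_soma = FALSE) {
  if (!file.exists(path)) stop("marker file does not exist: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- marker_set(df)
  if (require_soma) {
    ns <- sum(m$kind == "soma_seed")
    if (ns != 1L)
      stop("marker file ", path, " must contain exactly one soma_seed, found ", ns)
  }
  m
}

#' Write markers to CSV
#'
#' @param markers a [marker_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  write.csv(as.data.frame(markers), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract the soma seed / branch-terminal positions from a marker set
#'
#' @param markers a [marker_set()].
#' @return `soma_position`: the `(x, y, z)` of the single soma seed;
#'   `terminal_positions`: matrix (n x 3) of branch-terminal positions.
#' @export
soma_position <- function(markers) {
  s <- markers[markers$kind == "soma_seed", , drop = FALSE]
  if (nrow(s) != 1L)
    stop("marker set must contain exactly one soma_seed, found ", nrow(s))
  c(x = s$x[1], y = s$y[1], z = s$z[1])
}

#' @rdname soma_position
#' @export
terminal_positions <- function(markers) {
  t <- markers[markers$kind == "branch_terminal", , drop = FALSE]
  as.matrix(t[, c("x", "y", "z"), drop = FALSE])
}
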