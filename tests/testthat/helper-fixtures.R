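# Shared fixtures: small tube volumes and trees built in code.

# constant-intensity volume
flat_volume <- function(value, dims = c(4, 4, 4), spacing = c(1, 1, 1),
                        bit_depth = 8L) {
  volume3d(array(value, dims), spacing, bit_depth = bit_depth)
}

# straight bright tube along +x at fixed y/z, in a dark background
straight_tube_volume <- function(length_um = 100, radius = 2,
                                 spacing = c(2.5, 1, 1),
                                 neurite = 240, background = 120) {
  dims <- c(17, 21, ceiling((length_um + 20) / spacing[3]))
  y0 <- 10 * spacing[2]
  z0 <- 8 * spacing[1]
  x0 <- 8
  tr <- swc_tree(data.frame(id = 1:2, stype = c(1L, 3L),
                            x = c(x0, x0 + length_um), y = y0, z = z0,
                            radius = radius, parent = c(-1L, 1L)))
  spec <- phantom_spec(shape = dims, spacing = spacing,
                       neurite_mean = neurite, background_mean = background,
                       noise_sd = 0)
  list(volume = voxelize_tree(tr, spec), tree = tr,
       start = c(x0, y0, z0), end = c(x0 + length_um, y0, z0))
}

# Y-shaped tube: stem along +x then two arms at +-45 degrees in the xy plane
y_tube_volume <- function(stem = 50, arm = 50, radius = 2,
                          spacing = c(2.5, 1, 1)) {
  p0 <- c(10, 60, 20)
  p1 <- p0 + c(stem, 0, 0)
  pa <- p1 + arm * c(cos(pi / 4), sin(pi / 4), 0)
  pb <- p1 + arm * c(cos(pi / 4), -sin(pi / 4), 0)
  tr <- swc_tree(data.frame(
    id = 1:4, stype = c(1L, 3L, 3L, 3L),
    x = c(p0[1], p1[1], pa[1], pb[1]),
    y = c(p0[2], p1[2], pa[2], pb[2]),
    z = p0[3], radius = radius, parent = c(-1L, 1L, 2L, 2L)))
  dims <- c(17, 121, 121)
  spec <- phantom_spec(shape = dims, spacing = spacing, noise_sd = 0)
  list(volume = voxelize_tree(tr, spec), tree = tr, soma = p0,
       junction = p1, tips = rbind(pa, pb))
}

# small, fast phantom spec for pipeline-level tests
small_phantom_spec <- function(seed = 7, n_bifurcations = 2L,
                               segment_length = c(20, 32), ...) {
  phantom_spec(shape = c(32L, 128L, 128L), n_bifurcations = n_bifurcations,
               segment_length = segment_length, seed = seed, ...)
}

# unbranched 11-node straight SWC path, 10 um steps
chain_tree <- function(n = 11, step = 10) {
  swc_tree(data.frame(id = seq_len(n), stype = c(1L, rep(3L, n - 1)),
                      x = (seq_len(n) - 1) * step, y = 0, z = 0,
                      radius = 1, parent = c(-1L, seq_len(n - 1))))
}

# simple Y SWC tree: stem 50, arms 50 each (3 branches, 1 bifurcation)
y_tree <- function() {
  swc_tree(data.frame(
    id = 1:4, stype = c(1L, 3L, 3L, 3L),
    x = c(0, 50, 50 + 50 * cos(pi / 4), 50 + 50 * cos(pi / 4)),
    y = c(0, 0, 50 * sin(pi / 4), -50 * sin(pi / 4)),
    z = 0, radius = 1, parent = c(-1L, 1L, 2L, 2L)))
}
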