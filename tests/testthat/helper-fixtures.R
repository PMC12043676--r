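# shared fixtures: small grids, analytic kernels, cheap axon contexts

uniform_grid <- function(dims, tissue = "muscle", spacing = 1) {
  lab <- array(tissue_codes()[[tissue]], dim = dims)
  voxel_grid(lab, spacing_mm = spacing)
}

lin_idx <- function(g, i, j, k) {
  as.integer(i + g$shape[1] * (j - 1) + prod(g$shape[1:2]) * (k - 1))
}

# whole-layer Dirichlet plates normal to an axis
plate_idx <- function(g, axis, layer) {
  ijk <- which(slice.index(g$label, axis) == layer)
  as.integer(ijk)
}

# wrap an analytically sampled potential so field/AF operators accept it
fake_potential <- function(phi, grid, current_mA = 1) {
  structure(list(phi = phi, grid = grid, dirichlet = NULL,
                 relres = 0, iterations = 0L, current_mA = current_mA),
            class = "potential_field")
}

# cell-centre coordinate arrays of a grid
grid_coord_arrays <- function(g) {
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 0.5) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$shape[2]) - 0.5) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(g$shape[3]) - 0.5) * g$spacing[3]
  list(x = array(rep(xs, times = prod(g$shape[2:3])), g$shape),
       y = array(rep(rep(ys, each = g$shape[1]), g$shape[3]), g$shape),
       z = array(rep(zs, each = prod(g$shape[1:2])), g$shape))
}

# point-source drive (mV per mA) for an axon at distance d_mm from the fibre
point_source_drive <- function(axon, d_mm = 2, sigma = 0.35) {
  x <- axon$position_mm - mean(range(axon$position_mm))
  1e-3 / (4 * pi * sigma * (sqrt(x^2 + d_mm^2) * 1e-3)) * 1000
}

# small axon shared across protocol tests (51 nodes keeps titration ~s-scale)
test_axon <- local({
  ax <- NULL
  function(n_nodes = 51, ...) {
    if (is.null(ax)) ax <<- build_axon(5.7, n_nodes = n_nodes)
    ax
  }
})

# coarse but complete phantom config for pipeline tests
coarse_config <- function() {
  cfg <- default_config()
  cfg$phantom$radius_mm <- 20
  cfg$phantom$length_mm <- 60
  cfg$phantom$layers <- list(skin = 1.5, sat = 3.5, muscle = 7)
  cfg$nerves <- list(median = 5.5)
  cfg$pulses$widths_us <- c(30, 146, 495)
  cfg$axon$n_nodes <- 21
  cfg$solver$tol <- 1e-7
  cfg
}
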