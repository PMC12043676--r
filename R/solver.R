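#' Solve the Ohmic quasi-static potential on a voxel grid
#'
#' Solves `div(sigma grad phi) = 0` with Dirichlet voltages on electrode node
#' sets and insulating (zero normal current) outer boundaries, using a
#' 7-point finite-difference discretization with harmonic-mean face
#' conductivities and Jacobi-preconditioned conjugate gradients. Air voxels
#' are excluded from the system.
#'
#' @param grid a `voxel_grid`. If `dirichlet` is `NULL` the grid must carry a
#'   placed electrode montage (see [place_electrodes()]), whose Dirichlet node
#'   sets receive `+voltage` (anode) and `-voltage` (cathode).
#' @param dirichlet optional list of node sets, each
#'   `list(idx = <linear voxel indices>, value = <volts>)`.
#' @param voltage electrode voltage magnitude (V) when using the montage.
#' @param tol relative residual tolerance of the linear solve.
#' @param maxit iteration cap; non-convergence is an error.
#' @return object of class `potential_field`: `phi` (V, grid-shaped array),
#'   the grid, the Dirichlet sets, solver diagnostics, and the current
#'   scaling context (`current_mA`, anode current, when a montage is present).
#' @export
solve_potential <- function(grid, dirichlet = NULL, voltage = 1,
                            tol = 1e-8, maxit = 50000L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dirichlet)) {
    if (is.null(grid$electrodes)) stop("no Dirichlet sets: place electrodes or pass `dirichlet`")
    dirichlet <- list(
      anode = list(idx = grid$electrodes$anode$dirichlet, value = voltage),
      cathode = list(idx = grid$electrodes$cathode$dirichlet, value = -voltage))
  }
  idx <- unlist(lapply(dirichlet, `[[`, "idx"), use.names = FALSE)
  val <- unlist(lapply(dirichlet, function(d) rep(d$value, length(d$idx))), use.names = FALSE)
  if (anyDuplicated(idx)) stop("Dirichlet node sets overlap")
  sol <- .cpp_solve_potential(grid$sigma, as.integer(grid$shape), grid$spacing,
                              as.integer(idx), as.numeric(val), tol, as.integer(maxit))
  if (!sol$converged)
    stop(sprintf("linear solve did not converge: relative residual %.3g after %d iterations",
                 sol$relres, sol$iterations))
  pf <- structure(list(phi = sol$phi, grid = grid, dirichlet = dirichlet,
                       relres = sol$relres, iterations = sol$iterations,
                       current_mA = NA_real_), class = "potential_field")
  cr <- try(electrode_current(pf), silent = TRUE)
  if (!inherits(cr, "try-error")) pf$current_mA <- cr$anode_mA
  pf
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> phi in [%.4g, %.4g] V, relres %.2g (%d CG iterations)",
              min(x$phi), max(x$phi), x$relres, x$iterations))
  if (is.finite(x$current_mA)) cat(sprintf(", electrode current %.4g mA", x$current_mA))
  cat("\n")
  invisible(x)
}

#' Electrode current report
#'
#' Sums `sigma * dphi/dn * face area` over each electrode node set's contact
#' faces. For a converged solve the anode and cathode currents balance.
#'
#' @param potential a solved `potential_field` with at least two Dirichlet
#'   node sets (the first is reported as anode, the second as cathode).
#' @return list with `anode_mA`, `cathode_mA` and relative `imbalance`.
#' @export
electrode_current <- function(potential) {
  stopifnot(inherits(potential, "potential_field"))
  d <- potential$dirichlet
  if (length(d) < 2) stop("need two Dirichlet node sets to report a current")
  g <- potential$grid
  ia <- .cpp_set_current(potential$phi, g$sigma, as.integer(g$shape), g$spacing,
                         as.integer(d[[1]]$idx)) * 1e3
  ic <- .cpp_set_current(potential$phi, g$sigma, as.integer(g$shape), g$spacing,
                         as.integer(d[[2]]$idx)) * 1e3
  list(anode_mA = ia, cathode_mA = ic, imbalance = abs(ia + ic) / abs(ia))
}

#' Rescale a solved potential to a target electrode current
#'
#' The quasi-static problem is linear, so one unit solve per montage is
#' rescaled to any injected current without re-solving.
#'
#' @param potential a solved `potential_field`.
#' @param target_mA desired anode current, mA.
#' @return a `potential_field` scaled so the electrode current is `target_mA`.
#' @export
scale_to_current <- function(potential, target_mA) {
  cur <- electrode_current(potential)
  if (!is.finite(cur$anode_mA) || cur$anode_mA == 0) stop("input potential carries zero current")
  f <- target_mA / cur$anode_mA
  potential$phi <- potential$phi * f
  potential$dirichlet <- lapply(potential$dirichlet, function(d) {
    d$value <- d$value * f; d
  })
  potential$current_mA <- target_mA
  potential
}

# one-axis derivative of a grid array restricted to the conductive mask:
# central where both neighbours are conductive, one-sided otherwise, 0 if no
# conductive neighbour.
.masked_gradient_axis <- function(arr, mask, axis, spacing) {
  dm <- dim(arr)
  n <- dm[axis]
  idx_all <- function(shift) {
    ii <- lapply(dm, seq_len)
    ii[[axis]] <- pmin(pmax(ii[[axis]] + shift, 1L), n)
    ii
  }
  slice_shift <- function(x, shift) {
    # value of x at index + shift along `axis`, clamped (clamp handled by valid mask)
    ii <- idx_all(shift)
    do.call(`[`, c(list(x), ii, list(drop = FALSE)))
  }
  inb <- function(shift) {
    ii <- array(rep(seq_len(n), each = prod(dm[seq_len(axis - 1)])), dim = dm)
    ii + shift >= 1 & ii + shift <= n
  }
  vp <- slice_shift(arr, 1L); vm <- slice_shift(arr, -1L)
  mp <- slice_shift(mask, 1L) & inb(1L)
  mm <- slice_shift(mask, -1L) & inb(-1L)
  d <- array(0, dim = dm)
  both <- mp & mm
  d[both] <- (vp[both] - vm[both]) / (2 * spacing)
  onlyp <- mp & !mm
  d[onlyp] <- (vp[onlyp] - arr[onlyp]) / spacing
  onlym <- mm & !mp
  d[onlym] <- (arr[onlym] - vm[onlym]) / spacing
  d[!mask] <- 0
  d
}

#' Electric field from a solved potential
#'
#' `E = -grad(phi)` by central differences in the interior of the conductive
#' domain and one-sided differences against air or the grid boundary. The
#' mm-to-m conversion (factor 1000) is applied here, once: with `phi` in V
#' and spacing in mm the result is in V/m. Air voxels have zero field.
#'
#' @param potential a solved `potential_field`.
#' @return object of class `efield_map` with components `Ex`, `Ey`, `Ez` and
#'   `magnitude` (V/m).
#' @export
electric_field <- function(potential) {
  stopifnot(inherits(potential, "potential_field"))
  g <- potential$grid
  mask <- g$sigma > 0
  E <- lapply(1:3, function(ax)
    -1000 * .masked_gradient_axis(potential$phi, mask, ax, g$spacing[ax]))
  mag <- sqrt(E[[1]]^2 + E[[2]]^2 + E[[3]]^2)
  structure(list(Ex = E[[1]], Ey = E[[2]], Ez = E[[3]], magnitude = mag,
                 grid = g, current_mA = potential$current_mA),
            class = "efield_map")
}
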