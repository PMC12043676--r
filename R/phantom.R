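#' Construct a voxel grid from a label array
#'
#' Cell-centered regular grid; voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 0.5) * spacing`. Axis order is x (across the arm),
#' y (depth, skin at +y), z (along the arm). Conductivity is derived from the
#' label array through the tissue table, so label/conductivity consistency
#' holds by construction.
#'
#' @param label integer 3-D array of tissue codes (see [tissue_codes()]).
#' @param spacing_mm numeric length 3 (or 1, recycled), voxel edge in mm.
#' @param origin_mm numeric length 3, position of the grid corner in mm.
#' @param tissues named conductivity table, see [tissue_table()].
#' @param meta optional list of phantom metadata (radius, layers, ...).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(label, spacing_mm = 1, origin_mm = c(0, 0, 0),
                       tissues = tissue_table(), meta = list()) {
  stopifnot(length(dim(label)) == 3)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0 on all axes")
  codes <- setNames(seq_along(tissues) - 1L, names(tissues))
  if (!all(unique(as.vector(label)) %in% codes))
    stop("label array contains codes without a tissue table entry")
  sigma_by_code <- as.numeric(tissues)          # code k -> tissues[k + 1]
  sigma <- array(sigma_by_code[as.vector(label) + 1L], dim = dim(label))
  structure(list(
    shape = dim(label), spacing = spacing_mm, origin = as.numeric(origin_mm),
    label = label, sigma = sigma, tissues = tissues, codes = codes,
    electrodes = NULL, meta = meta
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  tb <- table(names(x$codes)[x$label + 1L])
  cat("  tissues:", paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# cell-centre coordinates along one axis (1 = x, 2 = y, 3 = z)
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

# (i, j, k) matrix -> linear index into the grid arrays
grid_lindex <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  ijk[, 1] + grid$shape[1] * (ijk[, 2] - 1L) +
    prod(grid$shape[1:2]) * (ijk[, 3] - 1L)
}

#' Voxel volume in mm^3
#' @param grid a `voxel_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Build the layered cylindrical forearm phantom
#'
#' A concentric-cylinder surrogate for the forearm: the cylinder axis runs
#' along z, the listed layers are stacked from the skin inwards, and the
#' remaining core is filled with `core_tissue`. Voxels outside the cylinder
#' are air. Construction is deterministic.
#'
#' @param radius_mm outer (skin) radius, mm.
#' @param length_mm cylinder length along z, mm.
#' @param spacing_mm voxel spacing (scalar or length 3), mm.
#' @param pad_mm air margin added around the cylinder in x and y (must leave
#'   room for the electrode gel), mm.
#' @param layers named list/vector of layer thicknesses (mm), ordered from
#'   the surface inwards, e.g. `c(skin = 1.5, sat = 3.5, muscle = 15)`.
#' @param core_tissue tissue filling the remaining core.
#' @param tissues conductivity table.
#' @return a `voxel_grid` with phantom metadata in `$meta`.
#' @export
#' @examples
#' g <- build_phantom(radius_mm = 10, length_mm = 10, spacing_mm = 2,
#'                    layers = c(skin = 2), core_tissue = "muscle")
build_phantom <- function(radius_mm = 40, length_mm = 120, spacing_mm = 1,
                          pad_mm = 4, layers = c(skin = 1.5, sat = 3.5, muscle = 15),
                          core_tissue = "cortical_bone", tissues = tissue_table()) {
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  layers <- unlist(layers)
  if (length(layers) && (is.null(names(layers)) || any(!nzchar(names(layers)))))
    stop("layers must be named by tissue")
  if (any(layers <= 0)) stop("layer thicknesses must be positive")
  if (sum(layers) >= radius_mm) stop("layer thicknesses must sum to less than the radius")
  if (length(layers) && max(spacing_mm[1:2]) > min(layers))
    stop("spacing larger than the thinnest layer would erase it")
  codes <- setNames(seq_along(tissues) - 1L, names(tissues))
  for (nm in c(names(layers), core_tissue))
    if (!nm %in% names(codes)) stop("unknown tissue: ", nm)

  half <- radius_mm + pad_mm
  nx <- as.integer(ceiling(2 * half / spacing_mm[1]))
  ny <- as.integer(ceiling(2 * half / spacing_mm[2]))
  nz <- as.integer(round(length_mm / spacing_mm[3]))
  if (abs(nz * spacing_mm[3] - length_mm) > 1e-9)
    stop("spacing must divide the phantom length")
  origin <- c(-nx * spacing_mm[1] / 2, -ny * spacing_mm[2] / 2, 0)

  xc <- origin[1] + (seq_len(nx) - 0.5) * spacing_mm[1]
  yc <- origin[2] + (seq_len(ny) - 0.5) * spacing_mm[2]
  r2d <- sqrt(outer(xc^2, yc^2, `+`))

  # radius bands from the surface inwards
  inner <- radius_mm - cumsum(layers)
  outer_r <- c(radius_mm, inner[-length(inner)])
  lab2d <- matrix(codes[["air"]], nx, ny)
  inside <- r2d <= radius_mm
  lab2d[inside] <- codes[[core_tissue]]
  for (li in rev(seq_along(layers))) {        # inner layers first, surface last
    band <- r2d <= outer_r[li] & r2d > inner[li]
    lab2d[band] <- codes[[names(layers)[li]]]
  }
  label <- array(rep(as.integer(lab2d), nz), dim = c(nx, ny, nz))

  voxel_grid(label, spacing_mm, origin, tissues,
             meta = list(radius_mm = radius_mm, length_mm = length_mm,
                         pad_mm = pad_mm, layers = layers,
                         core_tissue = core_tissue))
}

#' Electrode specification
#'
#' A disc electrode on the upper (+y) skin surface of the phantom: a
#' conductive gel layer topped by an equipotential (Dirichlet) pad surface.
#' The metal pad itself is not meshed.
#'
#' @param x_mm,z_mm centre of the disc footprint, mm.
#' @param radius_mm disc radius, mm (default 3).
#' @param thickness_mm combined gel + pad thickness, mm (default 2).
#' @param polarity `"anode"` or `"cathode"`.
#' @export
electrode_spec <- function(x_mm = 0, z_mm = 0, radius_mm = 3, thickness_mm = 2,
                           polarity = c("anode", "cathode")) {
  polarity <- match.arg(polarity)
  if (radius_mm <= 0) stop("electrode radius must be > 0")
  if (thickness_mm <= 0) stop("electrode thickness must be > 0")
  structure(list(x_mm = x_mm, z_mm = z_mm, radius_mm = radius_mm,
                 thickness_mm = thickness_mm, polarity = polarity),
            class = "electrode_spec")
}

#' Default two-electrode montage
#'
#' Anode and cathode of equal radius, centred over the arm axis (x = 0) and
#' separated along z, mirroring a wrist TENS placement.
#'
#' @param grid phantom `voxel_grid`.
#' @param separation_mm centre-to-centre separation, mm (default 20).
#' @param radius_mm,thickness_mm see [electrode_spec()].
#' @export
default_montage <- function(grid, separation_mm = 20, radius_mm = 3, thickness_mm = 2) {
  zc <- mean(range(axis_centers(grid, 3)))
  list(anode = electrode_spec(0, zc - separation_mm / 2, radius_mm, thickness_mm, "anode"),
       cathode = electrode_spec(0, zc + separation_mm / 2, radius_mm, thickness_mm, "cathode"))
}

#' Place a two-electrode montage on the phantom
#'
#' Fills gel voxels (conductivity from the tissue table entry `gel`) from the
#' local skin surface up to the pad plane, and records the top gel layer of
#' each electrode as its Dirichlet node set.
#'
#' @param grid phantom `voxel_grid`.
#' @param montage list with elements `anode` and `cathode`
#'   ([electrode_spec()]); default wrist montage if `NULL`.
#' @return the grid with gel voxels added and `$electrodes` populated.
#' @export
place_electrodes <- function(grid, montage = NULL) {
  if (is.null(montage)) montage <- default_montage(grid)
  stopifnot(all(c("anode", "cathode") %in% names(montage)))
  a <- montage$anode; c_ <- montage$cathode
  if (sqrt((a$x_mm - c_$x_mm)^2 + (a$z_mm - c_$z_mm)^2) <= a$radius_mm + c_$radius_mm)
    stop("electrodes overlap")
  R <- grid$meta$radius_mm
  if (is.null(R)) R <- max(axis_centers(grid, 2)[apply(grid$sigma > 0, 2, any)])
  xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
  gel_code <- grid$codes[["gel"]]
  air_code <- grid$codes[["air"]]

  place_one <- function(spec) {
    cols <- which(outer((xs - spec$x_mm)^2, (zs - spec$z_mm)^2, `+`) <= spec$radius_mm^2,
                  arr.ind = TRUE)
    if (nrow(cols) == 0) stop("electrode footprint covers no voxel column")
    y_top <- R + spec$thickness_mm
    j_top_allowed <- which(ys <= y_top)
    gel_idx <- integer(0); dirichlet <- integer(0)
    for (rr in seq_len(nrow(cols))) {
      i <- cols[rr, 1]; k <- cols[rr, 2]
      col_lab <- grid$label[i, , k]
      surf <- which(col_lab != air_code)
      if (length(surf) == 0) stop("electrode extends beyond the phantom surface")
      j_surf <- max(surf)
      if (col_lab[j_surf] != grid$codes[["skin"]])
        stop("electrode footprint is not on the skin surface")
      j_gel <- seq_len(grid$shape[2])
      j_gel <- j_gel[j_gel > j_surf & j_gel %in% j_top_allowed]
      if (length(j_gel) == 0) stop("pad_mm leaves no room for the gel layer")
      gel_idx <- c(gel_idx, grid_lindex(grid, cbind(i, j_gel, k)))
      dirichlet <- c(dirichlet, grid_lindex(grid, cbind(i, max(j_gel), k)))
    }
    list(spec = spec, gel = gel_idx, dirichlet = dirichlet)
  }

  pa <- place_one(a); pc <- place_one(c_)
  if (length(intersect(pa$gel, pc$gel))) stop("electrodes overlap")
  grid$label[c(pa$gel, pc$gel)] <- gel_code
  grid$sigma[c(pa$gel, pc$gel)] <- grid$tissues[["gel"]]
  grid$electrodes <- list(anode = pa, cathode = pc)
  grid
}

#' Straight nerve trajectory at a given depth
#'
#' A polyline parallel to the arm (z) axis passing `depth_mm` below the skin
#' point under the electrode midline (x = 0, top of the cylinder), sampled at
#' the axon node-of-Ranvier spacing.
#'
#' @param grid phantom `voxel_grid`.
#' @param name nerve name (`"median"`, `"radial"`, `"ulnar"`, or custom).
#' @param depth_mm depth below the skin surface, mm.
#' @param spacing_mm sample spacing along the polyline, mm; default the
#'   5.7 um fibre internode length (0.5 mm).
#' @return object of class `nerve_trajectory` with a `points` matrix (mm).
#' @export
make_nerve_trajectory <- function(grid, name = "median", depth_mm = 5.5,
                                  spacing_mm = 0.5) {
  R <- grid$meta$radius_mm
  if (is.null(R)) stop("grid carries no phantom radius metadata")
  if (depth_mm <= 0 || depth_mm >= R) stop("depth must lie inside the phantom")
  y <- R - depth_mm
  zs <- axis_centers(grid, 3)
  z <- seq(min(zs), max(zs), by = spacing_mm)
  if (length(z) < 2) stop("trajectory needs at least 2 points")
  pts <- cbind(x = 0, y = y, z = z)
  structure(list(name = name, depth_mm = depth_mm, points = pts,
                 spacing_mm = spacing_mm), class = "nerve_trajectory")
}

# trilinear interpolation of a grid-shaped array at points (n x 3, mm);
# clamps to the outermost cell centres, errors if a point leaves the grid box
interp_trilinear <- function(arr, grid, points) {
  points <- matrix(points, ncol = 3)
  lo <- grid$origin
  hi <- grid$origin + grid$shape * grid$spacing
  for (ax in 1:3) {
    if (any(points[, ax] < lo[ax] - 1e-9) || any(points[, ax] > hi[ax] + 1e-9))
      stop("point outside the grid on axis ", ax)
  }
  n <- nrow(points)
  # continuous voxel coordinate relative to cell centres
  out <- numeric(n)
  f <- matrix(0, n, 3); i0 <- matrix(1L, n, 3)
  for (ax in 1:3) {
    t <- (points[, ax] - (grid$origin[ax] + 0.5 * grid$spacing[ax])) / grid$spacing[ax]
    t <- pmin(pmax(t, 0), grid$shape[ax] - 1)
    i0[, ax] <- pmin(as.integer(floor(t)) + 1L, grid$shape[ax] - 1L)
    i0[, ax] <- pmax(i0[, ax], 1L)
    f[, ax] <- t - (i0[, ax] - 1L)
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- grid_lindex(grid, cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz))
    out <- out + w * arr[idx]
  }
  out
}
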