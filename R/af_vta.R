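#' Activating function from the Hessian of the potential
#'
#' Computes, per conductive voxel, the eigenvalues of the Hessian matrix of
#' the electric potential (central second differences; stencils shift inward
#' against air or the grid edge) and reduces them to a scalar activating
#' function, by default the largest absolute eigenvalue. Units are V/m^2
#' (the mm-to-m conversion is applied once inside the kernel). The AF scales
#' linearly with the field, so it carries the current context of the
#' potential it was computed from.
#'
#' @param potential a solved `potential_field`.
#' @param keep_eigenvalues retain the per-voxel eigenvalue triplets.
#' @return object of class `af_field`: `af` (grid-shaped array, >= 0),
#'   optionally `eigenvalues` (3 x grid), the grid and `current_mA`.
#' @export
hessian_af <- function(potential, keep_eigenvalues = FALSE) {
  stopifnot(inherits(potential, "potential_field"))
  g <- potential$grid
  res <- .cpp_hessian_af(potential$phi, as.integer(g$shape), g$spacing,
                         g$sigma > 0, isTRUE(keep_eigenvalues))
  structure(list(af = res$af, eigenvalues = res$eigenvalues, grid = g,
                 current_mA = potential$current_mA),
            class = "af_field")
}

#' Rescale an activating-function field to another current
#'
#' AF is linear in the injected current, so a single Hessian evaluation per
#' montage serves every amplitude.
#'
#' @param af an `af_field` with a known current context.
#' @param target_mA desired current, mA.
#' @export
rescale_af <- function(af, target_mA) {
  stopifnot(inherits(af, "af_field"))
  if (!is.finite(af$current_mA) || af$current_mA == 0)
    stop("AF field has no current context to rescale from")
  f <- target_mA / af$current_mA
  af$af <- af$af * f
  if (!is.null(af$eigenvalues)) af$eigenvalues <- af$eigenvalues * f
  af$current_mA <- target_mA
  af
}

#' Calibrate the AF threshold from a titrated axon
#'
#' The activating level that "just activates" is defined as the maximum AF
#' sampled along the target axon trajectory when the field is evaluated at
#' that axon's titrated threshold current: any tissue seeing at least this AF
#' under the same pulse is counted as activated.
#'
#' @param af an `af_field` evaluated at the threshold current of
#'   `titration` (rescale with [rescale_af()] first).
#' @param trajectory the calibrating `nerve_trajectory`.
#' @param titration optional `titration_result` providing the (PW, current)
#'   context; if given, its threshold current must match the AF current.
#' @return object of class `af_threshold`: `value` (V/m^2), `current_mA`,
#'   `pw_us`, `nerve`.
#' @export
calibrate_af_threshold <- function(af, trajectory, titration = NULL) {
  stopifnot(inherits(af, "af_field"), inherits(trajectory, "nerve_trajectory"))
  if (!is.null(titration) && is.finite(af$current_mA) &&
      abs(af$current_mA - titration$threshold_mA) >
        1e-6 * max(1, abs(titration$threshold_mA)))
    stop("AF field is not evaluated at the titrated threshold current")
  vals <- interp_trilinear(af$af, af$grid, trajectory$points)
  structure(list(value = max(vals), current_mA = af$current_mA,
                 pw_us = if (!is.null(titration)) titration$pw_us else NA_real_,
                 nerve = trajectory$name), class = "af_threshold")
}

#' Volume of tissue activated
#'
#' Thresholds the AF map (evaluated at a common comparison current) at a
#' calibrated activating level. Only biological tissue counts: air and
#' electrode gel voxels are excluded from the mask.
#'
#' @param af an `af_field` with a known current context.
#' @param threshold an `af_threshold` (or a positive number, V/m^2).
#' @param grid the `voxel_grid` (defaults to the AF field's grid).
#' @return object of class `vta_result`: logical `mask`, `volume_mm3`
#'   (= voxel count x voxel volume), `depth_mm` (max depth below the skin
#'   under the electrode midline; `NA` with `empty = TRUE` for an empty
#'   mask), `pw_us` and `current_mA`.
#' @export
vta <- function(af, threshold, grid = af$grid) {
  stopifnot(inherits(af, "af_field"))
  if (inherits(threshold, "af_threshold")) {
    thr <- threshold$value; pw <- threshold$pw_us
  } else {
    thr <- as.numeric(threshold); pw <- NA_real_
  }
  if (!is.finite(thr) || thr <= 0) stop("threshold must be positive")
  if (!is.finite(af$current_mA))
    stop("AF field has no current context; evaluate it at a known current")
  biological <- !(grid$label %in% c(grid$codes[["air"]], grid$codes[["gel"]]))
  dim(biological) <- dim(grid$label)
  mask <- biological & af$af >= thr
  n <- sum(mask)
  depth <- if (n > 0) .mask_max_depth(mask, grid) else NA_real_
  structure(list(mask = mask, volume_mm3 = n * voxel_volume(grid),
                 n_voxels = n, depth_mm = depth, empty = n == 0,
                 pw_us = pw, current_mA = af$current_mA,
                 threshold = thr), class = "vta_result")
}

# maximum depth below the skin surface (under the electrode midline) over a mask
.mask_max_depth <- function(mask, grid) {
  ref_y <- grid$meta$radius_mm
  if (is.null(ref_y)) {
    ys <- axis_centers(grid, 2)
    ref_y <- max(ys[apply(grid$sigma > 0, 2, any)]) + grid$spacing[2] / 2
  }
  jj <- which(apply(mask, 2, any))
  ys <- axis_centers(grid, 2)[jj]
  max(ref_y - ys)
}

#' Maximum activation depth of a VTA mask
#'
#' Depth below the skin surface along the depth (y) axis under the electrode
#' midline, maximized over masked voxels.
#'
#' @param result a `vta_result` (non-empty mask).
#' @param grid the phantom `voxel_grid`.
#' @return depth in mm.
#' @export
activation_depth <- function(result, grid) {
  stopifnot(inherits(result, "vta_result"))
  if (result$empty) stop("activation depth is undefined for an empty VTA mask")
  .mask_max_depth(result$mask, grid)
}

#' Linear fit of VTA against pulse width
#'
#' Ordinary least squares of VTA volume on pulse width across results
#' evaluated at one common current.
#'
#' @param results list of `vta_result` (>= 3 pulse widths).
#' @return list with `slope_mm3_per_us`, `intercept_mm3`, `r_squared`, the
#'   underlying `table` and `fit`.
#' @export
vta_vs_pw <- function(results) {
  if (length(results) < 3) stop("need at least three pulse widths")
  tab <- data.frame(pw_us = sapply(results, `[[`, "pw_us"),
                    volume_mm3 = sapply(results, `[[`, "volume_mm3"))
  if (any(!is.finite(tab$pw_us))) stop("every VTA result must carry its pulse width")
  fit <- lm(volume_mm3 ~ pw_us, data = tab)
  sst <- sum((tab$volume_mm3 - mean(tab$volume_mm3))^2)
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else NA_real_
  structure(list(slope_mm3_per_us = unname(coef(fit)[2]),
                 intercept_mm3 = unname(coef(fit)[1]),
                 r_squared = r2,
                 table = tab, fit = fit), class = "vta_fit")
}

#' @export
print.vta_fit <- function(x, ...) {
  cat(sprintf("<vta_fit> VTA = %.4g + %.4g * PW (R^2 = %.3f)\n",
              x$intercept_mm3, x$slope_mm3_per_us, x$r_squared))
  invisible(x)
}
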