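#' Published double-cable fibre geometry sets
#'
#' Diameter-dependent geometry of the MRG myelinated axon (node/MYSA/FLUT/
#' STIN double cable): axon and node diameters, internode spacing, FLUT
#' (juxtaparanode) length and number of myelin lamellae for the nine
#' published fibre diameters. MYSA diameter equals the node diameter and the
#' FLUT/STIN diameter equals the internodal axon diameter.
#'
#' @return data.frame, one row per published fibre diameter (um).
#' @export
mrg_geometry_table <- function() {
  data.frame(
    fiber_um = c(5.7, 7.3, 8.7, 10.0, 11.5, 12.8, 14.0, 15.0, 16.0),
    g_ratio  = c(0.605, 0.630, 0.661, 0.690, 0.700, 0.719, 0.739, 0.767, 0.791),
    axon_um  = c(3.4, 4.6, 5.8, 6.9, 8.1, 9.2, 10.4, 11.5, 12.7),
    node_um  = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
    internode_um = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    flut_um  = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
    lamellae = c(80, 100, 110, 120, 130, 135, 140, 145, 150)
  )
}

# nodal channel densities (S/cm^2). The motor set is the canonical published
# parameterization. The exact sensory densities used by the commercial
# implementation are not public; the sensory variant here raises persistent
# Na+ and lowers slow K+ density, the qualitative modification reported for
# sensory fibres (longer strength-duration time constant, lower rheobase).
.mrg_channels <- function(variant) {
  switch(variant,
    motor   = list(gnaf = 3.0, gnap = 0.01, gks = 0.08, gl = 0.007),
    sensory = list(gnaf = 3.0, gnap = 0.025, gks = 0.06, gl = 0.007),
    stop("unknown variant: ", variant))
}

#' Build a double-cable myelinated axon model
#'
#' Constructs the compartment chain node-MYSA-FLUT-STIN x6-FLUT-MYSA
#' repeating, with geometry interpolated between the published fibre sets and
#' electrical parameters (axial and periaxonal resistances, axolemma and
#' myelin membrane properties, nodal channel densities) in the units used by
#' the integrator (nF, uS, MOhm implicit). The leak reversal is balanced so
#' that the nodal ionic currents are exactly zero at the resting potential.
#'
#' @param diameter_um fibre diameter, um; within the published range
#'   (5.7 to 16). Values between published sets are linearly interpolated.
#' @param n_nodes number of nodes of Ranvier (>= 21; default 101).
#' @param variant `"sensory"` (default) or `"motor"` nodal channel set.
#' @return object of class `mrg_axon`.
#' @export
#' @examples
#' ax <- build_axon(5.7, n_nodes = 21)
#' ax$total_length_um
build_axon <- function(diameter_um = 5.7, n_nodes = 101,
                       variant = c("sensory", "motor")) {
  variant <- match.arg(variant)
  tab <- mrg_geometry_table()
  if (diameter_um < min(tab$fiber_um) || diameter_um > max(tab$fiber_um))
    stop(sprintf("diameter %.2f um outside the supported range [%.1f, %.1f]",
                 diameter_um, min(tab$fiber_um), max(tab$fiber_um)))
  if (n_nodes < 21) stop("n_nodes must be >= 21 to support a propagating spike")
  geo <- lapply(tab[-1], function(col) stats::approx(tab$fiber_um, col, diameter_um)$y)

  node_len <- 1; mysa_len <- 3
  flut_len <- geo$flut_um
  stin_len <- (geo$internode_um - node_len - 2 * mysa_len - 2 * flut_len) / 6
  # compartment pattern: node, then (MYSA FLUT STIN x6 FLUT MYSA node) repeated
  internode_types <- c("MYSA", "FLUT", rep("STIN", 6), "FLUT", "MYSA")
  type <- c("node", rep(c(internode_types, "node"), n_nodes - 1))
  ncomp <- length(type)
  stopifnot(ncomp == 11 * (n_nodes - 1) + 1)

  len <- c(node = node_len, MYSA = mysa_len, FLUT = flut_len, STIN = stin_len)[type]
  d_ax <- c(node = geo$node_um, MYSA = geo$node_um, FLUT = geo$axon_um,
            STIN = geo$axon_um)[type]
  peri_space <- c(node = 0.002, MYSA = 0.002, FLUT = 0.004, STIN = 0.004)[type]

  rho_ohm_cm <- 70          # axoplasm and periaxonal resistivity
  mycm <- 0.1; mygm <- 0.001  # per lamella membrane, uF/cm^2 and S/cm^2
  nl <- geo$lamellae
  fiberD <- diameter_um

  a_ax_cm2 <- pi * d_ax * len * 1e-8          # axolemma area
  a_my_cm2 <- pi * fiberD * len * 1e-8        # myelin (fibre surface) area
  C_nF <- 2 * a_ax_cm2 * 1e3                  # cm = 2 uF/cm^2 everywhere
  gpas_scm2 <- c(node = 0, MYSA = 0.001, FLUT = 0.0001, STIN = 0.0001)[type]
  gpas_uS <- gpas_scm2 * a_ax_cm2 * 1e6
  epas <- rep(-80, ncomp)

  is_node <- type == "node"
  ch <- .mrg_channels(variant)
  gnaf <- ifelse(is_node, ch$gnaf * a_ax_cm2 * 1e6, 0)
  gnap <- ifelse(is_node, ch$gnap * a_ax_cm2 * 1e6, 0)
  gks  <- ifelse(is_node, ch$gks * a_ax_cm2 * 1e6, 0)
  gl   <- ifelse(is_node, ch$gl * a_ax_cm2 * 1e6, 0)

  # myelin sheath: 2*nl membranes in series; nodes get a near-short to the
  # extracellular space (no myelin), mirroring the reference implementation
  Cmy_nF <- ifelse(is_node, 0, mycm / (2 * nl) * a_my_cm2 * 1e3)
  gmy_uS <- ifelse(is_node, 1e10 * a_ax_cm2 * 1e6, mygm / (2 * nl) * a_my_cm2 * 1e6)

  # axial resistances per compartment (MOhm)
  r_intra <- rho_ohm_cm * (len * 1e-4) / (pi * (d_ax / 2 * 1e-4)^2) / 1e6
  a_peri_cm2 <- pi * ((d_ax / 2 + peri_space)^2 - (d_ax / 2)^2) * 1e-8
  r_peri <- rho_ohm_cm * (len * 1e-4) / a_peri_cm2 / 1e6
  ga <- 1 / ((r_intra[-ncomp] + r_intra[-1]) / 2)
  gp <- 1 / ((r_peri[-ncomp] + r_peri[-1]) / 2)

  vrest <- -80
  gates <- .cpp_node_gates_inf(vrest)
  ena <- 50; ek <- -90
  g_na <- ch$gnaf * gates[["m"]]^3 * gates[["h"]] + ch$gnap * gates[["p"]]^3
  g_k <- ch$gks * gates[["s"]]
  el <- vrest + (g_na * (vrest - ena) + g_k * (vrest - ek)) / ch$gl

  pos_um <- cumsum(len) - len / 2
  structure(list(
    diameter_um = diameter_um, variant = variant, n_nodes = n_nodes,
    type = type, node_idx = which(is_node), length_um = len,
    position_mm = pos_um / 1000, total_length_um = sum(len),
    internode_um = geo$internode_um, node_diameter_um = geo$node_um,
    axon_diameter_um = geo$axon_um, flut_um = geo$flut_um, lamellae = nl,
    C_nF = C_nF, gpas_uS = gpas_uS, epas_mV = epas,
    gnaf_uS = gnaf, gnap_uS = gnap, gks_uS = gks, gl_uS = gl,
    ena = ena, ek = ek, el = el, vrest = vrest,
    Cmy_nF = Cmy_nF, gmy_uS = gmy_uS, ga_uS = ga, gp_uS = gp
  ), class = "mrg_axon")
}

#' @export
print.mrg_axon <- function(x, ...) {
  cat(sprintf("<mrg_axon> %.1f um %s fibre, %d nodes, %d compartments, %.1f mm\n",
              x$diameter_um, x$variant, x$n_nodes, length(x$type),
              x$total_length_um / 1000))
  invisible(x)
}

#' Sample extracellular potentials along a nerve trajectory
#'
#' Trilinearly interpolates a solved potential at each axon compartment
#' centre, with the axon centred on the trajectory's arclength. Values are
#' returned in mV.
#'
#' @param potential a solved `potential_field`.
#' @param trajectory a `nerve_trajectory`.
#' @param axon an `mrg_axon`.
#' @return object of class `extracellular_drive`: per-compartment potentials
#'   (mV) and the current context they were sampled at.
#' @export
sample_extracellular <- function(potential, trajectory, axon) {
  stopifnot(inherits(potential, "potential_field"),
            inherits(trajectory, "nerve_trajectory"), inherits(axon, "mrg_axon"))
  pts <- trajectory$points
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))                      # arclength, mm
  L_ax <- axon$total_length_um / 1000
  if (L_ax > s[length(s)] + 1e-9)
    stop(sprintf("trajectory (%.1f mm) is shorter than the axon (%.1f mm)",
                 s[length(s)], L_ax))
  offset <- (s[length(s)] - L_ax) / 2
  si <- offset + axon$position_mm
  xyz <- sapply(1:3, function(ax) stats::approx(s, pts[, ax], si)$y)
  phi_mV <- 1000 * interp_trilinear(potential$phi, potential$grid, xyz)
  structure(list(values_mV = phi_mV, points = xyz, nerve = trajectory$name,
                 current_mA = potential$current_mA),
            class = "extracellular_drive")
}

#' Integrate the axon response to an extracellular stimulus
#'
#' Advances the double-cable equations with a backward-Euler step on the
#' coupled linear system (Rush-Larsen updates for the nodal gates). The
#' extracellular potential of compartment `i` at time `t` is
#' `amplitude * a(t) * drive_i`.
#'
#' @param axon an `mrg_axon`.
#' @param drive an `extracellular_drive` (or numeric vector, mV per
#'   compartment).
#' @param pulse a `pulse_spec` from [make_pulse()].
#' @param amplitude unitless scale factor on the drive (the titration factor).
#' @param duration_ms,dt_ms solver window and time step (defaults 3.5 and
#'   0.0025 ms). `dt_ms` must be <= 0.005.
#' @return object of class `membrane_trace`: time vector (ms) and node
#'   voltage matrix (mV, time x node).
#' @export
integrate_axon <- function(axon, drive, pulse, amplitude,
                           duration_ms = 3.5, dt_ms = 0.0025) {
  stopifnot(inherits(axon, "mrg_axon"))
  if (dt_ms > 0.005) stop("dt_ms must be <= 0.005 ms")
  v <- if (inherits(drive, "extracellular_drive")) drive$values_mV else as.numeric(drive)
  if (length(v) != length(axon$type)) stop("drive length must equal the compartment count")
  if (any(!is.finite(v))) stop("drive contains non-finite values")
  if (duration_ms < 2 * pulse$pw_us / 1000 + pulse$interphase_ms)
    stop("duration must cover the pulse")
  nt <- as.integer(round(duration_ms / dt_ms))
  a_t <- pulse$a((1:nt) * dt_ms)
  res <- .cpp_mrg_integrate(as.integer(axon$type == "node"), axon$C_nF,
                            axon$gpas_uS, axon$epas_mV, axon$gnaf_uS,
                            axon$gnap_uS, axon$gks_uS, axon$gl_uS,
                            axon$ena, axon$ek, axon$el, axon$vrest,
                            axon$Cmy_nF, axon$gmy_uS, axon$ga_uS, axon$gp_uS,
                            v, a_t, amplitude, dt_ms,
                            as.integer(axon$node_idx))
  if (res$blown_up)
    stop(sprintf("membrane integration unstable (|Vm| reached %.0f mV)", res$max_abs_Vm))
  structure(list(time_ms = (0:nt) * dt_ms, V = res$V, rest_mV = axon$vrest,
                 node_position_mm = axon$position_mm[axon$node_idx],
                 dt_ms = dt_ms, amplitude = amplitude),
            class = "membrane_trace")
}

#' Detect a propagating action potential in a membrane trace
#'
#' A spike is counted when the node voltage crosses `level_mV` upwards at a
#' minimum number of distinct nodes, at least one of which lies several nodes
#' away from the initiation site (the earliest-crossing node), so that a
#' local, non-propagating depolarization does not qualify.
#'
#' @param trace a `membrane_trace`.
#' @param level_mV detection level (default -20 mV, upward crossing; at the
#'   smallest fibre diameter the converged spike peak lies near 0 mV, so the
#'   level sits midway between rest and peak).
#' @param min_nodes minimum number of crossing nodes (default 3).
#' @param min_span minimum node distance from the initiation site (default 5).
#' @return list with `spike` (logical), `nodes`, `times_ms`, `initiation`.
#' @export
detect_ap <- function(trace, level_mV = -20, min_nodes = 3, min_span = 5) {
  V <- trace$V
  cross <- (V[-1, , drop = FALSE] > level_mV) & (V[-nrow(V), , drop = FALSE] <= level_mV)
  first <- apply(cross, 2, function(cc) if (any(cc)) which(cc)[1] else NA_integer_)
  nodes <- which(!is.na(first))
  if (length(nodes) == 0)
    return(list(spike = FALSE, nodes = integer(0), times_ms = numeric(0),
                initiation = NA_integer_))
  times <- trace$time_ms[first[nodes] + 1L]
  init <- nodes[which.min(times)]
  spike <- length(nodes) >= min_nodes && max(abs(nodes - init)) >= min_span
  list(spike = spike, nodes = nodes, times_ms = times, initiation = init)
}

#' Conduction velocity from node crossing times
#'
#' Linear regression of first spike times against node position over the
#' central portion of the fibre (away from the initiation site and the sealed
#' ends), in m/s (mm/ms).
#'
#' @param trace a `membrane_trace` containing a propagating spike.
#' @param level_mV crossing level, as in [detect_ap()].
#' @return conduction velocity in m/s.
#' @export
conduction_velocity <- function(trace, level_mV = -20) {
  det <- detect_ap(trace, level_mV)
  if (!det$spike) stop("no propagating action potential in the trace")
  nodes <- det$nodes; times <- det$times_ms
  init <- det$initiation
  # use one propagation direction, away from initiation and the ends
  side <- nodes[nodes > init + 3 & nodes < max(nodes) - 2]
  if (length(side) < 5) side <- nodes[nodes < init - 3 & nodes > min(nodes) + 2]
  if (length(side) < 5) stop("too few nodes for a velocity regression")
  tt <- times[match(side, nodes)]
  pos <- trace$node_position_mm[side]
  abs(unname(coef(lm(pos ~ tt))[2]))
}
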