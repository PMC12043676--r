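---
title: "Pulse-width dosimetry for TENS: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-width dosimetry for TENS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tensdepth` studies one question: at matched current, how does the pulse
width of a transcutaneous electrical nerve stimulation (TENS) device change
the volume and depth of activated tissue in the forearm? This vignette
documents the model chain, the parameters that matter, the numerical
choices, and what a passing test suite does and does not establish.

## 1. The volume conductor

At TENS pulse rates tissue behaves resistively, so the potential obeys the
Ohmic quasi-static equation

$$\nabla\cdot\sigma\nabla\varphi = 0,$$

with fixed voltages on the electrode pad surfaces (Dirichlet) and zero
normal current on every other boundary. The discretization is a
cell-centred 7-point finite-difference stencil; face conductances use the
harmonic mean of the two adjacent voxel conductivities, which is exact for
layered media and conservative across tissue jumps. Air voxels
(σ = 0) are removed from the system rather than regularized — they would
otherwise destroy the conditioning. The symmetric positive-definite system
is solved matrix-free with Jacobi-preconditioned conjugate gradients to a
relative residual of 1e-8 (default; halving it changes the solution by
< 1e-6, and the anode/cathode currents balance to machine precision because
the discrete operator conserves flux).

Linearity is exploited throughout: one unit solve (±1 V) per montage is
rescaled to any injected current (`scale_to_current()`), so titration across
many amplitudes costs one field solve.

Units are fixed once at the boundaries of each operator: σ in S/m, spacing
in mm, φ in V; the electric field applies the mm→m factor (1000) inside
`electric_field()` (V/m) and the Hessian kernel applies 1e6 inside
`hessian_af()` (V/m²).

## 2. The phantom: a stated world, not an anatomy

No anatomical dataset ships with the package. The synthetic forearm is a
concentric-cylinder surrogate: radius 40 mm, length 120 mm, layers
skin 1.5 mm → subcutaneous adipose tissue 3.5 mm → muscle down to a 20 mm
bone radius, cortical bone to the axis (the inner cancellous/marrow detail
is configurable via `layers` but off by default). Conductivities are the
standard low-frequency database values (skin 0.1482 S/m, SAT/fat 0.0776,
muscle 0.4610, cortical bone 0.0063, gel 1.7, …). Two gel disc electrodes
(radius 3 mm, total thickness 2 mm, centres 2 cm apart) sit on the upper
skin surface; the pad metal is not meshed — the top gel layer is the
equipotential Dirichlet surface. Nerve trajectories are straight lines
parallel to the arm axis under the electrode midline at the reported skin
depths: median 5.5 mm, radial 13.1 mm, ulnar 14.9 mm.

What this surrogate preserves from real anatomy: the layered-conductivity
physics (resistive skin, conductive muscle, insulating bone core), realistic
electrode geometry, and the depth ordering of the three nerves. What it
drops: cross-sectional asymmetry, discrete vessels/tendons, curved and
branching nerves, and all absolute geometry beyond the layer radii. A green
pipeline test therefore establishes the *pulse-width relationships*
(threshold ordering and monotone volume/depth growth), never absolute
thresholds, field values or volumes — a ±1 V montage drives ~1.6 mA here,
while anatomical arm models report ratios nearer 2 mA/V, and all downstream
numbers inherit such differences.

The default layer thicknesses at the electrode site are a choice (the
geometry of a real arm there is not tabulated); they place the median
trajectory just inside muscle, under the fascia-like SAT/muscle interface.
Grid spacing defaults to 1 mm (0.5 mm for convergence studies): at 0.5 mm
the unit electrode current changes by 7.7% and titrated thresholds by ~1%.

## 3. The sensory axon

The fibre is the McIntyre–Richardson–Grill double cable: nodes of Ranvier
with fast Na⁺, persistent Na⁺, slow K⁺ and leak channels; passive
MYSA/FLUT/STIN internodal axolemma under a myelin sheath (2·`lamellae`
membranes in series); an explicit periaxonal space with its own axial
resistance. Geometry and electrical constants follow the published
parameter sets for 5.7–16 µm fibres, linearly interpolated in between; the
default is 5.7 µm with 101 nodes (50 mm). Commercial solvers expose a
"5 µm" setting, but their interpolation below the smallest published set is
not public, so the nearest published set is the default here.

**Sensory variant.** TENS targets sensory fibres, and sensory-modified MRG
parameterizations exist, but their channel values are not published in a
transcribable form. The `sensory` default here keeps the
published cable and kinetics and adjusts nodal densities (persistent Na⁺
0.01 → 0.025 S/cm², slow K⁺ 0.08 → 0.06 S/cm²), in the direction reported
for sensory axons; `variant = "motor"` restores the canonical set for
cross-checking. A density scan showed the extracellular chronaxie of this
cable is pinned at ~70–80 µs regardless of plausible density choices — the
published sensory chronaxie (~230 µs) evidently comes from modified channel
*kinetics*, which are not available to transcribe. This is the package's
main known infidelity; its consequence is quantified in §6.

**Numerics.** The coupled (membrane, periaxonal) system is advanced by
backward Euler — the nodal dynamics are stiff — as a 2×2-block tridiagonal
solve per step, with Rush–Larsen exponential gating updates; dt = 0.0025 ms
over 3.5 ms (standard settings for single-pulse titration). Titrated thresholds move by ~1.3% under
dt → dt/4. The leak reversal is solved so nodal currents are exactly zero
at −80 mV, giving a drift-free rest (< 1e-9 mV over 3.5 ms); no junction
potential correction is applied to reported voltages.

**Spike criterion.** A propagating action potential is an upward crossing
of −20 mV at ≥ 3 nodes, at least one ≥ 5 nodes from the initiation site.
The level is −20 mV, not 0 mV, because at 5.7 µm the dt-converged spike
peak lies near 0 mV (−0.4 to +0.9 mV across mid-fibre nodes), so a 0 mV
level sits on the peak and flips with the time step; −20 mV lies midway
between rest and peak. After a spike the fibre shows the model's
depolarizing afterpotential (~5 mV at 3.5 ms), which is why the
charge-balance test is run just below threshold, where the residual is
< 1 mV.

## 4. Titration and strength–duration analysis

The stimulus is a charge-balanced rectangular biphasic pulse, cathodic
first (the common TENS convention; a flag flips polarity), one phase
width PW ∈ {30, 88, 146, 262, 495} µs, 0.1 ms interphase. The threshold
factor T doubles from 0.1 until a spike occurs (cap 2¹⁵), then bisects to a
1% relative bracket; the threshold current is `I_T = T · I` exactly, with
I the 5 mA baseline. T halves when the baseline doubles, `I_T` is
baseline-invariant, and the bisected threshold agrees with a brute-force
0.5%-step scan within the combined granularity.

Strength–duration curves are fit by Weiss, `I = I_rh(1 + c/PW)`, or
Lapicque, `I = I_rh/(1 − 2^{−PW/c})` (port-algorithm nonlinear least
squares, positivity bounds); in both forms `c` is the chronaxie and the
Lapicque membrane time constant is `c/ln 2`. Noiseless Lapicque data at the
five pulse widths are recovered to 0.1%; with 5% multiplicative noise the
median chronaxie over 100 replicates stays within 10%.

## 5. Activating function and volume of tissue activated

The activating function is computed per voxel as the largest absolute
eigenvalue of the Hessian of φ (closed-form symmetric 3×3
eigendecomposition). Second differences are central where both neighbours
are conductive; against air or the grid edge the stencil shifts one voxel
inward, and a mixed partial falls back to zero when a corner is
unavailable — boundary AF is therefore a constant-extrapolation estimate,
kept rather than masked (tissue-boundary AF spikes are a real feature of
heterogeneous media). The
orientation of candidate fibres is deliberately ignored (magnitude-only
reduction; alternatives such as the along-axon second difference can be
derived from the retained eigenvalues).

Calibration follows the usual multi-step construction: titrate the
reference (median) axon at a pulse width; evaluate the AF field at that
threshold current; the maximum AF sampled along the axon trajectory is the
activating level for that pulse width. All pulse widths are then compared
at one common current — the arithmetic mean of the shortest- and
longest-pulse thresholds — and the VTA is the set of biological-tissue
voxels (air and gel excluded — a rule of this package) whose AF meets the level. Volume is voxel count × voxel
volume exactly; activation depth is the maximum depth below the skin
surface under the electrode midline over the mask. Because AF, thresholds
and the mask all scale linearly with current, VTA is monotone in pulse
width by construction whenever thresholds are.

## 6. What the default pipeline reproduces — and the one miss

On the default phantom the pipeline reproduces, deterministically: strictly
decreasing strength–duration thresholds over 30→495 µs; strictly higher
thresholds for the deeper radial and ulnar nerves at every pulse width;
strictly increasing VTA and non-decreasing activation depth with pulse
width at the common current.

The VTA-vs-PW straight-line fit reaches R² = 0.892 at 1 mm (0.888 at
0.5 mm), short of the 0.9 that anatomical models of this protocol report. The shape is traced to
§3: with chronaxie ~76 µs instead of ~232 µs, thresholds flatten beyond
~150 µs, the per-pulse-width AF levels stop moving, and the volume
saturates — bending the line. The corresponding acceptance test is left
failing rather than loosened; fixing it requires the unpublished sensory
channel kinetics.

## 7. Degenerate inputs and tie-breaks

Zero or negative pulse widths, electrode radius 0, overlapping electrodes,
trajectories outside the phantom, trajectories shorter than the axon,
single-voltage Dirichlet sets and disconnected electrodes are all explicit
errors. Integration aborts if |Vm| exceeds 500 mV (numerical-instability
guard; the strongest physical artifacts stay below it at titration scales).
An empty VTA mask reports volume 0 with an undefined-depth flag. The
titration result records its bracket, so `T(1+tol)` spikes and `T(1−tol)`
does not, by construction. Config files are schema-checked and unknown keys
rejected by name; the run report carries a content hash of the validated
config, and the pipeline is bit-reproducible for a fixed config.
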