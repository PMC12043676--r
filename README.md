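# tensdepth

Computational dosimetry for transcutaneous electrical nerve stimulation
(TENS): how does the **pulse width** setting of a TENS device change **how
deep** the stimulation reaches?

TENS devices expose therapy modes that differ in pulse width (tens to
hundreds of microseconds). Longer pulses are empirically felt as "deeper"
stimulation. `tensdepth` reproduces that relationship mechanistically on a
desk-scale model of the forearm:

1. **Arm phantom** — a voxelized concentric-cylinder forearm (skin, SAT,
   muscle, bone; standard low-frequency tissue conductivities) with
   two gel disc electrodes (radius 3 mm, 2 mm thick, 2 cm apart) on the
   wrist, and straight median/radial/ulnar nerve trajectories at 5.5, 13.1
   and 14.9 mm below the skin.
2. **Volume conductor** — the Ohmic quasi-static potential, `∇·σ∇φ = 0`,
   with Dirichlet electrode voltages and insulating outer boundaries; solved
   by conjugate gradients on a 7-point harmonic-mean finite-difference
   stencil (air excluded). The problem is linear, so one unit solve per
   montage is rescaled to any injected current.
3. **Sensory axon** — a McIntyre–Richardson–Grill (MRG) double-cable
   myelinated fibre (node/MYSA/FLUT/STIN, default 5.7 µm, 101 nodes) driven
   by the extracellular potentials sampled along a nerve trajectory;
   backward-Euler integration at 0.0025 ms over 3.5 ms.
4. **Titration** — the excitability threshold `I_T(t) = I · T · a(t)`: the
   scale factor `T` on a charge-balanced biphasic pulse `a(t)` (widths
   {30, 88, 146, 262, 495} µs, 0.1 ms interphase) is bracketed and bisected
   until exactly one propagating action potential is elicited. Repeating
   across pulse widths yields the strength–duration (S-D) curve, fit by
   Weiss (`I = I_rh(1 + c/PW)`) or Lapicque (`I = I_rh/(1 − 2^{−PW/c})`)
   to report rheobase `I_rh` and chronaxie `c`.
5. **Activating function & VTA** — the activating function is the largest
   absolute eigenvalue of the Hessian of φ per voxel (V/m²); the AF level
   that "just activates" is calibrated from the titrated axon at its
   threshold current; thresholding the AF map at one common current (the
   mean of the extreme-pulse-width thresholds) gives the volume of tissue
   activated (VTA), its maximum activation depth, and the VTA-vs-PW linear
   fit.

## Worked example

```r
library(tensdepth)

cfg <- default_config()            # 40 mm arm, 1 mm grid, 5 mA baseline
report <- run_pipeline(cfg)        # ~3 min on one CPU
print(report)
```

Output on this machine (abridged):

```
<run_report> hash ... | unit current 1.643 mA | common current 13.21 mA
strength-duration table:
  nerve pw_us    factor threshold_mA
 median    30  4.512500    22.562500
 median    88  2.043750    10.218750
 median   146  1.418750     7.093750
 median   262  0.996875     4.984375
 median   495  0.771875     3.859375
 radial    30 12.550000    62.750000
 ...
VTA table:
 pw_us threshold_current_mA af_threshold_V_per_m2 volume_mm3 depth_mm
    30            22.562500              827284.5         60      0.5
    88            10.218750              374684.3        424      5.5
   146             7.093750              260101.9        860      5.5
   262             4.984375              182758.8       1332      5.5
   495             3.859375              141509.2       1684      5.5
<vta_fit> VTA = 181.6 + 3.381 * PW (R^2 = 0.892)
```

Reading this: at ±1 V the montage drives 1.64 mA through the phantom;
shorter pulses need more current (22.6 mA at 30 µs vs 3.9 mA at 495 µs for
the median nerve, strictly decreasing, and deeper nerves always need more);
at the common evaluation current of 13.21 mA the activated volume grows
monotonically with pulse width (60 → 1684 mm³), as does the activation
depth — the pulse-width/depth effect the package is built to study.

`write_outputs(report, "out/")` writes `sd.csv`, `vta.csv`, `report.json`
and (optionally) VTK field files. A command-line front end is installed at
`inst/cli/tens-depth.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tens-depth.R", package="tensdepth"))')" \
    run --config run.yaml --out results/
```

## Scope

The phantom is a layered cylinder, not an anatomical arm: absolute
thresholds, field magnitudes and VTA volumes are not comparable to
anatomical models; the pulse-width *relationships* are. See the methods
vignette (`vignettes/tens-pulse-width-dosimetry.Rmd`) for the model
assumptions, numerical choices and limitations.
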