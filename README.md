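# glymphflow

Regularized optimal mass transport (rOMT) analysis of cerebrospinal-fluid
and glymphatic transport from dynamic contrast-enhanced MRI (DCE-MRI), for
researchers quantifying brain solute flow from intrathecal-tracer imaging
in small animals.

DCE-MRI with a gadolinium tracer infused into the CSF yields a 4D record of
tracer density (percent signal change from baseline is proportional to
density). `glymphflow` turns that record into flow physiology:

- **rOMT solver** — between each pair of adjacent frames it estimates the
  velocity field `v` minimizing the Benamou–Brenier kinetic energy
  `∫∫ ρ|v|² dx dt + β‖ρ(1) − ρ₁‖²` subject to the advection–diffusion
  constraint `∂ρ/∂t + ∇·(ρv) = σΔρ` (Gauss–Newton with adjoint gradients
  and matrix-free sensitivity products; mass-conserving push-forward
  advection, implicit Neumann diffusion).
- **Lagrangian read-outs** — RK4 pathlines through the estimated fields;
  speed maps (µm/s); mean solute speed; volume transport flux (v-flux,
  which in the tissue compartment measures glymphatic transport); velocity
  flux vectors.
- **ICP waveform decomposition** — respiratory (2 Hz low-pass) and
  cardiac-pulse (45-point Savitzky–Golay + 5 Hz high-pass, zero-phase)
  amplitude channels, per-cycle max–min amplitudes, baseline-normalized
  epoch summaries.
- **Lymph-node drainage kinetics** — CSF-normalized time–signal curves,
  2-step moving-average smoothing, time to peak, peak magnitude, AUC.
- **Voxel statistics** — 0.4 mm FWHM smoothing and pooled-variance
  two-sample t maps with one-sided p values in both directions.
- **Synthetic phantoms** — ground-truthed tracer simulations (independent
  upwind integrator on a refined grid), synthetic ICP traces and
  gamma-variate uptake curves, so every stage is testable without in vivo
  data.

## Worked example

Simulate a phantom whose true flow is 4 µm/s, run the full pipeline, and
compare the recovered mean solute speed with the ground truth:

```r
library(glymphflow)

spec  <- phantomSpec(noiseSd = 0, seed = 7)   # 32^3, 0.3 mm, 5 frames/300 s
truth <- makeVelocityField(spec)
series <- simulateTracerSeries(spec, truth)   # raw signal + 3 baselines

pc    <- preprocessSeries(series)             # % change, 0.1 mm smooth, floor
sols  <- solveSeries(pc, romtConfig())        # one rOMT solve per frame pair
paths <- tracePathlines(sols)                 # RK4 pathlines from the bolus
sm    <- speedMap(paths)
transportMetrics(sm, gridMask(imageGrid(sm), "brain"))
```

```
  compartment meanSpeed_um_s vFlux_mm3 nPositive maskVolume_mm3
1 whole brain       3.624894    84.132      3116        884.736
```

The estimator recovers 3.63 µm/s against the 4 µm/s ground truth (9%
low, within the 20% recovery contract its tests enforce), and the
pathline network sweeps 84 mm³. The ICP and lymph-node analyses run the
same way from `makeIcpWaveform()`/`splitChannels()`/`epochSummary()` and
`makeTsc()`/`smoothTsc()`/`tscMetrics()`; a two-cohort study with voxel
statistics is one call: `runGroupStudy(studyConfig(...))`.

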