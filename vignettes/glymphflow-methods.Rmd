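---
title: "Estimating glymphatic transport with regularized optimal mass transport"
author: "glymphflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating glymphatic transport with regularized optimal mass transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Dynamic contrast-enhanced MRI (DCE-MRI) with an intrathecally infused
gadolinium tracer images cerebrospinal fluid (CSF) and glymphatic transport
as a slowly evolving 4D signal: repeated T1-weighted volumes over roughly a
hundred minutes, at sub-millimetre resolution, in which the percent signal
change from baseline is proportional to the local tracer density. The
scientific question is not where the tracer *is* but how it *moves*: how
fast CSF and interstitial solutes flow, along which routes, and how much
tissue the transport network reaches. `glymphflow` answers this with a
regularized dynamic optimal mass transport (rOMT) model, Lagrangian
post-processing of the estimated flow, and the two companion physiological
analyses such studies lean on: intracranial-pressure (ICP) waveform
amplitude decomposition and lymph-node drainage kinetics. Because in vivo
data of this kind are rarely deposited, the package ships a ground-truthed
synthetic phantom generator, and every stage of the pipeline is validated
against phantoms with known velocity fields.

# The transport model

Between each pair of adjacent frames $\rho_0, \rho_1$ the package seeks a
time-varying velocity field $v$ that carries $\rho_0$ to $\rho_1$ under an
advection-diffusion constraint at minimal kinetic energy,

$$\min_v \; \int_0^1\!\!\int_\Omega \rho\,|v|^2 \,dx\,dt
  + \beta \int_\Omega (\rho(\cdot,1) - \rho_1)^2 \,dx
  \quad\text{s.t.}\quad
  \partial_t \rho + \nabla\cdot(\rho v) = \sigma \Delta \rho,$$

the dynamic (Benamou–Brenier) formulation of optimal transport with a
diffusion term added to the continuity equation — more faithful to
glymphatic physiology, where solutes both advect with bulk flow and diffuse.
The endpoint constraint is relaxed into a quadratic penalty with weight
$\beta$ so that imaging noise need not be transported.

## Discretization

The pseudo-time of one frame interval is divided into $m$ substeps
(default 8). One substep applies, by operator splitting:

1. **Mass-preserving push-forward advection.** Every voxel deposits its
   mass at its displaced position with trilinear weights; displaced
   positions are clamped inside the domain. This conserves total mass to
   machine precision by construction — the closed-skull analogue of
   zero-flux boundaries — which the test suite asserts at relative 1e-8.
2. **Implicit diffusion.** $(I - \sigma L)\rho' = \rho_{\mathrm{adv}}$ with
   $L$ the 7-point Neumann Laplacian, solved by conjugate gradient. The
   operator is symmetric positive definite and extremely well conditioned
   for the relevant $\sigma$, so a handful of CG iterations reach 1e-8.

Velocities are piecewise constant per substep and cell-centred, in internal
units of voxels per substep; conversion to µm/s
($|v| \cdot \mathrm{voxel\;mm} \cdot 1000 \cdot m / \mathrm{interval\;s}$)
happens only at reporting, which keeps the optimization well scaled. The
energy is normalized so that a pure translation by $d$ voxels has kinetic
energy $\mathrm{mass}\cdot|d|^2$ — the squared Wasserstein-2 distance —
giving the solver an analytic yardstick that the acceptance suite checks on
translated Gaussians.

## Optimization

`solvePair` minimizes the discrete energy by Gauss-Newton. The exact
gradient comes from an adjoint recursion backwards through the $m$
substeps (validated against central finite differences at relative 1e-4 on
random problems). The Gauss-Newton step solves the normal equations
matrix-free by conjugate gradient: each operator product runs the
linearized substep recursion forwards (the sensitivity of the final density
to a velocity perturbation) and its adjoint backwards, plus the
density-weighted diagonal of the kinetic term and a small Levenberg-style
damping that keeps the operator positive definite where the density
vanishes. A backtracking Armijo line search guarantees the accepted-energy
log never increases; the whole solve contains no randomness, so identical
inputs give bitwise-identical output. Initialization is $v = 0$.

The model constants ($\sigma$ = 0.002 voxel²/substep, $\beta$ = 1e4,
$m$ = 8, 30 outer iterations) are exposed in `romtConfig` and recorded in
every output's provenance. They are this package's own defaults, chosen so
that sub-voxel per-substep displacements are resolved and the endpoint
penalty dominates the kinetic term at convergence; published applications
of this model family do not print their numeric settings, so results at
other settings may differ quantitatively. The velocity is masked to the
brain compartment during optimization (not only in post-processing) — with
no published statement either way, constraining the unknowns is the more
conservative choice.

# Lagrangian read-outs

`tracePathlines` seeds the voxel centres whose first-frame density exceeds
10% of the in-mask maximum (the seeding rule is exposed; no published rule
exists). The default presumes the first frame's background is clean at the
seed scale; under measurement noise the threshold must sit a few noise
standard deviations above background, or background voxels seed spurious
near-stationary pathlines that dilute the mean speed — for the 10%-noise
validation phantom (noise SD one-ninth of the first-frame maximum) the
package uses 0.3 of the maximum, about three noise SDs. Integration is one
classical RK4 step per substep through the
trilinearly interpolated, piecewise-constant-in-time velocity,
concatenated across frame intervals. A pathline is retained when its
traversed arc length reaches 0.5 voxel; arc length rather than start-to-end
displacement is deliberate, so closed orbits (which genuinely moved) are
kept — the rotation-phantom test traces a full revolution and checks both
sub-1% radius drift and orbit closure. Speed maps deposit each step's
|v| (µm/s) into the voxel containing the step's start point; a voxel's
value is the arithmetic mean of its deposits (order-independent,
tie-free). From a speed map and a compartment mask, `transportMetrics`
reports the mean of strictly positive voxel speeds (mean solute speed,
averaged over voxels — averaging over pathline sample points is the
documented alternative) and the positive-speed voxel volume (v-flux, the
volume of the transport network; in the tissue compartment this measures
glymphatic transport). `fluxVectors` returns start-to-end displacement
vectors, the "how far and which way" summary.

One documented limitation: a voxel counts as visited when an RK4 endpoint
lies in it; crossings between endpoints are not rasterized. At the default
half-voxel substep displacements the difference is negligible.

# The phantom generator

`simulateTracerSeries` is the package's evidence base: a Gaussian bolus (in
percent-signal-change units) transported by a known velocity field
(constant, rigid rotation, band-limited random, or zero, optionally with a
planted regional speed-up) with known diffusion. To prevent the recovery
tests from being self-fulfilling, the simulator never touches the solver's
forward operator: it integrates the same PDE with a different scheme
(flux-form first-order upwind with explicit diffusion), on a refined grid
(2x spatial, at least 4x temporal with CFL-limited substeps), and
downsamples by mean pooling. Defaults mirror the target acquisition at desk
scale: 32³ voxels of 0.3 mm, five frames at 300 s. The diffusion default
(2e-4 mm²/s) is of the order of a small gadolinium chelate's diffusivity in
tissue; the default velocity (1.2 mm per interval, i.e. 4 µm/s) sits at the
upper end of reported CSF solute speeds so that per-interval displacements
span several voxels. The additive Gaussian noise default (1 percent-change
unit against a 30-unit bolus) is a free parameter — no measured noise level
for percent-change images is published — and the recovery tests state their
noise explicitly. Raw-signal mode emits three pre-contrast baseline frames
at signal level 100, so the percent-change stage of the pipeline is
exercised end to end.

What the phantoms deliberately do not model: MRI physics (coil profiles,
relaxivity, gating), Rician noise bias, and rat-brain anatomy. Passing
recovery tests therefore demonstrates the estimator's fidelity on data
satisfying its own assumptions — aligned, percent-change, additive-noise
images — not robustness to acquisition artefacts.

# Preprocessing

Percent signal change is computed per voxel against the mean of the
baseline frames (nonpositive baselines are zeroed and counted); frames are
smoothed with a 0.1 mm FWHM Gaussian (separable, mirror boundary, hence
total-preserving; smoothing is applied to percent-change frames — the
ordering is configurable since no published ordering exists); the series is
restricted to a 100-minute window; and finally values are clamped at zero
and offset by 1e-4 of the series maximum, because optimal transport needs
nonnegative mass and noise produces small negatives.

# ICP waveform decomposition

`splitChannels` forms a respiratory channel (zero-phase low-pass at 2 Hz)
and a pulse channel (45-point, order-3 Savitzky-Golay smoothing of the raw
waveform, then a zero-phase high-pass at 5 Hz). Both filters are 4th-order
Butterworth applied forward-backward; the filter family and order are this
package's choice (published work names only the cutoffs), made for
amplitude fidelity and zero phase distortion. The 45-point window is
interpreted as samples, as printed.

Respiratory cycles are delimited by troughs of the respiratory channel with
prominence at least half the channel RMS; the respiratory delta is each
cycle's max-min. The cardiac fundamental is the dominant periodogram
frequency above 3 Hz; pulse pressure is the max-min of the pulse channel
over consecutive windows of one cardiac period. One subtlety is handled
explicitly: a rodent heart rate of ~253 beats/min puts the cardiac
fundamental at 4.22 Hz, *below* the 5 Hz high-pass cutoff, so the filter
cascade itself attenuates the very oscillation being measured (a zero-phase
4th-order Butterworth passes only ~20% of a 4.22 Hz sinusoid's amplitude).
Since the published amplitudes obtained through this channel definition are
plainly unattenuated (~0.5 mmHg pulse pressure at that heart rate), the
package divides the measured window amplitudes by the analytic amplitude
response of the applied Savitzky-Golay + high-pass cascade at the estimated
cardiac fundamental. The correction factor is recorded in the result and
can be disabled (`icpConfig(compensate = FALSE)`). For components well
above the cutoff the factor is ~1 and nothing changes.

`epochSummary` restricts each annotated epoch to its first 10 respiratory
cycles, forms 1-second-interval means of the mean ICP and of the two
amplitude channels (the 1-second averaging is applied to the amplitude
channels — the published description is ambiguous on this), averages over
the epoch, and divides by the baseline epoch, whose normalized values are
exactly 1. Traces may be decimated to 1 kHz first (anti-aliased); tests
confirm full-rate and decimated analyses agree within 1%.

# Lymph-node drainage kinetics

Node time-signal curves are mean in-VOI signals per frame, normalized by
the maximum of the subject's CSF curve (divisor choice `max` or `mean` is
exposed and recorded; only the normalizing VOI is published). Noise
cancellation is a trailing 2-point moving average stamped at the later
time (the alignment is this package's choice), and `tscMetrics` reads time
to peak (earliest maximum on ties), peak magnitude (from the smoothed
curve, consistent with reading the peak time from it) and the trapezoidal
AUC. The gamma-variate generator peaks near 87 minutes by default,
matching deep-cervical-node drainage timescales.

# Voxel-wise statistics

Speed maps are smoothed at 0.4 mm FWHM and compared voxel-wise with a
pooled-variance two-sample t test, one-sided in both directions, with no
multiple-testing adjustment by default (deliberately matching the
analysis practice this pipeline reproduces); Welch and Benjamini-Hochberg
options are labelled extensions. Voxels lacking positive smoothed coverage
in any subject, or with zero pooled variance, are excluded and counted.
Type-I calibration is tested on 20 replicate null cohorts of synthetic
speed maps drawn from one distribution — the statistics module's contract
is tested at the speed-map level, since running hundreds of full inverse
solves per replicate would test nothing additional about the t map.

# Problem sizes and numerical choices

The validation suite runs, by choice, at these sizes: single-subject
recovery on the default 32³ five-frame phantom; the translated-Gaussian
transport benchmark on 32³ with β = 1e5 and 40 Gauss-Newton iterations;
and the two-cohort planted-contrast study (5 + 5 subjects) on a 24³
three-frame phantom with a 1.2 mm-radius contrast sphere whose interior
velocity is exactly 1.5x and whose boundary is smoothed over 0.45 mm. The
smooth edge matters: the estimator regularizes the velocity field, so a
velocity discontinuity is systematically smeared and the regional ratio
diluted; with a resolvable transition the planted factor is recovered
within the stated 20% while every region voxel tests significant in the
correct direction. Degenerate inputs are handled explicitly: identical
frames solve to zero velocity at zero energy; a failed first line search
returns the zero-velocity solution with a warning; empty masks, missing
baselines, and sub-2-frame windows are errors, not silent defaults.

# Known limitations

Single-resolution optimization (no coarse-to-fine), no unbalanced-transport
source term (intrathecal infusion is emulated in the generator, not
modelled in the inverse problem), first-order accuracy of the phantom
integrator, speed averaging over voxels rather than pathline points, and
phantom realism as described above. These bound what the green test suite
demonstrates: correct implementation of the stated model and faithful
parameter recovery under that model's assumptions.
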