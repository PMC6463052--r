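---
title: "Reconstructing embryonic outflow-tract hemodynamics from non-gated 4-D imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing embryonic outflow-tract hemodynamics from non-gated 4-D imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oftflow)
```

## The problem

During the looping stages of heart development (Hamburger–Hamilton stages
HH10–HH24 in the chick), the heart is a beating tube whose outflow tract
(OFT) — the distal segment connecting the ventricle to the arterial
system — functions as a primitive valve: paired endocardial cushions
coapt once per cycle to restrict backflow. The mechanical environment of
the OFT endocardium (wall shear stress, its oscillation over the cycle,
flow volumes) feeds back on morphogenesis, so quantifying it in
individual embryos matters.

Optical coherence tomography (OCT) can image the beating OFT at
140 frames/s as 2-D b-mode planes with co-registered Doppler (beam-axis)
velocities, but a 3-D+time acquisition is impossible directly: the
volume is scanned one cross-sectional plane at a time, with no gating,
so each plane's 200-frame movie starts at an arbitrary, unknown cardiac
phase. `oftflow` implements the complete computational chain that turns
such a non-gated stack into cycle-resolved hemodynamic maps:

1. **phantom** — a synthetic acquisition generator with full ground
   truth (there is no public reference dataset for this kind of scan);
2. **sync** — period estimation and phase alignment that reassembles one
   normalized cardiac cycle of 100 frames;
3. **segment** — lumen (and outer wall) contour extraction;
4. **geometry** — areas, volumes, centerlines, area-motion matrices, and
   structured hexahedral tube meshes;
5. **flow** — quasi-steady incompressible viscous flow with an inverse
   loop that fits the inlet boundary condition to the measured Doppler
   velocity;
6. **hemo** — wall shear stress (WSS), oscillatory shear index (OSI),
   flow volumes, cardiac efficiency, and unrolled endocardium maps;
7. `run_pipeline()` — one-call orchestration with a reproducibility
   manifest.

## The phantom: what it emulates and what it does not

`generate_phantom()` mimics the acquisition geometry: one longitudinal
b-mode/Doppler sequence along the tube plus cross-sectional sequences
every 20 µm (inlet to outlet), each of 200 frames at 140 frames/s, each
starting at a random phase drawn uniformly on [0, 1) — the signature of
an ungated scan. Wall motion follows a traveling-wave model with an
endocardial-cushion constriction,

$$R(s,\phi) = R_0(s)\,\bigl[1 + a\sin 2\pi(\phi - s/w)\bigr]\,
  \bigl[1 - c\,b(s)\,g(\phi)\bigr],$$

with `s` the normalized axial position, `phi` the phase in cycles, `a`
the pulsation amplitude (default 0.22), `w` the wave speed (default 2
tube lengths per cycle, i.e. a half-cycle inlet-to-outlet phase lag of
the kind visible in embryo area-motion plots), and `c` the cushion depth
(default 0.9, which closes the lumen below the segmentation threshold
during part of the backflow phase). The axial velocity field is
quasi-Poiseuille: the local flow rate follows mass conservation in the
deforming tube (inlet waveform minus the upstream lumen-volume rate of
change) and the radial profile is parabolic with no-slip at the moving
wall. Doppler planes record exactly $\cos(\text{beam tilt})$ times the
axial speed (default tilt 45°), zero outside the lumen.

Stage presets (`phantom_preset("HH14")` … `"HH18"`) anchor the cardiac
period (486–507–408–410–400 ms), tube length (0.54–0.78 mm) and radius
scale to the ranges reported for looping-stage chick embryos, with
driving velocities chosen so peak centerline velocities fall in the
measured 43–90 mm/s band. They are plausibility anchors, not
reproductions of any embryo.

Deliberate simplifications: images are rendered as a bright wall annulus
around a dark lumen with additive Gaussian speckle — there is no OCT
physics (attenuation, refraction, shadowing), no bulk embryo motion (the
original protocol discards such scans), and the imaging rasters are
axis-aligned while the beam tilt enters only through the Doppler
projection. Passing tests on the phantom therefore demonstrate the
*algorithms* (synchronization, segmentation, meshing, inverse fitting)
under controlled truth; they do not certify performance on real OCT
contrast.

## Synchronization

The cardiac period is estimated per slice by the **string-length
method**: columns of an m-mode (one pixel line per frame stacked against
time) are folded by a candidate period onto [0, 1), ordered by phase,
and the length of the resulting polyline in (phase, intensity) space is
minimized — a classic period-folding statistic. We grid-search in steps
of 0.1 frame and refine the minimum parabolically; the m-mode is
rescaled to [0, 1] first, which makes the estimate invariant to affine
intensity changes. Per-slice estimates are combined by the median. On
noiseless phantoms the estimate lands within ±0.1 frame of truth; the
package's tests require ±0.5 (noiseless) and ±1 frame (speckled).

Each cross-sectional sequence is pooled into a 200-bin normalized cycle
("pooled frames" of 1/200 cycle; empty bins are filled by circular
linear interpolation) and aligned to the pooled longitudinal m-mode
extracted at the matching position, by maximizing normalized
cross-correlation over circular lags with parabolic sub-bin refinement.
Normalized cross-correlation on mean-subtracted images was chosen as the
similarity metric because it is insensitive to brightness differences
between scan planes; ties break toward the smallest absolute shift.

A refinement pass then compares each aligned slice to its neighbors
(horizontal center-line m-modes), accumulates the pairwise shifts along
the tube with phase unwrapping, and fits a robust low-order polynomial
to the cumulative curve. Because the physical contraction wave makes the
true cumulative phase smooth in space, slices whose residual exceeds a
threshold (default 10 pooled frames = 5% of the cycle) are treated as
synchronization failures and snapped onto the smooth trend; well-aligned
slices are left untouched. This replaces the interactive plot-correction
step of a human operator with an outlier rule plus an optional override
table. Neighbor shifts near half a cycle are flagged as
unwrap-ambiguous.

Finally each sequence is re-sequenced to exactly 100 output frames:
output frame `j` holds cycle phase $(j-\tfrac12)/100$ and is the
circular-linear interpolation of the pooled columns at the aligned
position. Linear interpolation was chosen over splines to avoid ringing
at the bright wall edges. `validate_sync()` closes the loop the same way
the original protocol does: vertical-velocity curves at four
corresponding locations are compared between the longitudinal Doppler
record and the re-sequenced cross-sectional stack (correlation, lag,
RMS).

## Segmentation

The segmenter is deliberately simpler than the double-line
maximum-likelihood/active-contour machinery used on real OCT data: rays
are cast from a seed over 64 angles; the inner wall edge on each ray is
located at the maximum positive intensity gradient and refined by the
mid-level crossing of the edge ramp (the continuum maximum-gradient
point, far less alias-prone than the discrete peak); radii are
median-filtered over angle and low-pass filtered to 8 Fourier
harmonics; vertices are emitted at 64 fixed angles (vertex 1 on the
image +x axis) so contours correspond across slices and phases. A
second pass on the negative gradient beyond the inner edge yields the
outer (myocardial) boundary for wall-area plots. The scheme handles
star-convex lumens only; crescent-shaped partially coapted lumens are a
documented limitation. A slice is flagged fully coapted when the seed
lands on bright tissue or the median radius falls below 3 pixels;
closure is a real feature of cushion-bearing geometries but no standard
numerical criterion exists, so the threshold is this package's own,
surfaced as a parameter.

## Geometry

Lumen volume per phase is the **slab sum** $\sum_k A_k g_k$ with $g_k$
the mean distance between neighboring slice centerpoints (half-gaps at
the two ends — the end handling is our choice). This estimator works
even for phases whose closed slices cannot be meshed (they contribute
zero area). The centerline length is the centroid polyline length,
reported by convention at the minimum-volume (most closed) phase.

Meshing lofts the contours into a structured hexahedral **O-grid**: a
small square Coons-patch core surrounded by rings, so cells stay
well-shaped at the centerline. Two decisions matter numerically:

* contours are resampled to the mesh's circumferential resolution and
  **rescaled to preserve their enclosed area**, which makes the mesh
  volume agree with the slab volume at any angular resolution (a plain
  inscribed polygon at 24 divisions would be ~1% low);
* the core-corner radius is 0.2 of the local radius — with most of the
  disk covered by nearly orthogonal rings, the Poiseuille benchmark
  error at 16/32/48 circumferential divisions is 2.5/0.24/0.10%,
  against ~5/4/3% for the conventional 0.5.

Inlet and outlet are extended by straight segments (3 local diameters by
default, a standard entrance-length allowance at these Reynolds
numbers) whose cross-section tapers smoothly to the area-equivalent
circle over the first diameter; extension cells are tagged and excluded
from every post-simulation analysis. Angular correspondence between
sections anchors vertex 1 to the image +x axis with no twist
minimization — adequate for the phantom's negligible torsion,
a documented limitation for strongly curved real geometries.

## Flow

Each of the 100 phases is treated as an independent steady problem
(quasi-steady assumption), justified a posteriori by the diagnostics the
cycle driver reports: Reynolds numbers below ~5 and Womersley numbers
well below 1, so flow inertia and pulsatile phase lag are negligible.
The solver discretizes incompressible momentum + continuity with
trilinear hexahedral elements for both velocity and pressure (Q1–Q1)
and Brezzi–Pitkäranta pressure stabilization
($\alpha h_e^2/\mu\,\nabla p$, $\alpha = 0.1$ by default). Walls are
no-slip; the inlet carries a uniform normal traction (the unknown of
the inverse problem) and the outlet zero traction. Because the
extensions guarantee developed flow at the end faces, the traction is
equivalently imposed as a uniform end-face pressure; imposing it
strongly on the end pressure nodes removes the stabilization's spurious
boundary flux and restores second-order accuracy — the Poiseuille
centerline error falls monotonically from 2.5% (16 divisions) to 0.1%
(48). The default is the Stokes limit; a Picard-iterated convective
term is available (`include_inertia = TRUE`) and changes low-Re
solutions by under a few percent. Linear systems are solved by a
supernodal Cholesky factorization of the velocity block and
Jacobi-preconditioned conjugate gradients on the pressure Schur
complement (relative tolerance 1e-10).

The **inverse loop** mirrors the embryo-specific fitting strategy:
the inlet traction is updated by secant iteration until the computed
axial velocity at the monitor point — by default the lumen center of
the mid-tube section, configurable — matches the Doppler-derived target
within 1% (the tolerance the original protocol states; the 20-iteration
cap is ours). The secant starts from the known point (0 traction, 0
velocity), so in the Stokes limit, where the response is exactly
linear, it converges in at most two solves from any warm start. Each
phase warm-starts from the previous phase's fitted traction. Phases
with a coapted slice or a tangled loft are skipped; the fraction of the
cycle simulated is reported and expected to exceed 0.6. Doppler targets
are angle-corrected by the known phantom beam tilt by default; the
uncorrected option exists because real systems may report either.

Units are mm / mm/s / Pa throughout: with $\mu$ in Pa·s these are
self-consistent for Stokes flow, and the density (kg/m³) enters only
the convective term (scaled by $10^{-6}$) and the Reynolds diagnostic.

## Hemodynamic metrics

On the no-slip wall the velocity gradient reduces to its wall-normal
part, so the traction is evaluated from a one-sided derivative along
the structured radial node column. A three-point (quadratic) difference
is used rather than a single-layer linear one: the linear difference
has a first-order bias of order $h/R \approx 8\%$ on the default grid,
which would dominate the 5% Poiseuille WSS benchmark; the quadratic
form is exact for parabolic near-wall profiles. The full traction
$\sigma\cdot n = -p\,n + \mu(\nabla v + \nabla v^{T})\,n$ is formed and
the WSS vector is its tangential projection
$\tau = \sigma\cdot n - [(\sigma\cdot n)\cdot n]\,n$, tangent to the
wall by construction.

The oscillatory shear index per wall point is

$$\mathrm{OSI} = \frac12\left(1 -
  \frac{\lvert\int_T \tau\,dt\rvert}{\int_T \lvert\tau\rvert\,dt}\right)
  \in [0, 0.5],$$

with $T$ the **simulated** portion of the cycle: skipped (coapted)
phases are excluded from both integrals, and the quadrature weights are
the per-phase durations (on the uniform periodic grid the trapezoid and
midpoint rules coincide). An all-zero shear history is reported as OSI
0 with a flag rather than 0/0.

Flow rate is the surface integral of $v\cdot n$ over a structured
cross-section (default: the monitor section; any non-extension section
may be chosen, and mass conservation across stations is verified to
1%). Cycle volumes integrate the clipped waveform:
$V_F = \int \max(Q,0)\,dt$, $V_B = \int \max(-Q,0)\,dt$,
$SV = V_F - V_B$, and the cardiac efficiency $\eta = 1 - V_B/V_F$
(undefined and flagged when $V_F = 0$). Mean WSS is reported as the
pooled area-and-time-weighted space-time average, with the
time-then-space variant also exposed, because the averaging order
behind published summary tables is ambiguous. The "maximum backflow
velocity" is the most negative centerline axial velocity over space and
simulated time, since published labels leave the location unspecified.

Unrolled endocardium maps cut the wall surface along θ = π (the image
"top") and flatten it with the inlet at the bottom; resampling onto a
finer grid transports the per-point wall-patch areas the same way and
renormalizes them, so area-weighted means are conserved to better than
2%.

## Problem sizes and numerical defaults

The package's own test and demonstration runs use deliberately modest
sizes, chosen as the smallest configurations on which every algorithmic
property is still measurable: phantoms of 8–31 slices with 120–200
frames, meshes of 16–32 circumferential divisions and 2–4 rings
(roughly 1 000–8 000 cells), and full cycles of 100 phases at the
16-division resolution. The Poiseuille benchmark ladder (16/32/48
divisions) establishes monotone convergence; the mesh-doubling check on
deforming-tube geometries bounds the resolution sensitivity of the
monitor velocity and mean WSS at under 5%, mirroring the validation
logic used for the embryo models. All tolerances that matter — the 1%
inverse-fit tolerance, the 3-pixel closure threshold, the outlier
threshold of the cumulative-phase fit, the stabilization coefficient,
the extension length — surface as user-visible parameters with the
defaults above.

## Known limitations

* The radial segmenter requires star-convex lumens; crescent-shaped
  partially coapted configurations are flagged closed rather than
  traced.
* The loft uses no twist minimization; strongly torsional centerlines
  would shear the angular parameterization.
* The quasi-steady treatment ignores wall-motion-induced flow at nearly
  closed phases (where wall velocity rivals flow velocity) — precisely
  the phases that are skipped as unmeshable.
* The phantom's Doppler noise model is additive Gaussian; real Doppler
  OCT exhibits phase wrapping and angle-dependent dropout that the
  pipeline does not emulate.
* Exact numerical agreement with the original interactive
  implementations (string-length search granularity, manual phase
  correction) is not claimed; the package states its own conventions
  and verifies them against ground truth.
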