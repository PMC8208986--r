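---
title: "Coupled hemodynamics and leukocyte adhesion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled hemodynamics and leukocyte adhesion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Atherosclerotic plaque grows where leukocytes adhere to the endothelium
and transmigrate into the arterial wall, and adhesion is gated by the
local wall shear stress (WSS): high shear washes cells downstream before
bonds form, while low shear — typical of recirculation zones downstream
of a stenosis and of the inner side of tortuous segments — favors
capture. `leukoflow` implements the full model chain needed to test this
mechanism against longitudinal imaging: pulsatile blood flow in an artery
reconstructed from lumen contour frames, WSS extraction on the lumen
surface, transport of free-flowing leukocyte concentration with a
shear-thresholded wall sink, and correlation of the predicted adhesion
profile with the baseline-to-follow-up change in lumen area.

Clinical VH-IVUS datasets of this kind are not publicly distributable, so
the package ships a synthetic-study generator that emulates a
catheter-pullback acquisition (0.5 mm frame spacing, localized stenosis,
tortuous centerline, noisy contours) and a follow-up whose lumen loss is
a controlled function of a supplied adhesion profile. Every stage of the
pipeline is thereby testable end to end without patient data.

## Governing equations

**Flow.** Incompressible Navier–Stokes with constant density
$\rho_f$ and viscosity $\mu$ (Newtonian blood, defaults
$\rho_f = 1060\,\mathrm{kg/m^3}$, $\mu = 3.5\,\mathrm{mPa\,s}$; the
rigid-wall assumption is inherited from the modeling framework). The
flow is driven by a periodic triphasic bulk-velocity waveform
$U_\mathrm{bulk}(t)$ (period $T = 0.8$ s, mean $0.384$ m/s by default)
imposed through a parabolic inlet profile
$u(r) = 2 U_\mathrm{bulk} (1 - (r/R)^2)$, with a convective (radiative)
outlet condition.

**Leukocyte transport.** For each species $l$ the normalized
concentration $\rho_l$ obeys an advection equation with a wall sink,
$$\partial_t \rho_l + \mathbf{U} \cdot \nabla \rho_l = -R_l(W\!S\!S),$$
where the sink acts only at the endothelium and only where the
instantaneous shear magnitude is at or below a species threshold:
$$k_l(W\!S\!S) = \begin{cases} f_l(W\!S\!S) & |W\!S\!S| \le W\!S\!S_{th} \\ 0 & \text{otherwise.} \end{cases}$$
The realized sink in *tracked* mode is $R_l = k_l \,\rho_l$: a pure
function of WSS cannot simultaneously produce the documented
depletion-limited reduction of downstream adhesion, so the rate
coefficient multiplies the local free concentration and reduces to the
pure-WSS rate wherever $\rho_l = 1$. The *uniform* comparison mode
accrues $k_l \cdot 1$ without touching the field. The functional form
$f_l$ is pluggable; the default is a linear ramp from $k_{\max}$ at zero
shear to zero at the threshold (the threshold itself is adhesive, per
the $\le$ in the rate law). Only the neutrophil parameters
($W\!S\!S_{th} = 1.2$ Pa, reference concentration
$4.34\times10^9\,\mathrm{l^{-1}}$) are anchored to published values;
monocyte and lymphocyte defaults are provisional placeholders and must
be configured for quantitative work.

**Averages.** $\langle W\!S\!S\rangle$ denotes the time average over
whole cardiac periods at a wall point; the sectional average weights the
time average by $r\,d\theta$ and normalizes by the contour perimeter
$C$:
$$\overline{W\!S\!S}(s) = \frac{1}{C}\int_0^{2\pi} \langle W\!S\!S\rangle\, r\, d\theta .$$
Note $r\,d\theta$ is not the arclength element for non-circular
contours; the printed weighting is the default and an exact-arclength
variant is provided (`weighting = "arclength"`). $C$ is evaluated by
periodic trapezoid quadrature of $\sqrt{r^2 + r'^2}\,d\theta$, which
makes a circular contour with constant shear average exactly to that
constant; a chord-polygon perimeter would bias the result by
$O(M^{-2})$.

**Correlation.** The adhesion profile $\bar R_l(s_j)$ (sink averaged
over the cross-section bins and the retained cardiac period) is
registered to the frame grid by bin-averaging within $\pm$ half a frame
spacing and correlated with $\Delta A(s_j) = A_\mathrm{baseline} -
A_\mathrm{follow\text{-}up}$ (positive = narrowing) by a Pearson
coefficient with population ($1/N$) moments — exactly the printed
formula, so the reported standard deviations differ from the
$1/(N-1)$ convention although the ratio does not.

## Numerical method

The solver is a uniform staggered-grid (MAC) finite-difference code with
the lumen represented by an immersed boundary:

* **Space**: second-order conservative central differences for advection
  and diffusion; uniform spacing $h$ in all directions.
* **Time**: explicit low-storage third-order Runge–Kutta (Williamson)
  rather than the also-common Adams–Bashforth 2: AB2 with non-upwinded
  central advection has no stability margin on the imaginary axis,
  whereas RK3 is stable up to a CFL of order one at the cell Reynolds
  numbers of the validation cases.
  Diffusion is explicit; the step is the minimum of the advective CFL
  bound and a fraction (default 0.4) of the diffusive limit
  $h^2/(6\nu)$.
* **Projection**: fractional step with the previous pressure gradient in
  the predictor and a single pressure-Poisson correction per step,
  solved matrix-free by conjugate gradients with a warm start. The
  discrete divergence and the Poisson operator are *masked consistently*
  on the open fluid-face network, so the post-step divergence of every
  fluid cell is bounded by the solver tolerance (`poisson_rtol`,
  default `1e-8` relative).
* **Immersed boundary**: direct forcing. Faces inside the wall are
  zeroed; faces within one spacing of the surface are set from a
  quadratic no-slip profile through the wall (zero) and two probe points
  one and two spacings along the inward normal, with probes sampled by
  3×3×3 quadratic Lagrange interpolation; solid faces just outside the
  wall carry the ghost extension of the same wall quadratic. The linear
  (Fadlun-style) variants of each ingredient were measured during
  development to leave a systematic 4–9% wall-shear deficit at 24 cells
  per diameter; the quadratic scheme restores second-order grid
  convergence on plane Poiseuille (the suite computes the observed order
  and requires > 1.5) and brings pipe wall shear well inside the 5%
  analytic tolerance.
* **WSS extraction**: at each wall sample the tangential velocity is
  sampled at $1h$ and $2h$ along the inward normal and differentiated
  with the one-sided second-order stencil (zero at the wall) — exact for
  parabolic shear layers. Samples whose probes leave the fluid are
  flagged invalid and excluded (a sectional average with more than 10%
  invalid samples is itself flagged).
* **Scalar transport**: conservative first-order upwind (positivity
  preserving by construction), inlet value held at 1, convective
  outflow, and no scalar flux through wall-adjacent faces. The sink is
  applied in the single layer of wall-adjacent fluid cells with exact
  exponential decay per step, the removed amount credited to the nearest
  wall sample's $(s, \theta)$ ledger bin and normalized by the bin's
  endothelial area. Flux bookkeeping at the boundaries makes the global
  balance (influx − outflux − storage − ledger) close to machine
  precision, which is how the conservation criterion is verified.
* **Modes**: one code path covers 3D artery runs (inlet/outlet), planar
  2D channels (one periodic cell in the third direction), and axially
  periodic pipes driven at a prescribed bulk velocity (equivalent to a
  uniform pulsatile pressure gradient) for the analytic oracles.

## Geometry

Contour frames are stacked along the centerline in planes normal to the
local tangent. In-plane orientation propagates by a rotation-minimizing
(parallel-transport) frame: a Frenet frame is undefined at inflection
points of realistic centerlines, and the acquisition convention is not
recoverable, so parallel transport is the package's own choice.
Centerline curvature so high that adjacent frame planes intersect inside
the lumen is rejected with the offending arclength.

Flow extensions follow the published construction: a straight inflow
channel (default $5D$) whose circular inlet has the mean radius of the
first frame, blending linearly (smoothstep) into the first contour over
the final $2D$; and an outflow channel (default $8D$) whose centerline
eases cubically until the tangent is axis-parallel while the contour
relaxes to circular. The clinical segment is left bit-identical.

Point membership for the flow grid uses a radial signed distance in the
normal plane of the nearest finely-resampled centerline point — exact
for circular cross-sections and accurate to the contour's deviation from
circularity otherwise; cross-sections are star-shaped by construction
(positive radii on a monotone azimuth grid), so the sign test is exact.

## The synthetic study: what it emulates, and what it does not

`synth_baseline()` draws a stated world chosen once: mean diameter 2 mm,
frames every 0.5 mm, one cosine-squared stenosis (default severity 0.4
over 6 mm), a smooth tortuous centerline that starts axis-parallel
(amplitude 0.4 mm, wavelength 10 mm), and mild low-order Fourier contour
non-circularity (3%), with every contour rescaled so its polygon area
matches the target area profile exactly. `synth_followup()` shrinks
contours isotropically by $A_b - \alpha \bar R - \varepsilon$,
$\varepsilon \sim N(0, \sigma_g)$ truncated at 5% of baseline area.
Growth-noise defaults ($\sigma_g = 0.1\,\mathrm{mm^2}$) sit inside the
published per-patient spread of mean/maximum lumen change
(≈0.1–1.3 mm²). All randomness flows from the spec seed and is
byte-reproducible.

The generator does **not** emulate imaging physics, tissue
classification, catheter rotation artefacts, eccentric plaque growth
(an azimuthally localized option exists for exercising resolved
ledgers), or vessel-wall motion. A green end-to-end test therefore
establishes that the *model chain* — geometry, flow, shear, sink,
correlation — is internally consistent and recovers planted signals; it
says nothing about patient-level predictive power.

## Scaled-down validation runs

The test fixtures deliberately run at desk scale: coarse grids (10–32
cells per diameter), shortened nominal periods for steady cases, reduced
Reynolds numbers (bulk 0.05–0.1 m/s instead of 0.384 m/s), and shortened
extensions for the centerline-comparison case. The analytic oracles
(plane/pipe Poiseuille, oscillatory tube flow at Womersley number 2.5)
are exact at any scale; the qualitative criteria (downstream adhesion
peak, tracked-vs-uniform depletion, tortuosity-induced azimuthal shear
variability, $\overline{W\!S\!S}\propto R^{-3}$) are scale-robust
properties of the modeled physics. Clinical-scale Reynolds and Womersley
numbers are reachable with the same code by raising the resolution and
budget.

## Numerical choices and degenerate inputs

* Tolerances: Poisson relative residual `1e-8`; waveform table mean must
  match the declared mean within 0.1% (tables can be rescaled exactly);
  scalar CFL guard uses the sum of component maxima (sufficient for
  positivity of the upwind step).
* Uniform concentration is preserved exactly by the transport step away
  from the immersed wall; in wall-adjacent cells it drifts only by the
  (solver-tolerance) no-slip residual of the forced faces, which is why
  the constancy test asserts `1e-6` rather than machine zero.
* Zero-variance inputs to the correlation raise an explicit error rather
  than returning 0; partial-period inputs to time averaging are
  rejected; full lumen occlusion (severity 1) is rejected at
  specification time; negative shear to the rate law is an error rather
  than silently clamped.
* Waveform instants where the triphasic pulse crosses zero make a
  *relative* inlet/outlet flux mismatch ill-posed; diagnostics normalize
  such instants by 5% of the mean-flow scale (the absolute mismatch is
  at solver tolerance at every step).
* The default waveform *shape* is a representative triphasic left
  coronary pulse (systolic peak, brief end-systolic reversal, dominant
  diastolic peak); only its period and mean are anchored to published
  values, and any tabulated waveform can be supplied from file.

## Known limitations

Rigid walls; Newtonian rheology; fully activated endothelium (spatially
uniform rate law); no plaque growth or geometric remodeling — the model
predicts adhesion, and the correlation stage is the only contact with
disease progression. First-order upwind transport is diffusive; a
flux-limited variant is a natural extension. The monocyte/lymphocyte
parameter defaults are placeholders. The azimuthal weighting of the
sectional shear average follows the printed $r\,d\theta$ form by
default, which differs from the true arclength average on non-circular
contours; both are available because the original convention is not
recoverable from the text.
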