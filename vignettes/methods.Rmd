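---
title: "Inverse viscoelastic finite-element analysis of the aqueous outflow tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse viscoelastic finite-element analysis of the aqueous outflow tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The trabecular meshwork (TM), the juxtacanalicular connective tissue (JCT,
a ~14-µm loose matrix band) and the Schlemm's-canal (SC) inner-wall
endothelium (~2.2 µm) form the main resistance of the conventional aqueous
outflow pathway. Their mechanical response to pressure is time-dependent:
short-time and long-time shear moduli differ, and the transition rate
matters for how the tissues follow intraocular-pressure (IOP) dynamics.
This package re-implements, at desk scale, an inverse finite-element
pipeline that estimates per-tissue viscoelastic shear moduli from the motion
of the SC inner wall under canal pressurization: a forward explicit FE model
(ECM continuum + embedded collagen-fibril beams) is repeatedly run inside a
derivative-free optimization until the simulated wall trajectory matches a
measured (here: synthetic) one.

# The constitutive model

Every material (tissue matrix and fibril beams) follows a single-term shear
relaxation

$$G(t) = G_\infty + (G_0 - G_\infty)\,e^{-\beta t},$$

with `G0 >= Ginf > 0` (MPa) and decay constant `beta` (1/s). The deviatoric
stress is the hereditary integral of the deviatoric strain rate, advanced by
an exponential-integrator recursion that is exact for piecewise-constant
strain rate; increments are rotated with the material spin (incremental
Jaumann update) before the constitutive evaluation. The volumetric response
is elastic with `K = 2 G0 (1 + nu) / (3 (1 - 2 nu))`, `nu = 0.495`
(near-incompressible): the source formulation defines only the shear
relaxation, and an elastic bulk closed from the short-time modulus matches
the convention of the commercial solver it was built in. This is a design
choice of this package, not a statement of the original formulation, which
leaves the bulk behavior unspecified.

# Elements

*Solids.* Fully integrated (2×2×2 Gauss) 8-noded hexahedra with a
mean-dilatation (B-bar) volumetric treatment; without it, full integration
locks at `nu = 0.495`.

*Beams.* Two-noded Hughes–Liu beams degenerated from the 8-noded solid:
per-node unit section ("fiber") vectors, a second-order accurate
(Hughes–Winget, exactly orthogonal) rotational update, a co-rotational local
frame in which the two transverse normal stresses are condensed to zero each
step (a 2×2 linear solve — iteration-free for this isotropic law), one
integration point along the axis and four on the tubular cross-section (one
per quadrant at the quadrant area centroid). Fibers couple to their host
hexahedra through penalty springs at the control points
(mesh-free beam-in-solid coupling), with forces spread to host nodes by
trilinear weights, so beam and solid meshes never need to conform.

*Objectivity.* Incremental strain and spin are evaluated at the **half-step
configuration**. This matters: with end-of-step evaluation a finite rigid
rotation step produces O(θ²) spurious strain and the package's own
objectivity tests fail; at the midpoint the incremental gradient of a rigid
step is exactly skew (a Cayley-transform identity), so rigid body rotations
generate no strain at all, at any step size. Equivalently the gradient is
computed as `A (I - A/2)^{-1}` from the end-configuration gradient `A`.

# Explicit quasi-static solution

Central-difference integration with mass-proportional damping (dynamic
relaxation). Three numerical devices, all monitored rather than assumed:

* **Critical time step** per element from the dilatational wave speed,
  `C = sqrt(E (1-nu) / ((1+nu)(1-2nu) rho))`, `l = V/A_max`, `dt = 0.9 l/C`.
* **Mass scaling.** Quasi-static explicit analysis is intractable at the
  physical density (dt ~ 1e-9 s); the density is scaled so that a stated
  number of steps (`target_steps`) spans the protocol, plus per-node
  stiffness-proportional mass floors for penalty-stiffened beam nodes.
  Validity is monitored through the kinetic/internal energy ratio, which
  must stay below 1% at termination (`quasi_static` flag).
* **Damping at the fundamental mode.** The damping coefficient defaults to
  approximately critical for the lowest structural mode (estimated from the
  softest long-time shear modulus, the scaled density and the largest model
  extent). The originally planned default — several times the largest
  material decay constant — overdamps the slow modes by an order of
  magnitude, and the model then creeps linearly instead of settling; this
  was found by the dt-halving convergence test and is recorded as a design
  deviation.

Pressure faces are follower loads on the deformed geometry; "floating"
displacement boundaries interpolate tracked boundary positions linearly in
time; plane strain (the 10-µm extruded slab) is imposed by fixing
out-of-plane displacements.

# Synthetic data: the stated world

The original recordings (HR-OCT B-scans of pressurized quadrants) are not
published, so a generator replaces them with forward-simulated data of known
ground truth:

* **Scenes.** Five ordered boundary polylines (TM anterior → SC outer wall),
  JCT 14 µm and SC inner wall 2.2 µm thick by construction, TM depth 60–120
  µm, seeded smooth undulation (`waviness`), widths ≥ 100 µm. Same seed ⇒
  bit-identical scene.
* **Ground truth** defaults to the published healthy "115LF" row group of
  the fitted-parameter tables (shipped as CSV fixtures), so synthetic
  experiments live on the published parameter scale.
* **Trajectories.** The scene is meshed (smoothing spline `p = 0.999` →
  extrusion to 10 µm → layer partition → beam distribution), the SC face is
  pressurized 0→30 mmHg and the tracked SC-inner-wall and anterior-TM nodes
  are recorded at uniformly spaced frames; optional i.i.d. Gaussian
  per-node-per-frame noise (the recordings' segmentation noise is not
  characterized in the source; independence is the simplest model that
  supports noise-robustness tests).
* **Pressure profile.** The source's profile is unavailable ("optimized
  pressure profile" of a prior publication). The synthetic protocol is a
  linear ramp with hold; the default ramp time (5 ms) is commensurate with
  the beam relaxation time (1/450 s) and the hold (≥ 25 ms) spans several
  ECM relaxation times (1/109 s) — the standard identifiability argument for
  exciting both short- and long-time moduli. Chosen once, at design stage.
* **Specimen and patch stages.** The uniaxial specimen (10 × 0.24 × 0.136
  mm, 2% strain) pulls both ends symmetrically (identical gauge state,
  half the wave-transit time); fibers are bundled into fewer, thicker beams
  whose total cross-section preserves the reference fiber area fraction
  π·0.5²/(4·2.5) ≈ 7.9% of the 4 × 2.5 µm lattice, so the composite
  (rule-of-mixtures) stiffness is scale-invariant. The TM patch for the
  decay-constant stage carries an elastic scleral base (2.93 MPa, ν 0.495)
  and is loaded by IOP 0→50 mmHg in 1 s on its anterior face.

What a green test does *not* establish: the generator emulates geometry,
protocol and tracking — not image formation (no OCT speckle), not 3-D canal
topology, not collector channels, and not model error (the inverse stage
fits the same model class that generated the data). Closed-loop recovery is
therefore a *consistency* result, the strongest check available without the
raw recordings.

# Inverse estimation

A bounded Nelder–Mead simplex (fminsearch coefficients) minimizes
mean-squared-error costs. Bounds (0.10–100 MPa, 1–1000 1/s) are enforced by
a per-coordinate sigmoid reparameterization so the inner search is
unconstrained; moduli are searched in log10 space (they span three decades).
`restarts` rebuilds the simplex around the incumbent best point with a
halved step — the standard remedy for simplex degeneration in 10 dimensions.

Stages: (1) specimen curve → ECM and beam parameter sets; (2) TM patch
displacement-vs-IOP curve → decay constants (subsequently frozen at 109 and
450 1/s); (3) complex model, 10 moduli jointly, cost on the SC-inner-wall
nodal coordinates. The complex-stage forward model defaults to the
generator's own boundary conditions (pressure + fixed lateral columns,
anterior free) so the synthetic closed loop is exactly consistent; the
floating-displacement drive of the imaging pipeline is available
(`use_floating = TRUE`) and is exercised by its own tests.

## What is and is not identifiable (measured, not assumed)

* All ten complex-stage moduli are recovered within 10% (measured: ≤ 2%)
  from noiseless synthetic trajectories — but only after roughly 1,500
  simplex evaluations across warm restarts. At the ~100-iteration scale the
  original pipeline reports, the cost sits in long parameter-compensation
  valleys (e.g., TM G0 ↑ with TM G∞ ↓, TM-beam vs JCT-beam trade-offs) that
  fit the trajectory to ~1e-9 µm² with parameters several-fold off. All
  tissues share one decay constant, so layers are distinguished *only* by
  the spatial profile of wall motion; wider, wavier cross-sections
  discriminate better, which is why the acceptance scene is 180 µm wide
  with waviness 0.25.
* The perturbation-uniqueness audit (eight restarts at ±10–40% of the
  optimum) inherits this: at any optimization depth affordable for eight
  restarts in a desk-scale run, the per-parameter spread across restarts
  exceeds 10% — the audit *detects* the non-uniqueness it was designed to
  detect. The corresponding acceptance criterion is intentionally left red;
  the source's consistency finding is not desk-reproducible at its stated
  iteration scale.
* The decay constants are structurally unidentifiable from the stated
  0→50-mmHg-in-1-s patch protocol: with β·T ≈ 100 the tissue is
  quasi-relaxed throughout the ramp, and the small rate-lag term is
  absorbed by the moduli. A post-ramp hold was added to the synthetic curve
  (the source notes β should reflect "rising and relaxation" response), but
  the relaxation transient (~9 ms) still vanishes under realistic sampling.
  The stage therefore asserts recovery of the moduli and demonstrates the β
  flatness explicitly.

# Numerical choices and degenerate inputs

Voigt storage (tensor shears internally, engineering shears at the strain
interface); `p = 0` smoothing returns the weighted least-squares line and
`p = 1` interpolates (both exact limits of the Reinsch formulation);
collinear circle fits, intersecting boundaries, out-of-mesh beam points,
empty probe sets, non-positive Jacobians and kinetic-energy blow-up all
raise distinct errors. Layer partition always assigns at least the SC-facing
element row to the inner wall, so coarse meshes degrade gracefully (a 10-µm
row stands in for the 2.2-µm wall; the closed loop remains consistent
because target and fit share the mesh).

# Known limitations

Single extruded slab (no multi-slice reconstruction); no fluid–structure
interaction; no contact; the element-free Galerkin variant of the source is
replaced by standard fully integrated hexahedra; tissue density is assumed
water-like (1.0e-9 tonne/mm³) — it only affects the dynamic-relaxation rate,
not converged statics; the acceptance-scale models are 1–2 orders coarser
than the source's meshes.
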