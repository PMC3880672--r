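---
title: "Residual stress in passive myocardium: model, estimators and the cylinder surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual stress in passive myocardium: model, estimators and the cylinder surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resmyo)
```

## Scope and configurations

`resmyo` models the passive (diastolic) mechanics of ventricular
myocardium with residual stress at the scale of a thick-walled
incompressible cylinder. Three configurations matter:

* **B₀**, a fictitious stress-free configuration (the tissue never
  occupies it; the pre-deformations that create residual stress are
  generally incompatible);
* **B_r**, the *unloaded* configuration — no external loads, but carrying
  the residual Cauchy stress τ, which is symmetric, non-uniform, and
  self-equilibrated (Div τ = 0 with traction-free boundary);
* **B_t**, the current configuration under an endocardial pressure load.

All constitutive evaluation takes B_r as the reference; F, C = FᵀF and
B = FFᵀ measure deformation from B_r, and incompressibility det F = 1 is
enforced through a Lagrange pressure p.

## The constitutive law

The baseline energy is the orthotropic Holzapfel–Ogden form in the
invariants I₁, I₄f, I₄s, I₄fs of C and the fibre/sheet/normal triad
(f₀, s₀, n₀), with eight non-negative parameters (moduli a, a_f, a_s,
a_fs in kPa; exponents b, b_f, b_s, b_fs dimensionless). The fibre and
sheet terms carry a tension-only switch: they contribute only when
I₄f > 1 or I₄s > 1, since myocytes and collagen fibres support extension
but buckle in compression. The switch applies to the I₄f and I₄s terms
only — never to the coupling term I₄fs or to the residual terms — and
both energy and stress are continuous across I₄i = 1 because the
prefactor (I₄i − 1) vanishes there.

Residual stress enters through invariants coupling τ with C:
I₆ = tr(τC), I₇ = tr(τC²), and optionally I₈ = tr(τ²C), I₉ = tr(τ²C²).
Invariants coupling τ, C *and* the fibre directions are deliberately not
included; with the small residual stresses estimated below their effect
is higher order. Two formulations are provided:

* **simple** — `W += I₆/2`; Cauchy stress contribution Σ = FτFᵀ. This is
  the small-strain reduction (B ≈ I) of the general form.
* **extended** — `W += I₆/4 + I₇/8`; contribution Σ/2 + (ΣB + BΣ)/4.

The constant weights are not free: at F = I the stress of the law must
reduce to τ itself (the unloaded state is an equilibrium state of the
model). That fixes p_r = 2W₁ = a, 2(W₆ + 2W₇) = 1 and W₈ + 2W₉ = 0, which
`consistency_constants()` reports and the tests verify to machine
precision. A `model = "full"` research mode accepts user-supplied
constant weights W₆…W₉ satisfying the same conditions, including the
τ²-terms; it is off by default because the estimated residual stresses
(|τ| ≲ 0.3 kPa) make those terms negligible. The two printed forms of
the matrix exponent in the source material differ (`exp[b(I₁−3)]` vs
`exp[b(I₃)]` in one display); the former is used throughout, the latter
being an evident typographical slip.

When τ is diagonal in the fibre frame, I₆ reduces to invariants already
present in the law, I₆ = τ_nn I₁ + (τ_ff − τ_nn) I₄f + (τ_ss − τ_nn) I₄s
(using I₁ = I₄f + I₄s + I₄n for an orthonormal triad); `reduced_I6()`
implements this and the tests confirm it equals tr(τC) directly. I₂ is
computed by `strain_invariants()` for completeness but appears in no
energy; no role is invented for it.

### Parameters

The eight default parameters (a = 0.236 kPa, b = 10.81, a_f = 20.04 kPa,
b_f = 14.15, a_s = 3.72 kPa, b_s = 5.16, a_fs = 0.41 kPa, b_fs = 11.3)
are a published fit of the law to canine simple-shear data. They are
shipped as a key-value configuration file
(`inst/extdata/material_params.cfg`) rather than hard-coded: printed
parameter tables are easy to mis-transcribe, and users routinely
substitute their own fits. The parser is strict — all eight keys, no
others.

### Lagrange pressure

For an incompressible material p is statically indeterminate pointwise;
it is a field determined by equilibrium and traction boundary conditions,
not a material output. `cauchy_stress()` therefore returns the stress up
to −pI unless the caller supplies p, and `pressure_for_traction()` closes
p from one prescribed normal stress. Inside the tube solvers p is
eliminated analytically: the radial equilibrium ODE involves only the
p-free difference σ̂_θθ − σ̂_rr, and p is recovered afterwards from the
integrated radial stress.

## Estimating the residual stress

### From measured residual strains

Transmural residual strains are reported as the Euler–Almansi tensor e₀
of B_r relative to B₀, with components in the fibre frame. The left
Cauchy–Green tensor of the pre-deformation is B⁽ʳ⁾ = (I − 2e₀)⁻¹, which
must be positive definite (strain components of 0.5 sit on the
admissibility boundary and are rejected with the offending wall depth
named). Two constitutive assumptions are offered:

* **isotropic** (default): the fibres are taken as relaxed in B_r —
  consistent with the observation that collagen is coiled and wavy in
  unloaded tissue — so only the matrix term responds:
  τ = a·exp[b(I₁⁽ʳ⁾ − 3)]·B⁽ʳ⁾ − aI, with I₁⁽ʳ⁾ = tr B⁽ʳ⁾ and p_r = a.
* **orthotropic** (opt-in): the full law, tension switch included,
  evaluated on F₀ = (B⁽ʳ⁾)^{1/2} (the symmetric square root; the rotation
  part of F₀ is immaterial since the energy sees only C₀ = B⁽ʳ⁾). With
  the anisotropic moduli zeroed it reduces exactly to the isotropic
  estimate. Where the fibre pre-strain is tensile (epicardium) the active
  fibre term amplifies |τ_ff| substantially.

Shear strain components must be small (|e₀,ij| ≤ 0.02 by default); they
are zeroed before the estimate — making the principal-direction
assumption explicit and checkable — or retained with
`zero_shear = FALSE`. Larger shears are an error, never silently
truncated. Note the sign logic: a *compressive* fibre pre-strain (tissue
held shorter than its stress-free length) yields a *compressive* τ_ff;
an isotropic compressive e₀ = −εI likewise yields an isotropic
compressive τ. Fields estimated this way are generally **not**
self-equilibrated (measured mean strains are incompatible);
`divergence_diagnostic()` reports the radial equilibrium residual but
never rejects.

### The synthetic strain fixture

Published transmural residual-strain measurements exist as figures, not
machine-readable tables, so `generate_strain_fixture()` produces a
synthetic profile with the measured *structure*: smooth low-order
polynomials in the wall-depth fraction ξ ∈ [0, 1]; fibre strain from
−0.04 (endocardium, compressive) to +0.06 (epicardium, tensile) with a
slight bowing proportional to the span; smaller cross-fibre and radial
components of opposite trend; shears ≤ 0.005; all magnitudes ≤ 0.1. A
seeded smooth perturbation (sd 0.002 on two interior modes vanishing at
the surfaces) emulates specimen variability while keeping the surface
signs deterministic; output is byte-identical given the seed and the
caller's RNG stream is untouched. The fixture does **not** emulate
regional heterogeneity, base–apex variation, measurement noise
correlation, or strain incompatibility beyond what the smooth profiles
imply — passing tests demonstrate the estimator pipeline, not agreement
with any specific animal dataset.

### By the opening-angle method

A radially cut ring springs open into a sector (inner/outer radii R_i,
R_o, opening angle α); closing it back (circumferential stretch
κ = 2π/(2π − α), axial stretch λ_z) generates the residual stress of the
intact tube. The closing map r(R) = √((R² − R_i²)/(κλ_z) + r_i²) is
exactly isochoric. The radial equilibrium ODE
dτ_rr/dr + (τ_rr − τ_θθ)/r = 0 is integrated from the inner surface with
τ_rr(r_i) = 0, and the closed inner radius r_i is found by bracketed root
finding (bracket [0.2, 2]·R_i, tolerance 1e−10 cm) so that τ_rr also
vanishes at the outer surface. The default constitutive response of the
closing deformation is the **isotropic matrix part** of the law — the
same assumption as the strain-based estimator, keeping the two routes
mutually consistent — with the full orthotropic law as an option (frames
assigned by closed-tube depth fraction). For the reference sector
(α = 85°, R_i = 2.5 cm, R_o = 4.2 cm, λ_z = 1) the solved field runs from
τ_θθ ≈ −0.12 kPa at the endocardium to +0.08 kPa at the epicardium.
Single-cut opening angles likely under-release ventricular residual
stress (reported rodent mean angles are nearer 45°, yet matching measured
strain magnitudes needs ≈ 85°); this motivates offering the strain-based
route alongside, and is a scientific caveat, not something the package
can test.

`rotate_to_fibre_frame()` re-expresses the cylindrical field in the local
fibre frame (an orthogonal change of basis, trace- and
eigenvalue-preserving). The resulting fibre-frame shears are small
relative to the normal components for physiological fibre rules and are
zeroed by default, with `keep_shear = TRUE` to retain them.

## The fibre rule and frame convention

The transmural triad follows a linear rule in wall depth: helix angle φ
from +60° (endo) to −60° (epi), sheet angle β from −45° to +45°, with
f₀ = cos φ e_θ + sin φ e_z, s₀ = e_r rotated about f₀ by β, and
n₀ = f₀ × s₀. At φ = β = 0 this puts the sheet axis radial
(transmural) and the sheet-normal axial — the usual laminar-architecture
convention. The endo/epi assignment of the ±60° range is not dictated by
the measurements the rule abstracts; both orientations are exposed via
the `fibre_rule()` arguments, and +60 → −60 is the default. The rule is
an analytic stand-in for rule-based fibre generation on 3-D meshes, not a
reconstruction of any particular ventricle.

## The inflation surrogate

The LV wall is idealised as the unloaded tube (for opening-angle residual
stress, the closed tube of that solution), inflated by an endocardial
pressure P (mmHg at the interface, 1 mmHg = 0.133322 kPa internally)
under plane axisymmetric deformation with unit axial stretch. The
deformed inner radius is found by shooting on the radial equilibrium
equation with σ_rr = −P inside and 0 outside; incompressibility of the
map is exact, so the wall cross-section is conserved to machine
precision. The total stress adds the residual contribution of the chosen
formulation, with τ interpolated across the wall componentwise by
monotone cubic (Fritsch–Carlson) splines in the depth fraction —
monotone interpolation avoids overshoot between coarse strain samples.
Reported fibre-frame stresses σ_ff, σ_ss, σ_nn are normal stresses along
the *deformed* unit axes.

Two caveats are intrinsic to the 1-D surrogate. First, only the radial
equilibrium equation is enforced; the small σ_rθ, σ_rz shear components
generated by an out-of-plane sheet axis are reported but not balanced
(the classical thick-walled-tube treatment). Second, absolute stresses
depend on geometry and are **not** comparable with 3-D image-derived
models; only directions and relative magnitudes of residual-stress
effects are meaningful here — which is exactly what the acceptance
properties assert: fibre stress decreases at the endocardial surface and
increases at the epicardial surface when τ is included, the relative
effect weakens from 3 to 8 mmHg as the elastic stresses grow around the
fixed τ, the simple and extended formulations agree within a few tenths
of a percent for realistic τ, and normalised pressure–volume curves with
and without τ coincide within fractions of a percent. `surface_summary()`
averages over a thin band (default 5% of wall depth) adjacent to each
surface so that a mean ± sd is well defined on the axisymmetric profile.

## Recovering the unloaded configuration

Imaged geometry is loaded even in diastole, so the reference state must
be found inversely. At cylinder scale the geometry is two radii and the
backward-displacement iteration is
x_{k+1} = x_meas − (inflate(x_k, P) − x_k), starting from the measured
geometry. Convergence demands both radii within 1e−4 cm and cavity area
within 0.5%; the iteration count is capped at 50 and failure raises a
structured error carrying the full history. On the reference fixture the
mismatch decreases monotonically and reaches the percent level within a
handful of iterations (3–4 at diastolic pressures). Because tracking a
residual-stress field through changing reference geometries is ambiguous,
the default regenerates τ for each unloaded estimate (for the
opening-angle source, the sector is rescaled at fixed α so its closed
tube matches the current estimate; a wall-area identity plus one root
solve); `freeze_tau = TRUE` instead fixes the field computed at the first
iterate. Neither behaviour is claimed to be "the" correct one — the
ambiguity is intrinsic — so both are exposed.

## Numerical choices

* **Quadrature**: adaptive `stats::integrate` (absolute tolerance 1e−8
  kPa) inside the root solves, with a fixed-grid composite-Simpson
  fallback (4001 points) because the tension-only switches make the
  integrand piecewise smooth and the adaptive rule can refuse near a kink
  under tight tolerances. Cumulative radial profiles integrate the ODE
  with `deSolve` (rtol 1e−10, atol 1e−12).
* **Root solves**: `stats::uniroot`, tolerance 1e−10 cm (opening angle)
  and 1e−8 cm (inflation); brackets [0.2, 2]·R_i and [0.6, 2.5]·r_i with
  explicit bracket-failure errors reporting the endpoint residuals.
* **Grids**: 200 radial points by default; tests use 40–120 and the
  acceptance script 200. These choices put discretisation error far below
  reporting precision for the smooth profiles involved.
* **Symmetry/validation tolerances**: 1e−8 relative for tensor symmetry
  and frame orthogonality; inputs beyond tolerance are errors, never
  silently symmetrised (except the documented shear-zeroing rules).
* **Verification**: the analytic stress is checked against a central
  finite difference of the energy, σ + pI = F ∂W/∂F (step 1e−5, observed
  agreement ≈ 5e−8 relative); the identity-configuration consistency and
  the invariant identities are asserted at machine precision; equilibrium
  of returned fields is re-checked by independent trapezoid integration.
  A finite-difference diagnostic of a *tabulated* field is dominated by
  grid discretisation (second order in spacing), so solver-accuracy
  claims are tested through the boundary residuals and independent
  quadrature instead.

## Known limitations

* One-dimensional surrogate: no apex/base effects, no longitudinal
  curvature, no 3-D fibre dispersion; absolute stresses are
  geometry-specific.
* Passive diastole only: no active tension, viscoelasticity, growth or
  remodelling; τ–fibre coupling invariants are excluded, so conclusions
  do not extend to systolic strain levels.
* The strain-based τ is not self-equilibrated; attaching it to the tube
  shifts the true equilibrium unloaded state slightly (reported by the
  divergence diagnostic, quantified by the σ ≈ τ check at zero load,
  ~1e−3 kPa for the opening-angle field and larger for strain-based
  fields).
* Opening-angle fields assume complete release by a single radial cut.
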