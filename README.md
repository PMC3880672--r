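# resmyo

Residually stressed passive myocardium mechanics at cylinder scale.

Even with all external loads removed, the ventricular wall is not
stress-free: a radially cut equatorial ring springs open, revealing a
*residual stress* field — circumferential compression near the endocardium
and tension near the epicardium — that reshapes the transmural stress
distribution during diastolic filling. `resmyo` provides, for researchers
in tissue-scale cardiac biomechanics:

* the orthotropic **Holzapfel–Ogden strain-energy function** for passive
  myocardium, extended with **residual-stress invariants** so that the
  unloaded-but-stressed configuration is an exact equilibrium state of the
  law;
* two estimators of the residual Cauchy stress **τ** of the unloaded wall:
  from measured transmural Euler–Almansi residual strains, and by the
  **opening-angle method** for a radially cut ring;
* a desk-scale **thick-walled-cylinder surrogate** of the left ventricle,
  inflated through diastolic pressures (0–8 mmHg) with and without
  residual stress; and
* **backward-displacement recovery** of the unloaded configuration from a
  geometry measured in a loaded state.

## The model

The baseline strain energy is expressed in invariants of the right
Cauchy–Green tensor C = FᵀF and the material triad (f₀, s₀, n₀) of fibre,
sheet and sheet-normal axes:

    W = a/(2b) exp[b(I₁ − 3)]
      + Σ_{i=f,s} a_i/(2b_i) {exp[b_i (I_{4i} − 1)²] − 1}
      + a_fs/(2b_fs) {exp[b_fs I_{4fs}²] − 1},

with I₁ = tr C, I_{4f} = f₀·(C f₀), I_{4s} = s₀·(C s₀),
I_{4fs} = f₀·(C s₀), the fibre/sheet terms active only in extension
(I_{4i} > 1), and incompressibility (det F = 1) enforced through a
Lagrange pressure p. Residual stress enters through the invariants
I₆ = tr(τC) and I₇ = tr(τC²):

* **simple** formulation: W += I₆/2, giving a Cauchy-stress contribution
  Σ = F τ Fᵀ;
* **extended** formulation: W += I₆/4 + I₇/8, giving Σ/2 + (ΣB + BΣ)/4,
  B = FFᵀ.

The constant weights are fixed by consistency of the unloaded state: at
F = I with p = a the stress reduces to τ exactly, which requires
2W₆ + 4W₇ = 1 (and W₈ + 2W₉ = 0 if the τ²-invariants are included, an
optional research mode here). No extra material parameters are
introduced. The eight baseline parameters ship as configuration data
(`ho_params()`); pressures are mmHg at the interface, stresses kPa,
lengths cm.

## Worked example

Solve the opening-angle problem for a sector with opening angle 85°,
radii 2.5/4.2 cm and unit axial stretch, then inflate the closed
(unloaded, residually stressed) tube to 3 mmHg:

```r
library(resmyo)

params <- ho_params()
geom   <- cylinder_geometry(R_i = 2.5, R_o = 4.2, alpha_deg = 85)
field  <- opening_angle_field(geom, params)
attr(field, "geometry")[c("r_i", "r_o")]
#> $r_i
#> [1] 1.745715
#> $r_o
#> [1] 3.427567
```

The sector closes into a tube with inner radius 1.746 cm; the solved
residual field has τ_rr = 0 at both surfaces and a circumferential stress
running from −0.121 kPa (compression, endocardium) to +0.076 kPa
(tension, epicardium) — the classic opening-angle pattern:

```r
tibble::as_tibble(field)[c(1, 100, 200), c("r", "tau_rr", "tau_thth", "tau_zz")]
#>       r    tau_rr tau_thth   tau_zz
#> 1  1.75  0        -0.121   -0.0659
#> 2  2.61 -1.31e- 2  0.00797 -0.00280
#> 3  3.43 -3.22e-13  0.0756    0.0353
```

Inflating with and without this residual stress shows its physiological
effect — fibre stress is relieved at the endocardium and raised at the
epicardium, while the pressure–volume relation is essentially unchanged:

```r
tube    <- closed_tube(field)
sol_no  <- inflate(tube, pressure_mmHg = 3, params)
sol_tau <- inflate(tube, pressure_mmHg = 3, params, model = "simple",
                   tau = field)
surface_summary(sol_no)[c(1, 4), ]   # mean sigma_ff: endo 0.218, epi 0.168 kPa
surface_summary(sol_tau)[c(1, 4), ]  # mean sigma_ff: endo 0.143, epi 0.213 kPa
autoplot(sol_tau)
```

Finally, recover the unloaded geometry from the loaded one (the situation
with in vivo imaging, where only the pressurised configuration is seen):

```r
recover_unloaded(sol_tau$r_i_def, sol_tau$r_o_def, pressure_mmHg = 3,
                 params, model = "simple", tau_source = "opening_angle")
#> Unloaded configuration recovered in 3 iteration(s): r_i = 1.7458 cm, r_o = 3.4276 cm
#>   final mismatch 4.88e-05 cm (0.00545% cavity area) at 3 mmHg, model = simple
```

A batch interface is available through `run_pipeline()` (YAML
configuration, deterministic CSV/JSON outputs) and the thin command-line
wrapper `inst/cli/resmyo.R` with subcommands `opening-angle`,
`estimate-costa`, `inflate`, `pv`, `unload` and `selftest`.

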