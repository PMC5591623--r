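# artwall

Analytical mechanics of a residually-stressed two-layer artery.

Arteries are pre-stressed: an unloaded ring cut radially springs open
into a sector, and the *opening angle* α of that sector quantifies the
residual stress in the intact wall. This residual stress matters
clinically — it redistributes the load across the wall and changes the
pressure at which an arterial dissection (a tear between the wall
layers) starts to grow. `artwall` implements the full analytical
chain for a two-layer (media + adventitia) wall under plane strain:

- the incompressible **Holzapfel–Gasser–Ogden** law per layer,
  `W = c(I₁−3) + Σₙ k₁/(2k₂) {exp[k₂(Iₙ−1)²]−1}`, with tension-only
  collagen-fibre families at ±β from the circumferential direction
  (plane strain: `I₄ = λ_θ² cos²β`);
- the **opening-angle construction**: the incompressible closing map
  `r(R) = √((R²−R_i²)/k + r_i²)`, `k = 2π/(2π−α)`, reduces the
  traction-free boundary-value problem to one nonlinear integral
  equation, `∫ (σ_θθ − σ_rr) dr/r = p`, solved forward (close a
  stress-free sector into the unloaded ring), inverse (recover the
  sector from the ring), and under lumen pressure;
- transmural **residual-stress profiles** (σ_rr, σ_θθ, σ_zz and the
  incompressibility multiplier 𝔭 on a radial grid);
- the **linear cohesive traction–separation law** (T_c, G_c, Δu_c;
  only two independent) with damage bookkeeping, and the
  **tear-initiation criterion** σ_mp ≥ T_c with an approximate,
  clearly-labelled initiation-pressure estimator for the intact wall;
- a **seeded synthetic parameter generator** and the published rabbit
  carotid / provisional human aorta fixtures, so everything is
  testable offline.

## Worked example

Close the published rabbit carotid stress-free sector (α = 160°) into
its unloaded, residually-stressed ring and inspect the wall state:

```r
library(artwall)

fx  <- fixture("rabbit_omega0")     # sector + materials
sol <- solve_unloaded(fx$sector, fx$materials)
sol$annulus
#> Closed annulus: r_i = 0.7377, r_m = 0.9975, r_o = 1.1173 mm;
#>   t_m = 0.2597, t_a = 0.1199 mm; p_lumen = 0 kPa

st <- sol$state
st$sigma_tt_kPa[1]          # hoop stress, media inner surface
#> [1] -0.8918351
st$sigma_tt_kPa[nrow(st)]   # hoop stress, adventitia outer surface
#> [1] 0.1206714
```

Closing the ring puts the media's inner surface into circumferential
*compression* (−0.89 kPa) and the adventitia's outer surface into
*tension* (+0.12 kPa) — the signature of opening-angle residual
stress, which under pressure offloads the most-stressed inner wall.
The inverse problem recovers the stress-free sector for any opening
angle of the same ring:

```r
fr  <- fixture("rabbit_omega_r")
inv <- solve_stress_free(fr$annulus, alpha = 120, fr$materials)
inv$sector
#> Open sector (stress-free): R_i = 1.1731, R_m = 1.4326, R_o = 1.5596 mm;
#>   T_m = 0.2595, T_a = 0.1271 mm; alpha = 120 deg
```

The `analysis/` directory holds the narrative workflow, each script a
thin driver over the package that writes its tables under `results/`:

| script | what it computes |
| --- | --- |
| `01_geometry_family.R` | stress-free geometries for α = 0…200° of one unloaded ring, vs. the published family |
| `02_residual_stress_profiles.R` | transmural residual-stress profiles and their trends in α |
| `03_fibre_angle_sweep.R` | fibre-angle sweep: which β collapse onto the fibre-free geometry and why |
| `04_inflation_initiation.R` | inflation response and the initiation-pressure surrogate, including where its α-trend reverses |

## Notes

- Units everywhere: mm, kPa, degrees; cohesive energy in N/mm
  (1 kPa·mm = 10⁻³ N/mm).
- The methods vignette (`vignettes/opening-angle-mechanics.Rmd`)
  documents the model assumptions, the numerical design (composite
  quadrature with an explicit breakpoint at the fibre-engagement
  radius, safeguarded bracketing with a guarded Newton polish), the
  synthetic generator's ranges, and known limitations — including a
  ~0.2% systematic deviation of the published reference geometries
  from the exact solution of the stated equations, which the package
  quantifies rather than absorbs.
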