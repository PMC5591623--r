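---
title: "Opening-angle residual stress and dissection initiation in a two-layer artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opening-angle residual stress and dissection initiation in a two-layer artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artwall)
```

## The model

An unloaded artery is not stress-free: cut an excised ring radially
and it springs open into a sector.  The angle of that gap — the
*opening angle* $\alpha$ — is the standard clinical/experimental proxy
for the residual stress locked into the intact wall.  `artwall`
implements the analytical mechanics of this construction for a
two-layer (media + adventitia) wall under plane strain
($\lambda_z = 1$, an infinitely long vessel), from the stress-free
open sector $\Omega_0$ through the closed unloaded ring $\Omega_r$ to
the pressurised in-vivo state.

Each layer is an incompressible Holzapfel–Gasser–Ogden solid,

$$W = c\,(I_1 - 3) + \sum_{n=4,6} \frac{k_1}{2k_2}
      \left\{ e^{k_2 (I_n-1)^2} - 1 \right\}
      \quad (\text{fibre terms active only for } I_n > 1),$$

with an isotropic neo-Hookean matrix of stiffness $c$ (kPa) and two
symmetric collagen-fibre families at $\pm\beta$ from the
circumferential direction, stiffness $k_1$ (kPa) and dimensionless
exponent $k_2$.  Under plane strain the axial component of the fibre
direction is ignored, so both families share the invariant

$$I_4 = I_6 = \lambda_\theta^2 \cos^2\beta ,$$

and contribute stress only circumferentially.  Two consequences are
worth internalising, because they shape every result downstream:

* a fibre family at angle $\beta$ engages only once
  $\lambda_\theta > 1/\cos\beta$;
* the hoop stretch of the closing deformation stays below about 1.14
  for the rabbit geometries, so fibres at $\beta \ge 30^\circ$ —
  including the physiological pair (media $29^\circ$, adventitia
  $62^\circ$) — remain slack throughout the residual-stress problem,
  which is then governed by the matrix alone.  The
  `analysis/03_fibre_angle_sweep.R` script computes this collapse onto
  the fibre-free curve explicitly (deviation exactly 0 for
  $\beta \ge 30^\circ$; up to 2.8% of the media thickness for
  $\beta = 0^\circ$).

### Kinematics and equilibrium

Incompressibility makes the closing map one-dimensional: with
$k = 2\pi/(2\pi - \alpha)$,

$$r(R) = \sqrt{\frac{R^2 - R_i^2}{k} + r_i^2}, \qquad
  \lambda_\theta = \frac{k r}{R}, \qquad
  \lambda_r = \lambda_\theta^{-1},$$

so the only unknown is the closed inner radius $r_i$ (or, inversely,
the stress-free inner radius $R_i$).  Radial equilibrium plus
traction-free surfaces reduce to a single nonlinear integral equation

$$\int_{r_i}^{r_o} \left( \sigma_{\theta\theta} - \sigma_{rr} \right)
  \frac{dr}{r} = p_{\text{lumen}},$$

with $p_{\text{lumen}} = 0$ for the unloaded ring.  `solve_unloaded()`
closes a sector, `solve_stress_free()` recovers the sector from the
ring, and `solve_loaded()` inflates the ring; all three are roots of
the same integral in different variables.  Stresses are then recovered
by cumulative quadrature of the equilibrium equation from the inner
surface and the incompressibility multiplier
$\mathfrak{p} = -\sigma_{rr} + 2c\lambda_r^2$.

## Numerical design

The choices below were made once, from the structure of the problem,
and are exercised by the property suite.

* **Root finding.** Safeguarded bracketing (`uniroot` on a clamped
  residual) instead of raw Newton: the physical root is unique (the
  integrand is strictly increasing in the candidate radius) but Newton
  from a poor start can leave the physical branch.  Brackets:
  $[0.01\,R_i,\ R_o]$ closing, $[r_i,\ 10\,r_i]$ opening.  The HGO
  exponential overflows to `Inf` at extreme bracket endpoints; the
  clamp maps it to a huge signed value so bracketing logic is
  unaffected.  After convergence a guarded Newton polish accepts only
  improving steps: for stiff parameter draws the residual slope can
  exceed $10^8$ kPa/mm, so an x-converged root can still carry a
  visible residual.
* **Quadrature.** Composite Gauss–Legendre, 10 panels of order 10 per
  layer, with the layer interface always a panel boundary and a
  doubled-panel refinement check reported in `info`.  Crucially, the
  tension-only fibre switch at $I_4 = 1$ puts a *derivative kink
  inside a layer* wherever $\lambda_\theta \cos\beta$ crosses 1.  That
  radius has a closed form, and inserting it as an explicit breakpoint
  restores spectral convergence; without it the residual stalls near
  $10^{-6}$ relative accuracy no matter the order.  The same
  breakpoint is used in the cumulative stress profiles, which
  integrate on a sub-divided grid (4 sub-panels of order 8 per output
  interval) so their accuracy does not depend on how many output nodes
  were requested.
* **Grids.** Profiles default to 401 unique radii with the interface
  node duplicated and layer-tagged: $\sigma_{rr}$ is continuous across
  the interface but $\sigma_{\theta\theta}$ jumps, and a duplicated
  node represents the jump exactly.
* **Convergence criteria.** Bracket width $10^{-13}$ mm; solved states
  satisfy $|\sigma_{rr}|$ at both surfaces below
  $10^{-8} c_{\text{media}}$ and interior finite-difference
  equilibrium residuals below $10^{-4}$ kPa/mm on the default grid.
  Forward–inverse round trips over the full admissible parameter range
  reproduce radii to better than $10^{-11}$ mm.
* **Degenerate inputs.** $\alpha = 0$ short-circuits to the identity
  (zero stress); mismatched sector/ring pairs are rejected by an
  outer-surface traction check scaled by the profile's own stress
  magnitude; inflation detects the limit pressure of fibre-free tubes
  (no equilibrium beyond it) and backs the bracket off it rather than
  failing.

## Reference parameter set and units

The packaged fixture is the classic two-layer rabbit carotid artery:
media $c = 1.5$ kPa, $k_1 = 2.3632$ kPa, $k_2 = 0.8393$,
$\beta = 29^\circ$; adventitia $c = 0.15$ kPa, $k_1 = 0.5620$ kPa,
$k_2 = 0.7112$, $\beta = 62^\circ$; stress-free sector
$R_i = 1.43$ mm, $T_m = 0.26$ mm, $T_a = 0.13$ mm at
$\alpha = 160^\circ$.  Lengths are mm, stresses kPa, angles degrees at
every public interface (converted to radians internally).

Cohesive parameters follow the triangular traction–separation law:
peak traction $T_c$ (kPa), full-separation jump $\Delta u_c$ (mm), and
separation energy $G_c$ (N/mm), of which only two are independent
($G_c = T_c \Delta u_c/2$; note kPa·mm $= 10^{-3}$ N/mm, so the rabbit
media triple 3 kPa × 0.667 mm gives $G_c = 0.0010005$ N/mm).  A
provisional aged-human-aorta fixture ships with only its unambiguous
fields; its HGO constants are deliberately left unparsed rather than
guessed, and it is flagged as such.

## The cohesive law and initiation criterion

`cohesive_law()` completes and validates the parameter triple;
`cohesive_traction()` implements the initially-rigid linear-softening
envelope with irreversible damage.  The envelope is all the law
prescribes; for unloading we adopt the standard cohesive-zone
convention of a linear secant to the origin through the envelope point
at the largest jump seen.  `dissipated_energy()` integrates the
traction path exactly (trapezoids between the path's kinks): monotone
loading to $\Delta u_c$ dissipates exactly $G_c$, loading to
$\Delta u_c/2$ and unloading dissipates $G_c/2$, and no admissible
history exceeds $G_c$.

A tear initiates where the maximum principal Cauchy stress reaches the
cohesive strength, $\sigma_{mp} \ge T_c$ (boundary inclusive).  The
solved states are shear-free in $(r, \theta, z)$, so $\sigma_{mp}$ is
the largest diagonal component and propagation, perpendicular to the
maximum tensile principal direction within the cross-sectional plane,
is radial whenever hoop stress dominates.

## The initiation-pressure surrogate, honestly

`initiation_pressure()` inflates the *intact* wall and bisects for the
smallest lumen pressure at which $\max_r \sigma_{mp} \ge T_c$.  It is
deliberately a low-fidelity surrogate for the critical pressure of a
real dissection: no tear geometry, no tear-tip concentration, no
inner-wall buckling, no contact.  Treat its absolute values as
order-of-magnitude only.

Its trend with the opening angle is instructive and *two-sided*, and
the package reports it as computed rather than smoothing it over.  At
the pressurised inner surface residual stress is protective for every
$\alpha$: the inner hoop peak at fixed pressure falls monotonically as
$\alpha$ grows (asserted by the test suite).  While the inner surface
governs the wall-wide maximum ($\alpha \lesssim 80^\circ$ for
$T_c = 2c$), the initiation estimate rises with $\alpha$.  Beyond
that, the criterion site migrates to the *outer* media, where the
residual hoop tension — which grows with $\alpha$ — adds to the
load-induced stress, and the wall-wide estimate falls again
(`analysis/04_inflation_initiation.R` tabulates the crossover,
including the criterion radius).  A criterion confined to the inner
media, where dissections actually start, retains the protective trend
throughout; the wall-wide definition used here does not.

## Synthetic parameter generator

`draw_parameter_set()` exists so that every solver property can be
tested without any external data, across the whole admissible box
rather than at one fixture.  Ranges: inner radius 0.5–3 mm, media
thickness 15–35% of the inner radius, adventitia 30–80% of the media
thickness, $\alpha \in [0, 220]^\circ$, $c \in [0.1, 50]$ kPa and
$k_1 \in [0.05, 120]$ kPa log-uniform (stiffnesses are scale
parameters), $k_2 \in [0.1, 30]$, $\beta \in [0, 90]^\circ$ uniform,
$T_c = 2c$ with $\Delta u_c \in [0.3, 1]$ mm.  These bracket the
rabbit and human parameter sets with generous margins.  The RNG is
pinned (Mersenne–Twister, inversion) so a seed identifies one draw
anywhere, and the caller's RNG state is restored.

What the generator emulates is parameter diversity, not measurement
realism: real vessels have axial pre-stretch, dispersed fibre
orientations, perivascular tethering and layer-specific opening
angles, none of which are drawn.  Passing the property suite therefore
certifies the *solver* over the admissible box, not the model's
fidelity to any particular artery.

`noisy_profile()` adds seeded multiplicative Gaussian noise to the
stress columns (boundary nodes kept exact, since boundary tractions
are known) and feeds `recover_opening_angle()`, which inverts a
profile back to its opening angle by bounded scalar minimisation of
the relative $L_2$ profile error, guarded by a coarse unimodality
scan.  At 1% noise the recovered angle is within a fraction of a
degree of truth (mean absolute error $\approx 0.1^\circ$ over seeded
replicates); the $\pm 2^\circ$ acceptance margin is comfortable.

## Problem sizes

Default profiles use 401 nodes; sweeps and property tests use 31–201
nodes and 20–200 random draws, sizes at which every analysis script
and the full test suite complete in well under a minute on a single
core while leaving round-trip errors at the $10^{-11}$ mm level.

## Known limitations

* Plane strain with $\lambda_z = 1$: no axial pre-stretch, and the
  fibre convention discards the axial fibre component entirely.
* One opening angle for the whole two-layer ring; layer-specific
  opening angles are not represented.
* The initiation estimate is axisymmetric and intact-wall, as
  discussed above; tear propagation, XFEM-style enriched fields and
  face contact are out of scope (the `tear_spec` type is metadata
  only).
* The cohesive law is scalar and isotropic (mode-I-like normal
  separation).
* Published reference geometries for the opening-angle family carry a
  systematic deviation of up to 0.0038 mm (0.21%) from the exact
  solution of the stated equations; the package's solver agrees with
  an independent energy-minimisation route to $10^{-6}$ mm and with
  its own refinement checks to $10^{-15}$, so the package reports its
  computed values and tabulates the deviation
  (`analysis/01_geometry_family.R`).
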