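---
title: "A BMD-dependent crushable-foam model for femoral bone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A BMD-dependent crushable-foam model for femoral bone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonefoam)
```

## The problem

Trabecular bone is a cellular solid: beyond its yield point it crushes,
densifies, and — crucially — yields under hydrostatic pressure, which a
classical von Mises (J2) material can never do. Whole-bone simulations that
assign a pressure-insensitive criterion to the trabecular compartment
therefore overpredict stiffness and strength wherever the bone is confined
by stiffer structures (cortical shells, implants, test chambers). The
isotropic crushable foam (ICF) model closes that gap with a yield surface
that caps both the deviatoric and the hydrostatic stress, with all
parameters driven by the local bone mineral density (BMD) from calibrated
quantitative CT.

`bonefoam` implements the full chain: CT phantom calibration, BMD-to-
parameter mapping, the elastoplastic stress integrator (plus a softening von
Mises comparator), laboratory-style material-point drivers and curve
reduction, population-level power-law characterization, seeded synthetic
data generation, and a small voxel finite-element solver for cylindrical
specimens.

## The constitutive model

Stress invariants are the compression-positive pressure `p = -tr(sigma)/3`
and the von Mises equivalent `q`. The yield surface is an origin-centred
ellipse in the (p, q) plane,

$$F(p, q) = \sqrt{q^2 + \alpha^2 p^2} - B \le 0,$$

with shape factor `alpha` and size `B`. Two physical anchor points fix both
constants in terms of measured quantities: uniaxial yield
(`p = sigma_c/3`, `q = sigma_c`) and hydrostatic yield (`p = p_y`, `q = 0`).
Writing the strength ratio `K = sigma_c / p_y` (uniaxial over hydrostatic
yield stress) gives

$$\alpha = \frac{3K}{\sqrt{9 - K^2}}, \qquad
  B = \sigma_c\sqrt{1 + \alpha^2/9} = \frac{3\,\sigma_c}{\sqrt{9-K^2}},$$

which requires `0 < K < 3`; the ellipse degenerates at `K = 3`.

**Why this surface form.** With associated flow, the plastic strain rate is
proportional to `dF/dsigma = (3s/2 - alpha^2 p I/3)/g`. Evaluating the
transverse-to-axial ratio of that tensor under uniaxial compression gives
exactly

$$\nu_p = \frac{3 - K^2}{6},$$

the plastic Poisson's ratio the parameter tables state. That closed-form
agreement — reproduced numerically to 1e-11 by the test suite — is the reason
the centred ellipse was adopted. A known variant of foam plasticity hardens
volumetrically and carries a separate hydrostatic tension strength `p_t`
(an off-centre ellipse); the centred surface is symmetric in `p` and has no
distinct tensile cap. For the monotonic compression problems in scope the
tensile branch is never probed; the variant is noted here as the natural
extension if tensile regimes matter.

**Hardening.** The scalar internal variable `eps_bar_p` is defined through
plastic dissipation, `sigma : deps_p = sigma_c \, d\bar\varepsilon_p`, which
in uniaxial compression reduces to the accumulated axial plastic strain —
so the hardening table `sigma_c(eps_bar_p)` is literally the uniaxial
post-yield stress/plastic-strain curve. `B` is recomputed from `sigma_c`
through the two-point condition above, so hardening and softening move the
whole ellipse self-similarly. No published point-by-point hardening tables
exist for these specimens; the package ships two configurable templates as
stand-ins: a trabecular shape (mild softening, long plateau, densification
upswing toward 58% strain, the strain the compression protocol reaches) and
a cortical linear-softening-to-residual shape. Both scale with the card's
yield stress. Any table can replace them (`hardening_curve()`, CSV I/O).

**The comparator.** `svm_update()` is a standard J2 radial return with a
trilinear effective-stress law (elastic, linear softening, residual
plateau). It shares the elasticity and yield stress of the matching ICF
card, and is pressure-insensitive by construction — the mechanism behind the
confined-compression divergence between the two models.

## Density-to-parameter mappings

BMD is handled internally in g/ml; file interfaces accepting mg/ml convert
at the boundary. The femoral parameter set (`femoral_laws()`) carries:

| quantity | continuous | discontinuous (trab / cortical at 0.950 g/ml) |
|---|---|---|
| E (MPa) | 12980·BMD^2.567 | 5113·BMD^1.653 / 13750·BMD^2.429 |
| sigma_y (MPa) | 109.3·BMD^1.872 | 79.36·BMD^1.553 / 111.5·BMD^1.800 |
| nu_e | 0.16 | 0.16 |

The strength ratio follows `K = 1.361·BMD^-0.312` between 0.08 and
0.950 g/ml, clamped at 2.993 below and 1.383 above — the clamp values are the
power law evaluated at the breakpoints and rounded to three decimals, and
the constructor validates that continuity (5e-4) at load time rather than
hard-coding it. `nu_p = (3 - K^2)/6` follows. Sub-threshold voxels (marrow,
air) are clamped to a BMD floor of 0.001 g/ml and receive a minimal elastic
card; the clamping is part of the conversion contract, not an error.

## Specimen characterization

Test records are nominal stress/strain (force over initial area,
displacement over initial height, compression positive; geometry defaults
12 mm x 11.65 mm cylinders). Reduction follows the laboratory recipe:

* **Elastic modulus** — sliding-window regression, window 10% of the
  samples, keeping windows with R² ≥ 0.999 whose slope is at least the
  curve's overall chord (this last guard rejects flat plateau windows whose
  R² is a 0/0 artifact); the maximal qualifying slope is the modulus, and
  the window halves if none qualifies. The exact procedure used in the
  laboratory is unpublished; this automated rule recovers the generating
  modulus to machine precision on noiseless synthetic curves.
* **Yield** — 0.2% strain offset: first intersection of the curve with
  `sigma = E(eps - 0.002)`, interpolated between samples, ties toward lower
  strain.
* **Confined records** — the confined elastic slope is the constrained
  modulus `E(1-nu)/((1+nu)(1-2nu))`; `reduce_record()` divides it back out
  so `E` means Young's modulus for every record, and converts the axial
  yield stress to hydrostatic stress via `p_y = sigma_a(1+nu)/(3(1-nu))`
  (elastic lateral-stress relation at `nu = 0.16`).

**A caveat the tests quantify.** The hydrostatic conversion is the testing
protocol's own elastic approximation: the confined loading ray intersects
the yield ellipse away from its hydrostatic apex, by an amount that depends
on K. Round-tripping a known card through `run_confined()` and the
reduction recovers `p_y` within 5% only for K between roughly 2.2 and 2.6
(BMD 0.12–0.20 g/ml, where typical specimens sit); at the range ends the
systematic bias reaches about +17% (K = 2.99) and −20% (K = 1.8). This is a
property of the conversion, not of the integrator, and it propagates into
any K law derived from confined measurements.

**Power-law fitting** is ordinary least squares on log-log axes
(`a = exp(intercept)`, `b = slope`); the correlation is reported both as
log-log Pearson and Spearman's rho because published tables differ in which
they quote, and the standard error of the estimate is computed in original
units with `n - 2` degrees of freedom. A nonlinear refinement
(`refine = TRUE`) re-minimizes the original-units residual from the log-log
start, since SEE values are conventionally quoted in original units. The
stiffness law pools all records (both testing modes yield a Young's
modulus); the yield law uses uniaxial records, the hydrostatic-yield law
confined ones. The K law comes from the ratio of the two yield laws by
default, or from a direct fit on per-specimen ratios when a `pair_id`
column links the modes — with an evenly split population there are no true
pairs, which is why the ratio path is the default. Cortical data points can
be injected as clearly-labelled synthetic pseudo-records
(`cortical_pseudo_records()`) around the cortical laws, mirroring the use
of literature values where no raw cortical tests exist.

## Synthetic data: what it does and does not emulate

`gen_population()` draws BMD uniformly on (0.05, 0.40) g/ml — chosen so the
implied property ranges match reported femoral trabecular data (stiffness
roughly 100–1100 MPa, uniaxial yield 1–18 MPa) — and perturbs the law values
with independent unit-mean lognormal factors (positive, heteroscedastic
noise). The default coefficient of variation, 0.075, was calibrated once so
that refitting the trabecular laws on default populations reproduces
standard errors of estimate near the published trabecular values (about
47 MPa for stiffness, 0.74 MPa for yield stress) and then frozen. Records
split evenly between uniaxial and confined modes. `gen_curves()` integrates
each record's true card with the batched drivers (numerically identical to
the scalar integrators; asserted to 5e-10 in the tests). `gen_voxel_cylinder()`
paints a padded voxel volume (default 0.4 x 0.2 x 0.2 mm voxels) with a BMD
field, inverts the phantom calibration to HU, and emits a consistent
phantom table.

What the generators do **not** emulate: trabecular microarchitecture and its
anisotropy, platen end artifacts, machine compliance, DIC speckle noise,
inter-donor correlation structure, and beam-hardening or partial-volume CT
artifacts. Passing tests therefore demonstrate that the pipeline is
self-consistent and recovers known generating laws under realistic noise
levels — not that it is robust to every artifact of real laboratory data.

## The voxel FE solver

Eight-node hexahedra on the voxel lattice, small strain, full 2x2x2
integration with B-bar volumetric treatment (plastic Poisson's ratios near
0.5 at low K would otherwise lock). Element height rounds to divide the
specimen height exactly. Boundary elements cut by the cylinder surface are
kept with a partial-volume weight equal to their in-cylinder area fraction:
an all-or-nothing mask would make the modelled cross-section area itself
fluctuate by up to ±10% at 2 mm elements, and the mesh-size study would then
measure geometry error rather than discretization error. Per-element cards
come from mean-pooled BMD of the masked voxels.

Compression is displacement-controlled: bottom platen fixed axially, top
nodes stepped down, in-plane motion free (frictionless platens, two pin
constraints removing rigid in-plane modes without restraining uniform
contraction). Confined mode pins both in-plane components of the lateral
surface nodes — a rigid rough chamber; with the axisymmetric fields arising
here this is equivalent to the radial-only constraint up to boundary
jaggedness. Each increment is equilibrated by modified Newton iterations on
the once-factorized elastic stiffness, with the vectorized return mapping
supplying internal forces; convergence is declared at a force residual of
1e-8 relative to the platen reaction, which makes the top/bottom reaction
imbalance at most ~1e-6 relative (asserted). Total strain energy is the
trapezoidal work integral accumulated per Gauss point (elastic plus plastic
work), matching the half-sigma-epsilon closed form exactly in elastic runs
and the external platen work within 1% in plastic runs.

## Numerical choices

* ICF return mapping: the scalar unknown is the hardening increment; the
  residual is solved by the Illinois (safeguarded regula falsi) method on a
  doubling bracket to |F| ≤ 1e-10·B in the scalar path, and by 64 vectorized
  bisection steps in the FE path. Non-convergence triggers strain-increment
  halving (depth 10) before an error carrying trial-state diagnostics.
* Uniaxial drivers: secant iteration on the (equal) lateral strains to
  |sigma_lat| ≤ 1e-9·E (tightened to 1e-12·E where flow-rule ratios are
  measured to 1e-6).
* Hardening tables interpolate linearly and continue constant beyond both
  ends, so a one-knot table is perfect plasticity.
* Degenerate inputs: identical phantom HU values error as a degenerate fit;
  constant-response power fits are flagged (`degenerate = TRUE`, r = NA);
  purely elastic curves raise a typed no-yield condition that record
  reduction converts into an exclusion flag.
* Problem sizes: characterization round trips run curves to 6% strain in
  240 steps (the elastic window plus the 0.2%-offset crossing sit well
  inside); full-protocol curves to 58% strain remain available. The FE
  mesh-size study uses 1, 1.5 and 2 mm elements at 1% nominal strain with 5
  increments — the response there is dominated by the elastic regime, which
  is what a strain-energy convergence criterion probes. These are the
  package's standard study sizes and are what the acceptance script runs.

## Known limitations

* Small-strain kinematics and nominal stress throughout; at 50% nominal
  strain the numbers are protocol-consistent but not finite-deformation
  mechanics.
* No rate dependence (the emulated tests are quasi-static at 0.007 1/s), no
  damage variable, isotropy assumed.
* The centred ellipse has no independent tensile strength; tensile regimes
  are out of scope.
* Whole-femur fracture simulation (tetrahedral meshes from patient QCT,
  experiment-matched boundary conditions) is outside this package's scope;
  the FE module is a specimen-scale solver.
* Hardening templates are plausible shapes, not fitted curves; quantitative
  post-yield magnitudes inherit that uncertainty.
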