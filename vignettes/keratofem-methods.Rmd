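---
title: "keratofem: model, numerics and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{keratofem: model, numerics and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

keratofem models the loaded human cornea as a quasi-incompressible,
fiber-reinforced hyperelastic shell and solves two inverse problems on top
of the forward model: recovering the *stress-free geometry* (SFG) and the
physiological stress state from a *measured*, pressurized geometry.  This
vignette records the model equations, the regional parameterization, the
numerical choices, and how each ingredient is verified.

## Geometry and synthetic fixtures

The reference cornea is a pair of biconic surfaces (anterior and
posterior) over a 12 mm diameter plan form, with a central thickness of
about 545 µm thickening toward the limbus.  Keratoconus-like fixtures are
produced by subtracting a decentred Gaussian protrusion from both
surfaces and locally thinning the stroma; four canned severities
(`keratoconus_cone("G1")` … `"G4"`) scale the protrusion amplitude and
the thinning fraction.

```{r}
library(keratofem)
geom <- default_cornea(cone = keratoconus_cone("G1"))
topo <- to_topography(geom)      # topographer-style polar samples
```

`to_topography()` / `from_topography()` round-trip the geometry through a
plain CSV of polar elevation samples, which is also the CLI's exchange
format for measured geometries.

## Regional segmentation

The in-plane segmentation follows clinical zone maps: concentric rings at
2, 4, 6, 8, 10 and 11 mm diameter crossed with eight 45° octants whose
boundaries sit at ±22.5° around the cardinal meridians.  Cells are
classified into four material zones:

* `CENTRAL_NT_SI_STRONG` — central/paracentral cells on the
  nasal-temporal and superior-inferior octants (orthogonal fiber families,
  strongest reinforcement),
* `CENTRAL_OBLIQUE` — central cells on the oblique octants,
* `TRANSITION` — the annulus between them,
* `LIMBUS` — the outermost ring, reinforced by a single circumferential
  fiber family.

The same layout defines the measurement layout: per surface, 8 meridians
× 7 circles + the apex give 57 control nodes at which the inverse methods
enforce agreement with the measurement.

## Constitutive model

Per zone, the strain-energy density is

$$\psi = \tfrac{1}{2} k_0 (J-1)^2 + a_1(\bar I_1 - 3) + a_2(\bar I_2 - 3)
 + \sum_{i} \frac{k_1}{2k_2}\left(e^{k_2(\bar I_{4,i}-1)^2} - 1\right),$$

a Mooney–Rivlin matrix (isochoric invariants) plus exponential
Holzapfel-type fiber families, with a volumetric penalty
($k_0 = 5.5\,$MPa) enforcing quasi-incompressibility.  The matrix
parameters are shared by all zones ($a_1 = 40$ kPa, $a_2 = -10$ kPa);
$k_1$ is 50 kPa in the strong central zones and the limbus, 37.5 kPa in
the transition zone and 25 kPa in the oblique zones, with $k_2 = 200$.
Central zones carry two orthogonal families; the limbus carries one
circumferential family.

`cauchy_stress()` and `material_tangent()` are closed-form; the test
suite checks both against finite differences of `strain_energy()`
(stress to 1e-6 relative, tangent via directional derivatives), plus
objectivity, pure-dilation and single-family special cases.

## Forward solver

Eight-node hexahedra with mean-dilatation (B-bar) treatment integrate the
model on a butterfly-structured mesh whose element boundaries conform to
the segmentation rings and octant boundaries; layers stack through the
thickness.  The IOP acts as a follower pressure on the deformed posterior
surface, including its (symmetric) load-stiffness contribution.

Limbus support comes in two physiological variants, implemented as
multipoint constraints eliminated master–slave: `embedded` clamps every
rim cross-section node; `pivoting` lets each rim cross-section rotate
rigidly about its circumferential tangent through the section centroid.
A third mode, `radial_roller`, constrains rim nodes to rays through a
center and exists for the spherical-shell verification problem, where the
lateral cut must be exactly radial for the 1-D comparison to be valid (the
mesher option `rim_ray_center` places the rim node columns on such rays).

The nonlinear problem is solved by incremental Newton: 10 equal pressure
substeps, consistent tangent, relative residual tolerance 1e-8.  The
MPC-reduced tangent is symmetric, so each step uses a sparse Cholesky
factorization (with an LU fallback guarded against indefiniteness).  A
warm-start path reuses a previous solution with a single full-pressure
load step; the inverse iterations rely on it after their first pass.

```{r}
mesh <- generate_mesh(geom, segmentation_spec(), mesh_spec())
mats <- material_assignment(mesh)
state <- solve_forward(mesh, mats, build_bc(mesh, "embedded"),
                       iop_mmhg = 15)
```

### Verification against a 1-D shell solution

`sphere_inflation_reference()` integrates the radial equilibrium ODE of a
pressurized thick spherical shell (same constitutive law, isotropic
parameters) with a shooting method, validated internally by global force
balance.  A spherical-cap variant of the mesh (`spherical_cap_fixture()`)
with radial rollers reproduces the reference apex displacement within 2%
at a ~2000-element mesh and converges under refinement.

## Inverse methods

Both methods take the measured geometry as holding at a known IOP and
eliminate the unknown unloaded state:

* **Displacements method** — iterate on the reference coordinates with
  the fixed-point update $X \leftarrow X - (x(X) - X_m)$; at convergence
  the forward solve from the recovered SFG lands on the measurement at
  every control point (tolerance 1e-9 m).
* **Prestress method** — keep the reference fixed at the measurement and
  iterate a multiplicative per-Gauss-point prestress
  $F_{pre} \leftarrow F_{inc} F_{pre}$ until the IOP produces numerically
  zero displacement; an extra unloaded solve releases the model to its
  SFG.

Fiber directions are assigned once, on the measured mesh, and held fixed
throughout.  The two methods agree on the pressurized state (EPG) to
sub-micrometer accuracy but recover visibly different SFGs — the
prestress release does not re-equilibrate the anisotropic residual
stresses the way the displacements iteration does, which is exactly the
methodological difference the comparison tooling quantifies.

```{r}
rd <- displacements_method(mesh, mats, build_bc(mesh, "embedded"), 15)
rp <- prestress_method(mesh, mats, build_bc(mesh, "embedded"), 15)
compare_methods(rd, rp)
```

## Post-processing and CLI

`von_mises()`, `equivalent_strain()` (logarithmic strain deviator),
`zone_summary()` and `field_report()` condense Gauss-point fields;
`export_vtk()` writes legacy-ASCII VTK readable by ParaView.  The
`kfem_cli()` entry point (also installed as `inst/cli/keratofem`) chains
`fixture → mesh → solve / sfg → compare → report` under one YAML
configuration and writes manifests with a configuration hash; summary
JSON files contain no timing state and are byte-identical across reruns.

## Known limitations

* The mesher is specialized to the butterfly layout over the standard
  ring/octant segmentation; arbitrary segmentations are out of scope.
* Assembly is single-threaded; `--threads` is accepted for interface
  stability and does not change results.
* The pivoting constraint rotates sections about fixed axes evaluated on
  the current reference configuration; finite axis re-orientation during
  loading is neglected (consistent between forward and inverse use).
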