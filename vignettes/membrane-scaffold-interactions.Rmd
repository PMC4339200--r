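---
title: "Membrane-mediated interactions between rigid curved scaffolds: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-mediated interactions between rigid curved scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memscaffold)
```

## The physical model

Curvature-generating proteins such as BAR-domain dimers, dynamin oligomers
and reticulons bind lipid membranes as rigid, intrinsically curved
*scaffolds*.  A scaffold molds the membrane beneath it; the surrounding
membrane must bend to meet the scaffold's edge smoothly, and the overlap of
the deformation fields of two scaffolds produces a membrane-mediated
interaction between them.  This package computes that interaction for two
identical scaffolds as a function of their centre-to-centre distance `d`
and mutual orientation.

A scaffold is the segment of the quadric

$$\left(\frac{x}{\rho_a}\right)^2 + \mathrm{sign}(\rho_b)\left(\frac{y}{\rho_b}\right)^2 + \left(\frac{z}{\rho_a}\right)^2 = 1$$

cut by the elliptical cylinder $(x/r_a)^2 + (y/r_b)^2 = 1$.  Its principal
curvatures at the central point are $c_a = 1/\rho_a$ and $c_b = 1/\rho_b$;
positive $\rho_b$ gives a dome, negative $\rho_b$ a saddle, $\rho_b = \infty$
a cylinder-like element.  The membrane is a Helfrich sheet with bending
energy density $f = \tfrac12 \kappa J^2$, where $J$ is the total curvature
(twice the mean curvature) and $\kappa = 20\,k_BT$ by default.  Spontaneous
curvature is zero, the Gaussian-curvature term is a topological constant and
is omitted, and the membrane is tensionless unless a lateral tension
$\gamma$ is requested.  Along each scaffold rim the membrane surface normal
must coincide with the scaffold surface normal (*normal continuity*; the
contact angle between the rim normal and the centre normal varies along the
rim between $\phi_a = \arcsin(r_a/\rho_a)$ and $\phi_b = \arcsin(r_b/\rho_b)$).
Curvature continuity is *not* imposed: a rigid edge can exert bending
moments.

A pair configuration is described by the distance `d`, the in-plane angle
`phi` between the scaffold long axis and the connecting line, and the tilt
`theta` of the centre normals within the vertical plane containing the
connecting line.  Only mirror-symmetric orientations are used in the main
pipeline (`phi1 = phi2`, `theta1 = theta2`); a designed set of asymmetric
probes (`run_asymmetry_check()`) verifies that asymmetric orientations cost
more energy.  With `theta` restricted to one sign, positive `theta` is taken
to tilt the two normals *away* from each other, which is the direction the
energetics favour for convex scaffolds; orientation optima then lie inside
the `[0, 180]` degree range.

Three energies are derived from minimized shapes:

* the **elastic interaction** `F_el(d) = F_min(d) − F_min(d_ref)`, where
  `F_min` is the membrane energy minimized over the orientation angles and
  `d_ref` is a large reference separation standing in for infinity;
* the **free energy** from the Boltzmann integral over the orientation
  angles, $F(d) = -k_BT \log \int e^{-F_m(\varphi,\theta,d)/k_BT}\,
  \mathrm d\theta\,\mathrm d\varphi$ (angles in radians, reported relative
  to `d_ref`);
* the **orientational-entropy energy** `F_ent = F − F_el`, the repulsive
  free-energy cost of the orientation confinement.  Only mirror-symmetric
  orientations enter the integral, so the computed entropic repulsion is a
  lower bound; membrane-undulation (Casimir) entropy is outside the scope.

## Discretization

The membrane is a triangulated disc of radius `L` around the pair.  The
discrete total curvature uses the area-gradient (cotangent) formulation
with obtuse-safe mixed Voronoi areas: at a vertex $v$,
$J_v = |\nabla_v A|/A_v$ with $\nabla_v A$ the gradient of the total mesh
area and $A_v$ the mixed area, and
$E = \sum_v \tfrac{\kappa}{2} J_v^2 A_v$ over the energy-carrying vertices.
The analytic gradient of this energy (a hand-written reverse sweep,
verified against central finite differences to ~1e-6 relative error) drives
the minimization.

**Boundary conditions.**  Each scaffold contributes two fixed vertex rings
embedded in its analytic surface: the rim ring and an interior collar ring
at in-plane offset `collar_frac * h`.  The fully fixed strip between them
carries the scaffold's tangent plane, and the *rim vertices keep their
bending energy*: their mixed-area stars span the strip and the adjacent
membrane, so they form the discrete hinge that enforces normal continuity.
(Without this hinge term the contact-angle condition is silently lost — the
isotropic pair interaction collapses by four orders of magnitude.)  The
hinge stiffness scales as $\kappa/h$, so the condition sharpens under
refinement, and the associated self-energy converges as a boundary-layer
term.

**Outer boundary.**  The outer ring is pinned on the superposed asymptotic
tail of the single-scaffold solution (a catenoid matched to the mean rim
contact angle, with the partner's cross term removed so each rim height is
respected).  Two alternatives were implemented and rejected.  A fully free
outer rim admits a near-zero-cost global fold that absorbs mirror-symmetric
tilts: the linearized oracle with a held far field shows an almost flat
tilt response where the free-rim mesh showed a spurious several-fold energy
drop, and the resulting soft modes made minimization ill-conditioned.
Pinning the ring at height zero instead forces the logarithmic tail to bend
back, adding a large-domain adjustment that converges extremely slowly.
The matched-tail pinning keeps the far field consistent from the start; it
stands in for the closed, effectively flat membrane reservoir around the
pair.  The residual single-scaffold energy of this condition (a few
hundredths of kT at coarse resolution) is identical at every `d` and
cancels exactly in all interaction differences.

**Mesh layout.**  Rim and collar rings are sampled at approximately equal
arclength (at least 24 rim vertices; `h` is the target edge length near the
rims, `h = 0.3 min(r_a, r_b)` in the coarse profile and `0.16` in the
production profile).  Free rings graded by the factor `grading = 1.3`
surround each scaffold out to `patch_extent` shape units or, for
well-separated pairs, to about `0.55 d`, where their spacing matches the
background; rings crossing the mirror plane are clipped.  The background is
a set of circular rings around the origin whose layout depends only on
`(h, grading, L)` — never on the scaffold positions — so that its
discretization error is identical across a distance sweep and cancels in
energy differences.  The point cloud is Delaunay-triangulated (an
incremental Bowyer–Watson kernel with deterministic tie-breaking jitter)
and the triangles inside the collar rings are removed.

**Minimization.**  Every placement admitted by the overlap guard
(`d >=` sum of footprint support radii `+ 2h`) keeps the membrane a graph
over the initial plane, so shapes are minimized over the vertical positions
of the free vertices; in-plane quality is maintained by the regularizer
(tangential averaging plus edge flips restricted to nearly planar, strictly
convex quads) rather than by tangential degrees of freedom.  The inner
solver is a damped Newton iteration: the Hessian of the lagged-coefficient
quadratic model (cotangent weights and mixed areas frozen at the current
geometry) is assembled sparse and factored with `Matrix`'s Cholesky;
Levenberg–Marquardt damping plus step backtracking controls the physically
flat (harmonic) directions, and an L-BFGS polish serves as fallback.  The
lagged Hessian agrees with the true one to $O(\text{slope}^2)$, so a
handful of steps reach energy stationarity below 1e-8 kT.  A
limited-memory quasi-Newton descent on all coordinates was implemented
first and rejected: the graded mesh gives the energy a condition number of
order 1e6 and L-BFGS could not reach the 1e-4 kT accuracy the far-field
curves need within any reasonable iteration budget.

**Refinement and error control.**  `subdivide_mesh()` splits each triangle
in four, re-projecting new ring vertices onto the analytic surface;
`minimize_shape(refine = 1)` re-minimizes and reports the level-to-level
energy difference as the discretization error estimate
(`error_estimate()` also reports the maximum dihedral angle).  Interaction
energies converge from below (the hinge stiffens under refinement).

**Warm starts.**  Orientation sweeps reuse nearby solved states, but only
angularly nearby ones: warm starts from distant orientations leave
hysteresis in the converged energies, so the evaluator keeps a pool of
solved states and falls back to the analytic tail initialization otherwise.
Across distances the reference (solved first, cold) is re-minimized
warm-started from the nearest distance so its convergence depth matches the
sweep.

## Orientation optimization and the entropy integral

`optimal_orientation()` scans a coarse grid (five `phi` values in
`[0, 90]`, skipped for axisymmetric scaffolds; `theta` grid scaled by the
largest contact angle) and refines each angle parabolically, with a
boundary-aware variant that resolves optima adjacent to `theta = 0` (far
separations have `theta* ~ 0.2` degrees).  Ties break toward smaller
angles.

The free energy integrates Gauss–Legendre nodes in `phi` over (0°, 90°)
(`n_phi = 5` coarse, 9 production) and, per node, samples `theta` inside
the window where `F_m` exceeds the per-`phi` minimum by at most
`theta_window = 4` kT (bracketing plus bisection, `n_theta` nodes, natural
spline).  Outside the window the profile is extended quadratically, matched
at the window edges; the neglected weight is below $e^{-4}$ and doubling
the angular grids changes `F` by under 0.05 kT on the shallow suite.  If
the window never closes within `[0, 180]` the full range is integrated
with a warning.

## Parameter choices and problem sizes

The shallow-scaffold series uses `r_a = r_b = a = 1`, `a/rho_a = 0.2`, with
`c_b/c_a` in `{1, 0.75, 0, −0.75, −1}`; the BAR geometry is `r_a = 6.5`,
`r_b = 1.5`, `rho_a = 8.5` nm with the short-axis curvature `c_b` as the
sweep parameter.  Lengths are in scaffold radii for the shallow presets and
nm for BAR; energies are always in kT.  The footprint (`r_a`, `r_b`) is
held fixed while `c_b` varies.

Numerical choices that matter, with the reasons they were fixed as they
are:

* `d_ref = 20 r_a` by default.  For far-field power-law fits the package
  uses `d_ref = 40 r_a` and a *fixed* patch radius `L = 30 d_ref`: with a
  `1/d^2` branch, a reference at `20 r_a` distorts log-log slopes by ~0.4,
  and letting `L` grow with `d` makes the tilt-riding configuration's cost
  `d`-dependent, contaminating the axisymmetric decay with an apparent
  `1/d^2` component.
* Near-contact runs (the `c_b = 0.75 c_a` equilibrium distance) use
  `h = 0.09 a`: the short-range repulsive wall only resolves once the
  inter-rim gap holds at least three mesh edges, and the overlap guard
  (`d_min = 2a + 2h`) must admit distances below the expected
  `d* = 2.36 a`.
* Far-field points are placed where the signal exceeds the discretization
  error bar severalfold: the axisymmetric fit uses six distances in
  `[5, 12] a` with one refinement level (signals 1e-3 to 3e-2 kT against a
  ~1e-4 kT error bar); the saddle fit uses five distances in `[5, 15] a`
  at the base level (signals 0.1–1 kT).
* The test-suite profile (`coarse`) runs every experiment end-to-end on
  reduced distance and angular grids; the `production` profile doubles rim
  resolution and angular densities.  Well depths and equilibrium distances
  are quadratically interpolated through the three lowest points and
  reported alongside the level-difference error bar.

## What the computations do and do not show

The package reproduces, at reduced resolution, the orientation rule (convex
scaffolds front each other with their lowest-contact-angle faces; the BAR
geometry aligns short axes, long axes parallel), the pure repulsion of
isotropic caps with its `1/d^4` far field, the anisotropy-induced
attraction with its `1/d^2` far field and finite equilibrium distance
(`d* ≈ 2.34 a` against the reference value 2.36 for `c_b = 0.75 c_a`), the
~1 kT free-energy well of saddle scaffolds with entropic repulsion below
2 kT, and the tens-of-kT binding of BAR-like scaffolds with an entropy
contribution of order 1 kT.  The lateral-tension control (decay length
`xi = sqrt(kappa/gamma)` two orders of magnitude above the scaffold size)
verifies that the curvature part of the interaction is insensitive to the
far-field treatment.

Limitations to keep in mind: the entropic interaction is a lower bound
(symmetric orientations only); membrane-undulation entropy and many-body
effects are not modelled; the `c_b = 0` (cylinder-like) case has its
claimed attraction-to-contact below the discretization error bar, so the
package asserts only the absence of a resolvable minimum; and the
linearized Monge-gauge oracle used for cross-checks is valid only for
shallow scaffolds, which is precisely why it serves as an independent check
there and not elsewhere.

Two quantitative points deserve flagging.  First, at the BAR optimum the
orientational-entropy energy computed from the Boltzmann integral is
3.5–5 kT across the short-axis curvature range (stable under doubling of
both angular grids), not the ~1 kT sometimes quoted for this geometry: at
separations far below the scaffold length, most in-plane orientations are
sterically excluded, and the window term `−kT ln(Δφ_allowed/90°)` alone
contributes ~2 kT before tilt confinement is counted.  The operative
conclusion — the entropy cost is negligible against the tens-of-kT elastic
binding — is unaffected.  Second, with the tension decay length at
`xi = 50–100` scaffold radii the tension part of the interaction is of
order 1e-3 kT, below the discretization error; the test suite therefore
bounds its magnitude and verifies the gamma-independence of the curvature
part, rather than resolving the (sub-noise) sign of the tension part
itself.

## A worked example

```{r example}
library(memscaffold)

shape <- shape_preset("shallow_circular", cb_over_ca = -1)
params <- model_params(profile = "coarse")
curve <- elastic_interaction(shape, c(3, 4, 5, 7, 10), params)
print(curve)
fit <- fit_power_law(curve, c(3, 10))
print(fit)
```
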