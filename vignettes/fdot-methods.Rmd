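---
title: "Models and methods behind fdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fdot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fdot)
```

# Scope

`fdot` simulates frequency-domain diffuse optical tomography (FD-DOT) in
segmented head models and quantifies how much the *anatomy itself* — when
an atlas head is substituted for the subject's own — perturbs the
simulated measurements and their absorption sensitivities. The package
contains two independent forward solvers (voxel Monte Carlo and a P1
finite-element diffusion approximation), a harmonic level-set algorithm
separating subarachnoid from sulcal cerebrospinal fluid, a two-step
linear registration that forces a population of heads onto one shared
exterior, a synthetic neonatal-head phantom generator that stands in for
an MRI database, and the approximation-error statistics connecting it
all.

Units are fixed package-wide: lengths in mm, time in ns, optical
coefficients in mm^-1, modulation frequency in GHz (so 100 MHz = 0.1 and
the phase `2*pi*f*t` is in radians with `t` in ns). The vacuum speed of
light is 299.792458 mm/ns.

# Forward models

## Monte Carlo transport with the microscopic Beer-Lambert law

Photon packets are launched from a collimated disk of radius R
(default 1.5 mm) on the scalp toward the probe's centre of curvature.
Free path lengths are sampled from the local scattering coefficient,
directions from the Henyey-Greenstein phase function with the local
anisotropy `g`, and the packet is traced through the voxel grid with
exact axis-aligned chord lengths. When the scattering coefficient
changes across a voxel face, the remaining free path is rescaled by the
ratio of the old to the new coefficient; this is implemented by keeping
the free path as a dimensionless budget that each segment consumes in
proportion to the local `mu_s`, which is algebraically identical. At the
exterior boundary the packet either exits or is specularly reflected, a
binary decision drawn against the unpolarized Fresnel reflectance.
Specular reflection at launch is not applied: packets start on the
boundary with full weight.

Absorption is *not* applied during transport (the microscopic
Beer-Lambert law): trajectories are independent of `mu_a`, and the
weight of a detected photon is `exp(-sum_j mu_a_j * l_pj)` over its
stored per-voxel partial pathlengths. Everything downstream — the FD
measurement `X + iY` with `X = sum_p w_p cos(2 pi f t_p)` (divided by
the number of launched packets), `ln A`, the phase, tissue-sweep
perturbations and the absorption Jacobians — is recomputed from the
stored records for any absorption field without re-transport
("replay"). The exact replay derivatives are
`dX/dmu_a_j = -sum_p l_pj w_p cos(2 pi f t_p)` (and the sine analogue),
reduced to ln A and phase rows through
`d lnA = (X dX + Y dY)/A^2`, `d phase = (X dY - Y dX)/A^2`.

Each photon owns a counter-based RNG stream derived from
`(seed, launch index)` (splitmix64), so any subset of launch indices can
be re-simulated bit-identically; the test suite uses this to verify the
strict-replay contract.

Choices a user may need to know:

* **Termination**: packets die on exit or at a time-of-flight cutoff
  (default 5 ns, configurable). No Russian roulette is needed because no
  weight is lost in flight. The cutoff truncates the extreme late tail
  at long source-detector separations; with the default absorptions the
  discarded weight is negligible (`exp(-mu_a * c t)` at 5 ns is below
  1e-4 for all tissues here).
* **Detection**: a packet is detected when its exit point lies within
  the detector patch radius of a detector centre (chord distance; at
  patch radii of 1.5-3 mm the difference from the surface geodesic is
  far below the voxel size). There is no numerical aperture.
* **Zero-scattering voxels** are crossed in a straight line without
  consuming the free-path budget.

## Diffusion approximation with P1 finite elements

The FD diffusion approximation
`-div(kappa grad Phi) + (i omega / c + mu_a) Phi = 0` with the Robin
condition `(1 - rho) Phi + 2 (1 + rho) nu . kappa grad Phi = 4 Q_k` is
discretized with first-order tetrahedral elements; `kappa` is
`1 / (3 (mu_a + mu_s'))` and is treated as a function of `mu_a`
throughout, including in the sensitivities. The source `Q_k` is the
characteristic function of the source patch divided by its area; the
measurement is `M_jk = 1/2 (1 - rho)/(1 + rho) * int P_j Phi_k dS` with
`P_j` the characteristic function of the detector patch. All element
integrals (P1 stiffness, mass, boundary mass) are exact.

The effective reflection coefficient `rho` is computed once per
refractive-index pair by numerically integrating the unpolarized Fresnel
reflectance over the hemisphere of incidence angles (the standard
effective-reflectance construction): with
`R_phi = int 2 sin t cos t R_F(t) dt` and
`R_j = int 3 sin t cos^2 t R_F(t) dt`,
`rho = (R_phi + R_j) / (2 - R_phi + R_j)`. It is zero for matched
indices and monotone in the index ratio; for tissue `n = 1.4` against
air it is about 0.49.

**Linear algebra.** The real part of the system matrix is symmetric
positive definite and is factorized once with a sparse (CHOLMOD)
Cholesky decomposition. The complex-symmetric system `(A + iB) x = b`
(with `B = (omega/c) M` a mass-matrix perturbation) is then solved by a
conjugate-orthogonal CG iteration (COCG, unconjugated inner products)
preconditioned with that Cholesky factor; it converges to a relative
residual of 1e-11 in a handful of iterations at 100 MHz because `B` is
small relative to `A`. One factorization serves every source and
detector (adjoint) right-hand side — the invariant
`nFactorizations() == 1` is asserted in the tests.

**Adjoint sensitivities.** The adjoint field solves the same operator
with `4 P_j` as boundary data. The Fréchet derivative of `M_jk` with
respect to absorption in an element indicator `zeta` is
`1/4 (1 - rho) int zeta ( (1 / (3 (mu_a + mu_s')^2)) grad Phi_k . grad Phi*_j - Phi_k Phi*_j ) dx`,
where the gradient term is the chain rule through `kappa`. On the
discrete level this formula is *exactly* the derivative of the discrete
measurement (it was derived from the assembled system, and the
acceptance suite verifies it against perturb-and-resolve central
differences at `delta = 1e-5 mm^-1` to better than 1e-3 relative). This
exactness holds at any mesh resolution, which is why the acceptance
check runs on a sphere of roughly 1e4 nodes rather than the largest
mesh the hardware could hold: the property being tested does not sharpen
with mesh size, and the smaller problem keeps the whole suite inside a
half-hour on one CPU.

One numerical caveat applies to the finite-difference *oracle* rather
than to the derivative itself: a central difference of the measurement
under `mu_a +/- delta` in one element can only resolve sensitivities
above the cancellation floor `eps * |M| / (2 delta)` of double
precision. Elements buried far from the optodes have sensitivities many
orders below `|M|`; for them the measured FD "error" grows as `delta`
shrinks (pure round-off) while the adjoint value stays put. The
validation therefore draws its random elements from those whose
sensitivity exceeds ~1e4x that floor (the margin covers the
rounding amplification of the sparse solves, observed to be about an
order of magnitude) — a representability constraint of
the oracle, not a restriction of the derivative formula.

## Meshing

Label volumes are meshed by splitting every labelled voxel into six
Kuhn (Freudenthal) tetrahedra. All cubes are cut identically along the
same main diagonal, which makes the mesh conforming across voxel faces
by construction, preserves per-tissue volume exactly, and — usefully for
the population study — produces *identical* node and element numbering
for any two heads that share an exterior mask, so Jacobian columns align
element-by-element without interpolation. The price is a staircase
boundary; its effect shows up as a slow O(h) component in boundary-value
problems (see the convergence notes below). Local refinement near the
optode patches is available through recursive longest-edge (Rivara)
bisection with conformity closure; three passes halve the local edge
length. The study driver leaves refinement off at its default grid.

Optode patches are the boundary triangles whose centroid lies within the
patch radius of the optode centre; a triangle claimed by two patches
raises an error (sources and sensors must not overlap).

# CSF two-compartment segmentation

The outer CSF is split into semidiffusive subarachnoid CSF (CSF-1) and
clearer sulcal CSF (CSF-2, pooled with the ventricles) by solving
`Delta u = 0` on the CSF domain minus a one-voxel plate along the
longitudinal fissure, with `u = 0` on brain-adjacent boundary, `u = 1`
on skull/plate-adjacent boundary, and homogeneous Neumann conditions in
an `a`-neighbourhood of any junction of the two Dirichlet sets (the two
sets must never touch; with `a = 0` and a genuine junction the domain
builder refuses). The level set `u = theta` defines the interface;
voxels above it stay CSF-1. Defaults: `theta = 0.6` (the split is
insensitive to it near 0.6 on smooth phantoms; it is exposed because the
appropriate value for real anatomies is an expert choice),
`a = 1.0` mm — two fine voxels, just enough to absorb single-voxel
segmentation artefacts. The fissure plate is one voxel thick at the
head-centroid midline and starts at the lowest grey/white-matter voxel.

Voxel centres sit on the shared Kuhn diagonal of their six tetrahedra,
so the P1 interpolation at a centre is simply the mean of the two
diagonal corner values; plate voxels (outside the mesh) take the nearest
node value. The split only relabels CSF voxels: total CSF volume is
conserved exactly.

Following the source model of the study design, the two-compartment
optics are used by the Monte Carlo solver only; the diffusion solver
keeps a single semidiffusive CSF compartment, because the diffusion
approximation is not valid in nearly clear media.

On concentric spheres the solution has the closed form
`u(r) = (1/r_in - 1/r)/(1/r_in - 1/r_out)`; the suite checks the value
at mid-shell to 1% and the `theta = 0.6` interface radius to half a
voxel, and verifies that the error shrinks under mesh refinement. The
observed refinement ratio is above 2 but below the clean P1 factor of 4:
the staircase Dirichlet boundary contributes an O(h) perturbation that
the interior O(h^2) rate cannot beat. This is a property of voxelized
boundaries, not of the solver.

# Registration to a common exterior

The affine step minimizes
`RE = SRE + gamma1 * LRE1 + gamma2 * LRE2` where SRE is the mean squared
distance over all 254 cranial points (249 dense surface points + 5
landmarks) and LRE1/LRE2 are the mean squared distances of {Iz, Nz} and
{LPA, RPA}. Both point sets are first translated so the nasions
coincide; the 12-parameter transform is then solved as three independent
4-parameter weighted least-squares problems, with block weights
`1/sqrt(block size)` and `sqrt(gamma)`. The landmark rows are re-stacked
in addition to their appearance in the surface block (254 + 4 stacked
points); a pure-254-point variant with reweighted landmark rows is
available behind `restackLandmarks = FALSE`. Defaults
`gamma1 = 0.45, gamma2 = 0.55` sit at the midpoint of the plausible
0.4-0.5 / 0.5-0.6 ranges, since an automated pipeline has no visual
landmark-quality step. Orientation is enforced after the fact: a fitted
transform with negative determinant is rejected (hemisphere mirroring is
handled upstream, not by the fit).

The second step solves three per-axis scale factors about the nasion
from closest-point pairs between the subject and reference surfaces
inside the probe region (all points within a configurable radius of the
probe centroid); being a least-squares fit it can only reduce the
probe-region RMSE.

Shell filling then takes the reference scalp-and-skull mask — all
labelled voxels within the shell thickness of the exterior — and fills
its interior with the warped subject labels (nearest-label resampling at
the reference voxel centres): warped tissue outside the reference head
is cut, interior voxels the warped model leaves empty become S&S. Two
quality rules reject a subject: (1) within the probe region, the
nonzero-region mismatch between the warped and reference models may
involve only S&S and CSF-1, with at most 10 mm^3 of CSF-1 mismatch
("10 mm^3" is read as a volume, not a count of 0.125 mm^3 voxels; both
are configurable); (2) no white-matter voxel may be cut from the probe
region — together these guarantee grey matter always separates the
extracerebral tissues from white matter under the probe. Accepted
subjects share the reference exterior bit-exactly, hence identical
optode positions and aligned simulation grids.

# The synthetic phantom population

The generator emulates the *structure* of a segmented neonatal head —
nested scalp-and-skull, subarachnoid CSF, grey matter and white matter
shells around ellipsoids, CSF-filled sulci, and ventricles — with
controllable inter-individual variation. Sulci are meridional grooves
(bands of constant azimuth) cut into the grey matter to a configurable
depth and filled with CSF; their count, depth, width and phase are
parameters, with the phase drawn per head so that sulcus *placement*
varies across the population, which the study design identifies as a key
error source. Full-scale defaults correspond to a term neonate:
semi-axes (48, 58, 45) mm (head circumference ~33 cm), shell 3 mm
(clinically the median under the cranial points is ~3 mm), subarachnoid
CSF 1.5 mm, grey matter 7 mm, eight grooves of 5 mm depth. Population
spreads are fractional standard deviations; the default size spread
0.063 matches a 2.1/33.4 relative circumference spread. The cranial
point set is a deterministic 12-ring latitude/azimuth grid of 249
surface points plus the five landmarks, ray-cast from the head centroid
to the voxel surface — a synthetic, reproducible stand-in for a dense
10-5 montage that provides the named correspondences the registration
needs.

What the phantoms do *not* emulate: real cortical folding (grooves are
smooth meridional bands, not gyral anatomy), tissue heterogeneity within
a compartment, segmentation noise, asymmetry beyond the ellipsoid axes,
and faces (no nose/mouth exclusions are needed when placing the probe).
Consequently, a passing population study demonstrates that the
*machinery* — registration to a shared shell, aligned Jacobians,
error statistics, detectability ratios — behaves correctly under
controlled anatomical variation; the magnitudes of the ratios on real
MRI-derived anatomies will differ.

The probe is pressed onto the scalp by fitting a sphere to the covered
surface region, projecting the planar template radially toward the
sphere centre, and then relaxing each optode along the surface
(coordinate descent with a shrinking step, distances measured as arcs on
the fitted sphere) to match the template separations; the launch target
for all sources is the centre of a sphere fitted to the final optode
positions. On a spherical phantom the recovered separations match the
template to 2%.

# Approximation-error statistics

Given the reference measurement vector and the population vectors
(log-amplitude and phase treated as separate real vectors, masked to
source-detector separations below 55 mm), the error realizations are
`e_i = y_ref - y_i`, summarized by the sample mean, the unbiased sample
covariance, its eigendecomposition, and `STD = sqrt(trace)`. The
eigenpairs are computed through the N x N Gram matrix of the centred
differences — the same nonzero spectrum as the m x m covariance at a
fraction of the cost, with clean rank handling (rank is at most N - 1;
asserted in the tests). Difference-mode statistics replace
`y_ref - y_i` with `(J_ref - J_i) delta_x` for a fixed per-element
perturbation; the shared structured grids make the Jacobian columns
comparable without interpolation. Detectability is summarized by
`||P_v mu_e|| / STD` (how representative the reference is),
`||P_v delta_y|| / STD` (visibility of a signal over the anatomical
noise), and in difference mode additionally
`||delta_y|| / ||mu_e||`. All ratios are invariant under a common
rescaling of the inputs. The reference difference signal `delta_y` for
the ball perturbation is computed from a genuinely perturbed forward
solve (per-element absorption override in the FEM path; record
re-weighting in the MC path), not from the linearized product.

The default desk-scale study (`studyConfig()`): N = 20 half-scale heads
generated at 0.5 mm, registered at 0.5 mm, simulated with the diffusion
solver on a 1.5 mm grid (about 2e4 nodes per head), a 4 + 4 optode probe
at 8 mm pitch on the left hemisphere, 100 MHz, and a ball perturbation
of radius 5 mm and `delta mu_a = 0.005 mm^-1` centred 7 mm under the
probe — a physiologically scaled stand-in for a ~10% local brain
absorption increase. These sizes were chosen so the full study runs in
minutes on a single CPU while keeping at least two voxels across every
tissue layer at the generation resolution; they are stated here as the
package's reference conditions so results are comparable across runs.

# Known limitations

* The voxel (staircase) boundary limits boundary-value accuracy to
  first order in the voxel size; smooth surface meshing is out of scope.
* The MC solver computes absorption Jacobians only (scattering
  sensitivities would require a different replay).
* The DA solver keeps one CSF compartment; clear-CSF physics
  (radiosity-diffusion coupling) is out of scope.
* Phase-sign conventions differ between the solvers (the MC phase grows
  with time of flight; the DA fluence with `+i omega / c` rotates the
  opposite way); cross-solver comparisons use the magnitude of
  phase-vs-distance slopes.
* The registration is linear (affine + anisotropic scaling); it cannot
  reproduce local cortical deformation.
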