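---
title: "Biomechanical supine-prone breast registration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical supine-prone breast registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breast PET/CT is acquired supine, diagnostic breast MR prone. Between the two
postures gravity reverses along the anteroposterior axis and the breast — a
soft, nearly incompressible composite of adipose and fibro-glandular tissue
wrapped in skin — deforms by far more than any intensity-driven registration
can bridge reliably, especially for the low-resolution, nearly featureless
PET channel. `breastfem` registers such image pairs by *simulating* the
deformation with a patient-specific finite-element model and only then
applying a small landmark-based refinement, so the transformation never
depends on image intensity.

## The tissue model

Each tissue is an isotropic, nearly incompressible neo-Hookean solid with
strain energy density

$$\psi \;=\; \frac{\mu}{2}\left(\bar I_1 - 3\right)
       \;+\; \frac{K}{2}\left(J - 1\right)^2,
\qquad
\bar I_1 = J^{-2/3}\,\mathrm{tr}(F^TF),\quad J = \det F,$$

where $F$ is the deformation gradient. The initial shear and bulk moduli
derive from Young's modulus $E$ and Poisson's ratio $\nu$ through
$\mu = E/(2(1+\nu))$ and $K = E/(3(1-2\nu))$. The starting material table is

| tissue | $\rho$ (kg/m³) | $E$ (kPa) | $\nu$ |
|---|---|---|---|
| adipose | 950 | 250 | 0.49 |
| fibro-glandular | 1020 | 1875 | 0.49 |
| skin | 1000 | 1000 | 0.49 |

with the fibro-glandular modulus slaved to $7.5\times$ the adipose one
throughout. $\nu = 0.49$ encodes near-incompressibility; the printed
isochoric invariant in some sources degenerates typographically, and the
standard $\bar I_1 = J^{-2/3}\mathrm{tr}(F^TF)$ is implemented.

## Discretisation and solver

The breast label map is meshed with structured 8-node hexahedra (majority
vote per cell, ties toward the stiffer fibro-glandular class), which are more
efficient than tetrahedra at equal node count. A 1 mm skin layer is extruded
outward along averaged surface normals as *thin solid* hexahedra rather than
true shell elements: this keeps a single element technology and lets skin
carry the same constitutive law. At $\nu = 0.49$ low-order elements lock
volumetrically, so the isochoric term is integrated at the full 2×2×2 Gauss
rule and the volumetric term at the element centre only (selective reduced
integration).

Equilibrium under gravity minimises the total potential energy by Newton
iteration with an analytic residual and consistent tangent (verified against
finite differences to $10^{-6}$ relative), a backtracking line search with
an Armijo sufficient-decrease condition, and an incremental gravity ramp: 5
equal increments by default, an increment halves when Newton fails (up to 4
times) and *grows* again after fast convergence, so nearly linear solves
finish in two or three increments. The Armijo condition matters physically:
a plain energy-decrease test admits overshooting steps into buckled
configurations of the stiff thin skin, where the tangent turns indefinite;
demanding decrease proportional to the step keeps the iterates in
well-behaved territory. Adaptive growth and the line search change no
converged answer, only the path to it.

Two linear-solver backends sit behind one interface, chosen by problem size:
a sparse supernodal Cholesky factorisation ordered by a geometric nested
dissection of the structured node cloud, with the factor reused across
Newton iterations while the residual contracts fast (modified Newton); and,
for meshes beyond `direct_maxdof` (default $10^5$ degrees of freedom, where
the factor no longer fits comfortably in memory), a conjugate-gradient
solver preconditioned by a symmetric two-level cycle — Gauss–Seidel
smoothing plus a Galerkin coarse correction on a twice-coarser lattice —
with an Eisenstat–Walker-style forcing term. Should a factorisation still
meet an indefinite tangent (warm starts can land on post-buckled states),
that solve demotes itself to the conjugate-gradient path, which tolerates
indefiniteness through curvature-truncated steps. The internal unit system
is mm–mN–kPa–kg–s (so kPa is exactly mN/mm²); densities enter in kg/m³ and
are converted at the boundary, gravity is 9.81 m/s² with its sign along the
anteroposterior axis encoding posture.

The stated physical boundary condition — chest-wall nodes fixed
anteroposteriorly — leaves two in-plane translations and one rotation
unconstrained, so two chest-wall nodes receive minimal in-plane pins (2 + 1
degrees of freedom); `chest_fix = "all"` fixes all three axes instead.

## Reference-state estimation

Every image is acquired under load, so the supine geometry is not
stress-free. The load-free configuration is recovered by the classical
fixed-point scheme: starting from the observed geometry, forward-solve the
current guess under supine gravity and subtract the mismatch to the observed
surface, `X <- X - damping * (forward(X) - x_obs)`, until the mean surface
mismatch falls below 0.2 mm (a handful of iterations on the phantoms).
The damping factor starts at 1 and halves when the mismatch grows three
iterations in a row or an update produces an unsolvable geometry.

## Patient-specific stiffness

A rigid pre-registration of three chest-wall landmarks absorbs the patient's
repositioning between scanners; the distance between the prone nipple and
the rigidly-mapped supine nipple is the target displacement $V_{max}$. The
adipose modulus is then found by a multi-resolution grid search over
$E \in (0.5, 500)$ kPa: the *initial-table* modulus is simulated first
(mirroring an optimization loop that starts from the initial model), then a
12-point log-spaced coarse pass sweeps the admissible range upward, then up
to two 5-point refinement rounds around the incumbent. Every trial runs the
full reference-state + prone simulation with the fibro-glandular modulus at
$7.5\,E$; the search stops as soon as $|V_{max} - V_n| \le 1$ mm. Failed
solves (the softest moduli can make the supine compression of the stiff
skin shell genuinely unstable) are recorded and skipped; ties within
0.01 mm resolve to the smallest modulus. Consecutive trials warm-start each
other's reference geometry and prone displacement, roughly halving the cost
of a search.

An important consequence of the stiff 1 mm skin layer is that it carries
much of the gravity load by membrane action: on the default phantom the
supine-to-prone nipple displacement spans only about 0.03–4.5 mm across the
three-decade modulus range (about 0.9 mm per octave of $E$ near 2 kPa),
rather than the tens of millimetres seen clinically. The inverse problem
remains well posed — the objective is monotone and the recovery lands within
one grid step of the truth — but its sensitivity is bounded by that skin
dominance, which is a property of the stated material table, not of the
solver.

## Registration and evaluation

Converged node displacements are interpolated to a dense voxel field
(trilinear inside the structured mesh, nearest-inside extrapolation within
2 mm to cover the skin shell, zero outside), inverted per voxel by fixed
point (0.1 mm, 20 iterations), and used to pull the PET-like volume into the
prone frame. Because three landmark pairs cannot determine a 12-dof affine,
the final "affine" refinement is the closed-form similarity transform for 3
points, with the full affine unlocked at ≥ 4 non-coplanar pairs; reflections
are rejected. Registration quality is the 3D target registration error
(TRE), the Euclidean distance between lesion centroids in the fixed MR-like
image and the registered PET-like image; the warped PET lesion is delineated
at 50% of its maximum. Cohort-style summaries use Welch's unpaired t-test
(the safer default when only "unpaired t-test" is specified) for low/high
density (threshold 0.25 volumetric density, not the 25th percentile —
switchable) and small/large volume (median split) groups, and Pearson
correlation of TRE against six image features.

## The synthetic phantom

No clinical data ship with the package, so a seeded generator supplies the
study conditions: a hemispherical breast (default radius 60 mm, 2 mm voxels)
of adipose tissue on a flat chest-wall slab; fibro-glandular tissue as a
union of random ellipsoidal blobs grown and then bisected onto the target
volumetric density (defaults 0.27, the dense-cohort median; 0.15 emulates
the less dense cohort) to within ±0.02; one spherical lesion (6 mm radius)
on the nipple axis at a configurable location ratio; a surface nipple and
three chest-wall landmarks. The CT-like channel has distinct tissue means
plus Gaussian noise (fat darker than gland, as on CT); the PET-like channel
is a near-uniform soft-tissue background with a hot lesion blurred by a
4 mm-FWHM Gaussian, a typical clinical PET kernel. The prone "MR" volume is
the CT-like volume warped through a forward simulation at the ground-truth
moduli (default true adipose E of 2 kPa) plus a small seeded rigid
repositioning; the MR intensity characteristics are therefore CT-like by
construction. Identical spec and seed give bit-identical phantoms, and the
generator never touches the caller's RNG stream.

What the phantom does *not* emulate: Cooper's-ligament anisotropy, real PET
physics (attenuation, counts), MR contrast, chest-wall curvature, or
coil-contact forces. Passing tests therefore demonstrate the correctness and
internal consistency of the mechanics, inverse estimation and registration
machinery under known ground truth — not clinical-grade accuracy on real
anatomy.

## Numerical choices and problem sizes

Newton: relative residual $10^{-6}$, at most 30 iterations per increment.
Reference state: 0.2 mm mean-surface tolerance, 10 iterations. Field
inversion: 0.1 mm, 20 iterations. Fuzzy c-means: fuzzifier 2.0, $10^{-5}$
centroid-shift tolerance, 300 iterations, deterministic quantile
initialisation (25th/75th percentiles for two classes), lowest centroid →
adipose; a voxel exactly on a centroid takes membership 1 there. Plain
intensity clustering is used (no spatial regularisation). The mesh
convergence study evaluates the displacement at the *fixed* nipple landmark
by in-element interpolation rather than at the nearest mesh node, whose
position shifts by up to half an element between refinement rungs and would
otherwise contaminate the comparison. The test-suite and acceptance runs
use the 4 mm element size on the default phantom for the inverse
experiments, the 8/4/2 mm ladder for the convergence study, and default-size
phantoms at an 8 mm test mesh with a reduced grid (8 coarse points, one
3-point refinement) for the five-case registration comparison; these sizes
are the package's chosen desk-scale study conditions, with the 2 mm ladder
rung (about 66k elements) solved by the two-level conjugate-gradient
backend.

## Known limitations

The hexahedral mesher is voxel-aligned and stair-steps the smooth breast
surface (the skin layer inherits that roughness). The similarity baseline
in the five-case comparison is a landmark fit, standing in for an
intensity-similarity affine that clinical data would support. The skin's
thin-solid idealisation at the stated 1000 kPa bounds deformation magnitudes
well below clinical nipple displacements, as discussed above. The chest
wall is planar. Only the adipose modulus is searched (the option to search
both tissues independently exists but is off by default, matching the
near-constant published modulus ratios).
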