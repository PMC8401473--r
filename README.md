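# breastfem

Patient-specific biomechanical registration of supine and prone breast
images.

## The problem

Breast PET/CT is acquired with the patient supine; diagnostic breast MR is
acquired prone. Between those postures the breast — soft, nearly
incompressible tissue hanging from the chest wall — deforms by centimetres
under gravity, far beyond what intensity-driven registration can bridge for
a blurry PET channel. `breastfem` closes that gap physically: it builds a
finite-element model of the individual breast from the structural (CT-like)
image, simulates the gravity-induced supine→prone deformation, personalises
the tissue stiffness so the simulated nipple displacement matches the
observed one, and finishes with a landmark similarity refinement. Accuracy
is quantified as the 3D target registration error (TRE) of lesion
centroids. It is aimed at researchers in deformable medical-image
registration and breast biomechanics.

## The model

Tissues are isotropic nearly incompressible neo-Hookean solids,

ψ = μ/2 (Ī₁ − 3) + K/2 (J − 1)²,  Ī₁ = J^(−2/3) tr(FᵀF),  J = det F,

with μ = E/(2(1+ν)), K = E/(3(1−2ν)), ν = 0.49, and the starting moduli
E = 250 / 1875 / 1000 kPa (densities 950 / 1020 / 1000 kg/m³) for adipose,
fibro-glandular tissue and the 1 mm skin layer; the fibro-glandular modulus
stays 7.5× the adipose one. The pipeline is:

1. preprocessing: isotropic resampling, breast cropping, fuzzy c-means
   segmentation into adipose and fibro-glandular tissue;
2. structured hexahedral meshing with an extruded skin layer, verified by a
   mesh-convergence ladder (≤ 2% displacement change);
3. quasi-static total-Lagrangian solves under gravity (selective reduced
   integration against volumetric locking), including estimation of the
   load-free reference state by fixed-point iteration;
4. rigid pre-registration of chest-wall landmarks to measure the target
   nipple displacement V_max, then a grid search over the adipose modulus
   E ∈ (0.5, 500) kPa that stops when |V_max − V_n| ≤ 1 mm;
5. dense-field warping of the PET-like volume into the prone frame plus a
   closed-form similarity refinement from three chest-wall landmarks;
6. evaluation: lesion-centroid TRE, cohort group tests, feature
   correlations.

Because no clinical images ship with the package, a seeded phantom module
generates hemispherical two-tissue breasts with known ground-truth moduli,
landmarks and lesions, and forward-simulates their prone appearance.

## A worked example

```r
library(breastfem)

spec <- phantom_spec(seed = 7)            # 60 mm breast, density 0.27,
ph   <- make_supine_phantom(spec)         # true adipose E = 2 kPa
ph   <- make_prone_ground_truth(ph, element_size = 4)

mesh <- voxel_to_hex_mesh(ph$labels_supine, 4, nipple = ph$nipple_supine)
mesh <- add_skin_layer(mesh, 1)

pre <- rigid_preregister(ph$nipple_supine, ph$nipple_prone,
                         ph$chest_wall_landmarks,
                         ph$chest_wall_landmarks_prone)
pre$Vmax
#> [1] 3.258036
opt <- grid_search_optimize(mesh, pre$Vmax)
opt$state$history
#>             E         Vn  objective   ok
#> 1 250.0000000 0.03108257 3.22693554 TRUE
#> 2   0.6667607 4.65295479 1.39493668 TRUE
#> 3   1.1856869 4.36240119 1.10438309 TRUE
#> 4   2.1084825 3.19962946 0.05838865 TRUE
```

Reading the history: the search first simulates the initial material table
(E = 250 kPa; the stiff breast barely sags, 0.031 mm, missing the 3.26 mm
target by 3.23 mm), then sweeps the admissible range upward and stops at
E = 2.11 kPa, where the simulated nipple displacement (3.20 mm) is within
0.06 mm of the target — recovering the phantom's true 2 kPa adipose modulus
to within 5%. `evaluate_case(ph)` then warps the PET-like volume with the
fitted model and reports the lesion TRE against the landmark-similarity
baseline.

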