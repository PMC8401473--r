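#' Specification of a synthetic supine/prone phantom
#'
#' Defines a hemispherical two-tissue breast (adipose background with
#' fibro-glandular blobs at a target volumetric density) attached to a flat
#' chest-wall slab, with a spherical lesion on the nipple axis, a surface
#' nipple landmark and three chest-wall landmarks. The defaults emulate a
#' dense-breast case: radius 60 mm, volumetric density 0.27, 2 mm voxels,
#' with the ground-truth adipose modulus 2 kPa and a fibro-glandular /
#' adipose stiffness ratio of 7.5.
#'
#' @param breast_radius hemisphere radius, mm
#' @param chest_wall_extent chest-wall slab thickness behind the plane, mm
#' @param volumetric_density_target fibro-glandular volume fraction, in (0,1)
#' @param lesion_radius spherical lesion radius, mm
#' @param lesion_location_ratio_target lesion centre along the nipple axis as
#'   a fraction of the chest-to-surface distance, in (0,1)
#' @param true_E_adipose ground-truth adipose Young's modulus, kPa
#' @param stiffness_ratio fibro-glandular / adipose modulus ratio
#' @param voxel_spacing isotropic voxel size, mm
#' @param seed integer RNG seed; identical (spec, seed) pairs give
#'   bit-identical phantoms
#' @param ct_noise_sd additive Gaussian noise of the CT-like volume
#' @param pet_fwhm Gaussian blur FWHM of the PET-like volume, mm
#' @return list of class `breastfem_phantom_spec`
#' @export
phantom_spec <- function(breast_radius = 60, chest_wall_extent = 8,
                         volumetric_density_target = 0.27, lesion_radius = 6,
                         lesion_location_ratio_target = 0.5,
                         true_E_adipose = 2.0, stiffness_ratio = 7.5,
                         voxel_spacing = 2, seed = 1L,
                         ct_noise_sd = 10, pet_fwhm = 4) {
  if (volumetric_density_target <= 0 || volumetric_density_target >= 1)
    stop("volumetric_density_target must lie in (0, 1)")
  if (voxel_spacing <= 0) stop("voxel_spacing must be positive")
  rr <- lesion_radius / breast_radius
  if (lesion_location_ratio_target < rr ||
      lesion_location_ratio_target > 1 - rr)
    stop("lesion of radius ", lesion_radius,
         " mm does not fit inside the breast at location ratio ",
         lesion_location_ratio_target, " (needs ratio in [",
         signif(rr, 3), ", ", signif(1 - rr, 3), "])")
  structure(list(breast_radius = breast_radius,
                 chest_wall_extent = chest_wall_extent,
                 volumetric_density_target = volumetric_density_target,
                 lesion_radius = lesion_radius,
                 lesion_location_ratio_target = lesion_location_ratio_target,
                 true_E_adipose = true_E_adipose,
                 stiffness_ratio = stiffness_ratio,
                 voxel_spacing = voxel_spacing, seed = as.integer(seed),
                 ct_noise_sd = ct_noise_sd, pet_fwhm = pet_fwhm),
            class = "breastfem_phantom_spec")
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_phantom_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# reference CT-like tissue intensity means
CT_MEANS <- c(background = 0, adipose = 100, gland = 200, lesion = 210,
              chest_wall = 300)

#' Generate the supine phantom
#'
#' Builds the supine label map (hemisphere of adipose on a chest-wall slab,
#' fibro-glandular tissue as a union of random ellipsoidal blobs grown and
#' then bisected to the target density, one spherical lesion), a CT-like
#' volume (distinct tissue means plus Gaussian noise), and a PET-like volume
#' (near-uniform soft-tissue uptake with a hot lesion, blurred to emulate low
#' PET resolution). Prone fields remain unset until
#' [make_prone_ground_truth()].
#'
#' @param spec a [phantom_spec()]
#' @return list of class `breastfem_phantom`: `ct_supine`, `pet_supine`,
#'   `labels_supine`, `nipple_supine`, `lesion_centroid_supine`,
#'   `chest_wall_landmarks` (3 x 3 mm), `achieved_density`, `truth`
#' @export
make_supine_phantom <- function(spec) {
  stopifnot(inherits(spec, "breastfem_phantom_spec"))
  R <- spec$breast_radius
  s <- spec$voxel_spacing
  margin <- 4
  xv <- seq(-R - margin, R + margin, by = s)
  zv <- seq(-spec$chest_wall_extent, R + margin, by = s)
  d <- c(length(xv), length(xv), length(zv))
  origin <- c(xv[1], xv[1], zv[1])
  X <- array(rep(xv, times = d[2] * d[3]), d)
  Y <- array(rep(rep(xv, each = d[1]), times = d[3]), d)
  Z <- array(rep(zv, each = d[1] * d[2]), d)
  r2 <- X^2 + Y^2 + Z^2

  lab <- array(0L, d)
  lab[Z < 0] <- LABELS[["chest_wall"]]
  breast <- r2 <= R^2 & Z >= 0
  lab[breast] <- LABELS[["adipose"]]
  nbreast <- sum(breast)

  with_phantom_seed(spec$seed, {
    # fibro-glandular blobs: grow until the density target is crossed,
    # then bisect the scale of the last blob onto the target
    gland <- array(FALSE, d)
    target <- spec$volumetric_density_target
    blob_mask <- function(ctr, ax) {
      ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
        ((Z - ctr[3]) / ax[3])^2 <= 1
    }
    last <- NULL
    for (b in 1:400) {
      dens <- sum(gland & breast) / nbreast
      if (dens >= target) break
      u <- stats::runif(3, -1, 1)
      ctr <- c(u[1:2] * 0.65 * R, (0.08 + 0.77 * (u[3] + 1) / 2) * R)
      ax <- stats::runif(3, 0.10 * R, 0.28 * R)
      last <- list(ctr = ctr, ax = ax, prev = gland)
      gland <- gland | blob_mask(ctr, ax)
    }
    dens <- sum(gland & breast) / nbreast
    if (dens > target && !is.null(last)) {
      lo <- 0; hi <- 1
      for (it in 1:25) {
        mid <- (lo + hi) / 2
        cand <- last$prev | blob_mask(last$ctr, mid * last$ax)
        dc <- sum(cand & breast) / nbreast
        if (dc > target) hi <- mid else lo <- mid
      }
      gland <- last$prev | blob_mask(last$ctr, hi * last$ax)
    }
    lab[gland & breast] <- LABELS[["gland"]]

    # lesion on the nipple axis at the target location ratio
    lc <- c(0, 0, spec$lesion_location_ratio_target * R)
    les <- (X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2 <= spec$lesion_radius^2
    lab[les & breast] <- LABELS[["lesion"]]

    labels <- label_map(lab, rep(s, 3), origin)
    dens <- breast_volume_and_density(labels)$density

    ct <- array(CT_MEANS[lab + 1], d) +
      stats::rnorm(prod(d), sd = spec$ct_noise_sd)
    soft <- lab != 0L
    pet0 <- array(0, d)
    pet0[soft] <- 10
    pet0[les & breast] <- 100
    sigma <- spec$pet_fwhm / (2 * sqrt(2 * log(2)))
    pet <- gaussian_blur3(pet0, sigma, rep(s, 3)) +
      stats::rnorm(prod(d), sd = 0.5)

    lesidx <- which(lab == LABELS[["lesion"]], arr.ind = TRUE)
    lescen <- unname(colMeans(voxel_to_world(labels, lesidx - 1)))

    structure(list(
      ct_supine = volume(ct, rep(s, 3), origin),
      pet_supine = volume(pet, rep(s, 3), origin),
      labels_supine = labels,
      mr_prone = NULL, labels_prone = NULL,
      nipple_supine = c(0, 0, R), nipple_prone = NULL,
      lesion_centroid_supine = lescen, lesion_centroid_prone = NULL,
      chest_wall_landmarks = rbind(c(0.8 * R, 0, 0),
                                   c(-0.5 * R, 0.6 * R, 0),
                                   c(-0.5 * R, -0.6 * R, 0)),
      chest_wall_landmarks_prone = NULL,
      achieved_density = dens, truth = spec),
      class = "breastfem_phantom")
  })
}

#' @export
print.breastfem_phantom <- function(x, ...) {
  cat("<Phantom> R=", x$truth$breast_radius, " mm, density ",
      signif(x$achieved_density, 3), " (target ",
      x$truth$volumetric_density_target, "), lesion ratio target ",
      x$truth$lesion_location_ratio_target,
      if (!is.null(x$mr_prone)) ", prone ground truth set" else
        ", supine only", "\n", sep = "")
  invisible(x)
}

# separable 3D Gaussian blur (sigma in mm), edge-replicated
gaussian_blur3 <- function(arr, sigma_mm, spacing) {
  for (k in 1:3) {
    sv <- sigma_mm / spacing[k]
    hw <- max(1L, ceiling(3 * sv))
    ker <- stats::dnorm(seq(-hw, hw) / sv)
    ker <- ker / sum(ker)
    d <- dim(arr)
    perm <- c(k, setdiff(1:3, k))
    a <- aperm(arr, perm)
    dm <- dim(a)
    m <- matrix(a, dm[1], dm[2] * dm[3])
    mp <- rbind(m[rep(1, hw), , drop = FALSE], m,
                m[rep(dm[1], hw), , drop = FALSE])
    f <- stats::filter(mp, ker, sides = 2)
    m <- f[(hw + 1):(hw + dm[1]), , drop = FALSE]
    arr <- aperm(array(m, dm), order(perm))
  }
  arr
}

#' Forward-simulate the prone ground truth of a phantom
#'
#' Runs the reference-state estimation and prone-gravity solve with the
#' phantom's true moduli, then warps the supine CT-like volume into the
#' prone MR-like volume and records the ground-truth prone nipple, lesion
#' centroid and chest-wall landmarks. A small seeded rigid repositioning
#' (patient motion between scanners) is applied to the prone/MR frame unless
#' `reposition = FALSE`.
#'
#' @param case a `breastfem_phantom` from [make_supine_phantom()]
#' @param materials [material_params()]; default: the phantom's ground truth
#'   (`true_E_adipose`, `stiffness_ratio`, standard densities and skin)
#' @param config a [fem_config()]
#' @param element_size FE element size for the forward simulation, mm
#' @param reposition apply a seeded rigid motion to the prone frame
#' @return the phantom with `mr_prone`, `labels_prone`, `nipple_prone`,
#'   `lesion_centroid_prone`, `chest_wall_landmarks_prone`, the forward
#'   `field` (supine frame), `mesh`, `solution` and `reposition` set
#' @export
make_prone_ground_truth <- function(case, materials = NULL,
                                    config = fem_config(), element_size = 4,
                                    reposition = TRUE) {
  stopifnot(inherits(case, "breastfem_phantom"))
  spec <- case$truth
  if (is.null(materials))
    materials <- material_params(E_adipose = spec$true_E_adipose,
                                 stiffness_ratio = spec$stiffness_ratio)
  mesh <- voxel_to_hex_mesh(case$labels_supine, element_size,
                            nipple = case$nipple_supine)
  mesh <- add_skin_layer(mesh, config$skin_thickness)
  sol <- simulate_supine_to_prone(mesh, materials, config)

  # MR-frame grid: extended anteriorly so the hanging breast stays in view
  s <- spec$voxel_spacing
  R <- spec$breast_radius
  ext <- ceiling((0.45 * R + 10) / s) * s
  dsup <- dim(case$labels_supine$data)
  dmr <- dsup + c(0L, 0L, as.integer(round(ext / s)))
  mr_grid <- volume(array(0, dmr), rep(s, 3), case$labels_supine$origin)

  field <- field_to_grid(sol, case$labels_supine)

  Tr <- if (isTRUE(reposition)) {
    with_phantom_seed(spec$seed + 1000L, {
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      ang <- stats::runif(1, 2, 6) * pi / 180
      Kx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                     axis[2], -axis[1], 0), 3, 3)
      Rm <- diag(3) + sin(ang) * Kx + (1 - cos(ang)) * Kx %*% Kx
      tr <- stats::runif(3, -6, 6)
      A <- diag(4); A[1:3, 1:3] <- Rm; A[1:3, 4] <- tr
      structure(A, class = "breastfem_affine", kind = "rigid")
    })
  } else {
    structure(diag(4), class = "breastfem_affine", kind = "rigid")
  }

  mr <- warp_volume(case$ct_supine, field, target = mr_grid,
                    direction = "forward", post = Tr)
  labp <- warp_volume(case$labels_supine, field, target = mr_grid,
                      direction = "forward", post = Tr, interp = "nearest")

  # ground-truth landmarks from the node displacement field; the nipple uses
  # the in-element projection so coarse stair-stepped meshes (whose support
  # can miss the surface landmark) still carry the full surface motion
  nip <- case$nipple_supine +
    displacement_at_point(mesh, sol$u, case$nipple_supine)
  lesvox <- which(case$labels_supine$data == LABELS[["lesion"]], arr.ind = TRUE)
  pts <- voxel_to_world(case$labels_supine, lesvox - 1)
  adv <- pts + sample_field(field, pts)
  case$nipple_prone <- drop(apply_affine(Tr, rbind(nip)))
  case$lesion_centroid_prone <- unname(colMeans(apply_affine(Tr, adv)))
  case$chest_wall_landmarks_prone <- apply_affine(Tr, case$chest_wall_landmarks)
  case$mr_prone <- mr
  case$labels_prone <- labp
  case$field <- field
  case$mesh <- mesh
  case$solution <- sol
  case$reposition <- Tr
  case$materials_truth <- materials
  case
}

#' Write a phantom case to disk
#'
#' Writes the NIfTI volumes (`ct_supine`, `pet_supine`, `labels_supine`, and
#' if present `mr_prone`, `labels_prone`) and a JSON file with landmarks,
#' achieved density and the ground-truth spec.
#'
#' @param case a `breastfem_phantom`
#' @param dir output directory (created if missing)
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$ct_supine, file.path(dir, "ct_supine.nii.gz"))
  write_volume(case$pet_supine, file.path(dir, "pet_supine.nii.gz"))
  write_volume(case$labels_supine, file.path(dir, "labels.nii.gz"))
  if (!is.null(case$mr_prone)) {
    write_volume(case$mr_prone, file.path(dir, "mr_prone.nii.gz"))
    write_volume(case$labels_prone, file.path(dir, "labels_prone.nii.gz"))
  }
  meta <- list(
    nipple_supine = case$nipple_supine, nipple_prone = case$nipple_prone,
    lesion_centroid_supine = case$lesion_centroid_supine,
    lesion_centroid_prone = case$lesion_centroid_prone,
    chest_wall_landmarks = case$chest_wall_landmarks,
    chest_wall_landmarks_prone = case$chest_wall_landmarks_prone,
    achieved_density = case$achieved_density,
    truth = unclass(case$truth))
  jsonlite::write_json(meta, file.path(dir, "landmarks.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
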