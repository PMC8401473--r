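test_that("phantom generation is bit-identical under a fixed seed", {
  a <- make_supine_phantom(small_spec(volumetric_density_target = 0.15))
  b <- make_supine_phantom(small_spec(volumetric_density_target = 0.15))
  expect_identical(a$ct_supine$data, b$ct_supine$data)
  expect_identical(a$pet_supine$data, b$pet_supine$data)
  expect_identical(a$labels_supine$data, b$labels_supine$data)
  expect_identical(a$nipple_supine, b$nipple_supine)
  # a different seed changes the tissue texture
  c <- make_supine_phantom(small_spec(volumetric_density_target = 0.15,
                                      seed = 12))
  expect_false(identical(a$labels_supine$data, c$labels_supine$data))
})

test_that("phantom generation leaves the global RNG stream untouched", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(make_supine_phantom(small_spec()))
  expect_identical(runif(1), r1)
})

test_that("density and lesion-ratio targets are hit across random specs", {
  set.seed(77)
  targets <- runif(8, 0.10, 0.45)
  ratios <- runif(8, 0.25, 0.75)
  for (i in seq_along(targets)) {
    # default resolution: at coarser voxels the lesion-centroid quantisation
    # alone approaches the +-0.05 ratio tolerance
    ph <- make_supine_phantom(phantom_spec(volumetric_density_target = targets[i],
                                           lesion_location_ratio_target = ratios[i],
                                           seed = 100 + i))
    expect_lt(abs(ph$achieved_density - targets[i]), 0.02)
    # brute-force ratio check from the voxel surface: distance of lesion
    # centroid to the chest plane over the farthest surface voxel distance
    lab <- ph$labels_supine
    breast <- lab$data != 0L & lab$data != LABELS[["chest_wall"]]
    idx <- which(breast, arr.ind = TRUE)
    pts <- voxel_to_world(lab, idx - 1)
    r <- abs(ph$lesion_centroid_supine[3]) / max(pts[, 3])
    expect_lt(abs(r - ratios[i]), 0.05)
  }
})

test_that("anatomical invariants of the phantom hold", {
  ph <- small_phantom()
  R <- ph$truth$breast_radius
  # nipple on the breast surface
  expect_equal(sqrt(sum(ph$nipple_supine^2)), R, tolerance = 1e-9)
  # chest-wall landmarks on the chest plane, non-collinear
  expect_true(all(abs(ph$chest_wall_landmarks[, 3]) < 1e-9))
  sv <- svd(scale(ph$chest_wall_landmarks, scale = FALSE))$d
  expect_gt(sv[2], 1e-6)
  # tissue intensities separated in the CT-like volume
  lab <- ph$labels_supine$data
  m_ad <- mean(ph$ct_supine$data[lab == LABELS[["adipose"]]])
  m_gl <- mean(ph$ct_supine$data[lab == LABELS[["gland"]]])
  expect_gt(m_gl - m_ad, 50)
  # PET-like volume has its hot spot at the lesion
  hotidx <- which(ph$pet_supine$data == max(ph$pet_supine$data), arr.ind = TRUE)
  hot <- voxel_to_world(ph$pet_supine, hotidx - 1)
  expect_lt(sqrt(sum((hot - ph$lesion_centroid_supine)^2)),
            ph$truth$lesion_radius + 2 * ph$truth$voxel_spacing)
})

test_that("an oversized lesion for the requested location is rejected", {
  expect_error(small_spec(lesion_radius = 20,
                          lesion_location_ratio_target = 0.9),
               "does not fit")
})

test_that("zero gravity leaves the prone phantom identical to supine", {
  ph <- small_phantom()
  cfg <- fem_config(gravity_supine = c(0, 0, 0), gravity_prone = c(0, 0, 0))
  pr <- make_prone_ground_truth(ph, config = cfg, element_size = 6,
                                reposition = FALSE)
  expect_lt(max(abs(pr$solution$u)), 1e-9)
  d <- dim(ph$ct_supine$data)
  expect_equal(pr$mr_prone$data[, , seq_len(d[3])], ph$ct_supine$data,
               tolerance = 1e-6)
  expect_equal(pr$nipple_prone, ph$nipple_supine, tolerance = 1e-9)
})

test_that("softer ground-truth tissue increases the prone nipple displacement", {
  ph <- small_phantom()
  mesh <- add_skin_layer(voxel_to_hex_mesh(ph$labels_supine, 6,
                                           nipple = ph$nipple_supine), 1)
  d_soft <- nipple_displacement(simulate_supine_to_prone(
    mesh, material_params(E_adipose = 2), fem_config()))
  d_stiff <- nipple_displacement(simulate_supine_to_prone(
    mesh, material_params(E_adipose = 4), fem_config()))
  expect_gt(d_soft, d_stiff)
})

test_that("prone ground truth matches brute-force advection of the lesion", {
  ph <- fixture("small_prone", make_prone_ground_truth(
    small_phantom(), element_size = 6, reposition = FALSE))
  # brute force: advect every lesion voxel centre through the dense field
  lab <- ph$labels_supine
  idx <- which(lab$data == LABELS[["lesion"]], arr.ind = TRUE)
  pts <- voxel_to_world(lab, idx - 1)
  adv <- pts + breastfem:::sample_field(ph$field, pts)
  expect_lt(sqrt(sum((colMeans(adv) - ph$lesion_centroid_prone)^2)),
            ph$truth$voxel_spacing / 2)
  # and against the warped lesion mask centroid (independent image route)
  cm <- lesion_centroid(ph$labels_prone)
  expect_lt(sqrt(sum((cm - ph$lesion_centroid_prone)^2)),
            ph$truth$voxel_spacing)
  # lesion mass conservation at nu = 0.49: voxel count changes < 5%
  n0 <- sum(lab$data == LABELS[["lesion"]])
  n1 <- sum(ph$labels_prone$data == LABELS[["lesion"]])
  expect_lt(abs(n1 - n0) / n0, 0.05)
})

test_that("phantom files round-trip through NIfTI and JSON", {
  ph <- small_phantom()
  dir <- tempfile("phantom_io_")
  write_phantom(ph, dir)
  ct <- read_volume(file.path(dir, "ct_supine.nii.gz"))
  expect_equal(ct$data, ph$ct_supine$data, tolerance = 1e-6)
  expect_equal(ct$spacing, ph$ct_supine$spacing)
  lm <- read_volume(file.path(dir, "labels.nii.gz"), labels = TRUE)
  expect_identical(lm$data, ph$labels_supine$data)
  meta <- jsonlite::read_json(file.path(dir, "landmarks.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$nipple_supine, ph$nipple_supine)
  expect_equal(meta$achieved_density, ph$achieved_density)
})
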