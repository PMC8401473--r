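make_affine_volume <- function(n = 12, sp = 2) {
  ax <- (seq_len(n) - 1) * sp
  f <- function(x, y, z) 3 + 0.5 * x - 0.25 * y + 0.125 * z
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) arr[, , k] <- outer(ax, ax, function(x, y) f(x, y, ax[k]))
  volume(arr, rep(sp, 3), c(0, 0, 0))
}

test_that("resampling at the native spacing is the identity", {
  v <- volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)), c(1, 1, 1))
  expect_identical(resample_isotropic(v, 1)$data, v$data)
})

test_that("trilinear resampling reproduces affine intensity fields exactly", {
  v <- make_affine_volume(n = 12, sp = 2)
  r <- resample_isotropic(v, 1)
  ax <- (seq_len(dim(r$data)[1]) - 1) * 1
  expected <- array(0, dim(r$data))
  for (k in seq_along(ax))
    expected[, , k] <- outer(ax, ax, function(x, y) 3 + 0.5 * x - 0.25 * y + 0.125 * ax[k])
  # boundary planes beyond the last source voxel centre clamp, so compare
  # the interior where trilinear interpolation is exact
  inner <- which(ax <= max((seq_len(12) - 1) * 2))
  expect_equal(r$data[inner, inner, inner],
               expected[inner, inner, inner], tolerance = 1e-12)
})

test_that("resampling preserves extent and scales the voxel counts", {
  v <- volume(array(rnorm(50 * 20 * 10), c(50, 20, 10)), c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  expect_equal(dim(r$data), c(100, 40, 20))
  expect_lt(abs(dim(r$data)[1] * 1 - 50 * 2), 1 + 1e-9)
  expect_error(resample_isotropic(volume(array(c(NA, rnorm(7)), c(2, 2, 2))), 1),
               "non-finite")
})

test_that("round-trip resampling of a smooth field stays within O(h^2)", {
  n <- 21; sp <- 2
  ax <- (seq_len(n) - 1) * sp
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n))
    arr[, , k] <- outer(ax, ax, function(x, y) sin(x / 10) * cos(y / 12) + ax[k] / 40)
  v <- volume(arr, rep(sp, 3), c(0, 0, 0))
  back <- resample_isotropic(resample_isotropic(v, 1), 2)
  inner <- 3:(n - 3)
  err <- max(abs(back$data[inner, inner, inner] - v$data[inner, inner, inner]))
  # curvature bound: |f''| h^2 / 8 per pass, h = 2 mm
  expect_lt(err, 2 * max(1 / 100, 1 / 144) * sp^2 / 8 + 1e-6)
})

test_that("cropping clamps to bounds and respects margins", {
  lab <- array(0L, c(20, 20, 20))
  lab[8, 9, 10] <- 1L
  lm <- label_map(lab, c(1, 1, 1))
  v <- volume(array(rnorm(8000), c(20, 20, 20)), c(1, 1, 1))
  cr <- crop_breast(v, lm, margin = 5)
  expect_equal(dim(cr$volume$data), c(11, 11, 11))
  expect_equal(cr$labels$data[6, 6, 6], 1L)
  # world coordinates preserved
  expect_equal(cr$volume$origin, c(2, 3, 4))
  # whole-volume mask, zero margin -> identity
  lab2 <- array(1L, c(4, 4, 4))
  lm2 <- label_map(lab2, c(1, 1, 1))
  v2 <- volume(array(rnorm(64), c(4, 4, 4)), c(1, 1, 1))
  cr2 <- crop_breast(v2, lm2, margin = 0)
  expect_identical(cr2$volume$data, v2$data)
  # margin beyond bounds is clamped, no padding
  cr3 <- crop_breast(v2, lm2, margin = 50)
  expect_identical(dim(cr3$volume$data), dim(v2$data))
  expect_error(crop_breast(v2, label_map(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("fuzzy c-means separates two point masses onto their class means", {
  arr <- array(c(rep(100, 40), rep(200, 60)), c(10, 10, 1))
  v <- volume(arr, c(1, 1, 1))
  mask <- array(TRUE, dim(arr))
  fr <- fcm_segment(v, mask)
  expect_equal(fr$centroids, c(100, 200), tolerance = 1e-6)
  hard_ok <- apply(fr$memberships, 1, max) >= 0.99
  expect_true(all(hard_ok))
  expect_true(all(abs(rowSums(fr$memberships) - 1) < 1e-12))
})

test_that("fcm memberships always sum to one and the objective never increases", {
  set.seed(3)
  arr <- array(c(rnorm(300, 90, 12), rnorm(200, 170, 15)), c(50, 10, 1))
  v <- volume(arr, c(1, 1, 1))
  fr <- fcm_segment(v, array(TRUE, dim(arr)))
  expect_true(all(abs(rowSums(fr$memberships) - 1) < 1e-9))
  expect_true(all(diff(fr$objective) <= 1e-8 * abs(fr$objective[-1]) + 1e-12))
  expect_true(fr$converged)
  expect_true(all(diff(fr$centroids) > 0))
})

test_that("fcm agrees with the reference cmeans implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- c(rnorm(400, 100, 10), rnorm(300, 205, 12))
  v <- volume(array(x, c(70, 10, 1)), c(1, 1, 1))
  fr <- fcm_segment(v, array(TRUE, c(70, 10, 1)))
  ref <- e1071::cmeans(matrix(x), centers = matrix(fr$centroids), m = 2)
  expect_equal(sort(as.numeric(ref$centers)), fr$centroids, tolerance = 1e-4)
})

test_that("fcm recovers the phantom tissue labels almost everywhere", {
  ph <- small_phantom()
  fr <- fcm_segment(ph$ct_supine, ph$labels_supine)
  truth <- ph$labels_supine$data
  inside <- truth == LABELS[["adipose"]] | truth == LABELS[["gland"]]
  agree <- mean(fr$labels$data[inside] == truth[inside])
  expect_gte(agree, 0.99)
})

test_that("breast volume and density count voxels correctly", {
  lab <- array(1L, c(10, 10, 10))   # 1000 breast voxels at 1 mm^3
  lab[seq_len(270)] <- 2L           # 270 of them fibro-glandular
  lm <- label_map(lab, c(1, 1, 1))
  bd <- breast_volume_and_density(lm)
  expect_equal(bd$volume_ml, 1.0)
  expect_equal(bd$density, 0.27)
  # all-gland breast
  lm2 <- label_map(array(2L, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(breast_volume_and_density(lm2)$density, 1.0)
  expect_error(breast_volume_and_density(label_map(array(0L, c(2, 2, 2)), 1)),
               "no breast")
})

test_that("phantom density presets are achieved within the stated tolerance", {
  for (target in c(0.15, 0.27)) {
    ph <- make_supine_phantom(small_spec(volumetric_density_target = target))
    bd <- breast_volume_and_density(ph$labels_supine)
    expect_lt(abs(bd$density - target), 0.02)
    expect_true(bd$density >= 0 && bd$density <= 1)
    expect_gt(bd$volume_ml, 0)
  }
})
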