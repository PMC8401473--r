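test_that("landmark transforms recover constructed maps exactly", {
  src <- rbind(c(0, 0, 0), c(40, 5, 0), c(10, 35, 2), c(5, 8, 30))
  # identity
  A <- affine_from_landmarks(src, src, "similarity")
  expect_equal(unclass(A), diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(attr(A, "rms"), 1e-10)
  # rotation + translation
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  dst <- t(R %*% t(src)) + matrix(c(12, -3, 7), 4, 3, byrow = TRUE)
  Ar <- affine_from_landmarks(src, dst, "rigid")
  expect_equal(Ar[1:3, 1:3], R, tolerance = 1e-9)
  expect_equal(Ar[1:3, 4], c(12, -3, 7), tolerance = 1e-9)
  expect_lt(attr(Ar, "rms"), 1e-9)
  # uniform scale through the similarity kind
  As <- affine_from_landmarks(src, src * 1.1, "similarity")
  expect_equal(det(As[1:3, 1:3])^(1 / 3), 1.1, tolerance = 1e-10)
  # translation-only with 3 points is absorbed exactly
  tr <- affine_from_landmarks(src[1:3, ], src[1:3, ] +
                                matrix(c(10, 0, 0), 3, 3, byrow = TRUE), "rigid")
  expect_equal(tr[1:3, 4], c(10, 0, 0), tolerance = 1e-9)
  expect_equal(tr[1:3, 1:3], diag(3), tolerance = 1e-9)
})

test_that("degenerate landmark configurations are rejected", {
  line <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(affine_from_landmarks(line, line, "rigid"), "collinear")
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(affine_from_landmarks(tri, tri, "affine"), "non-coplanar")
  # a reflected correspondence is refused
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  dst <- src %*% diag(c(-1, 1, 1))
  expect_error(affine_from_landmarks(src, dst, "affine"), "reflection")
})

test_that("rigid pre-registration measures the gravity displacement alone", {
  cw <- rbind(c(30, 0, 0), c(-20, 25, 0), c(-20, -25, 0))
  nip_s <- c(0, 0, 60)
  # same frame, nipple moved by gravity only: Vmax is the plain distance
  pre0 <- rigid_preregister(nip_s, nip_s + c(0, 0, 25), cw, cw)
  expect_equal(pre0$Vmax, 25, tolerance = 1e-9)
  expect_equal(unclass(pre0$transform), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # whole-body translation is absorbed by the chest landmarks
  shift <- c(10, 0, 0)
  pre1 <- rigid_preregister(nip_s, nip_s + shift,
                            cw, sweep(cw, 2, shift, `+`))
  expect_equal(pre1$Vmax, 0, tolerance = 1e-9)
})

test_that("dense fields reproduce constant and linear node fields", {
  ph <- small_phantom()
  mesh <- voxel_to_hex_mesh(ph$labels_supine, 6, nipple = ph$nipple_supine)
  sol <- structure(list(u = matrix(rep(c(3, -2, 5), each = nrow(mesh$nodes)),
                                   ncol = 3), mesh = mesh),
                   class = "breastfem_displacement")
  fld <- field_to_grid(sol, ph$labels_supine)
  supp <- fld$support
  for (c in 1:3)
    expect_equal(max(abs(fld$d[, , , c][supp] - c(3, -2, 5)[c])), 0,
                 tolerance = 1e-12)
  # affine node field: u = B x + t reproduced exactly inside the support
  B <- rbind(c(0.01, 0.002, 0), c(0, -0.01, 0.003), c(0.001, 0, 0.02))
  tt <- c(1, 2, -1)
  sol2 <- sol
  sol2$u <- mesh$nodes %*% t(B) + matrix(tt, nrow(mesh$nodes), 3, byrow = TRUE)
  fld2 <- field_to_grid(sol2, ph$labels_supine)
  d <- dim(ph$labels_supine$data)
  ax <- lapply(1:3, function(k)
    ph$labels_supine$origin[k] + (seq_len(d[k]) - 1) * ph$labels_supine$spacing[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  want <- pts %*% t(B) + matrix(tt, nrow(pts), 3, byrow = TRUE)
  for (c in 1:3) {
    got <- as.numeric(fld2$d[, , , c])
    expect_lt(max(abs(got[supp] - want[supp, c])), 1e-9)
  }
})

test_that("warping through a zero field is the identity", {
  ph <- small_phantom()
  mesh <- voxel_to_hex_mesh(ph$labels_supine, 6)
  sol <- structure(list(u = matrix(0, nrow(mesh$nodes), 3), mesh = mesh),
                   class = "breastfem_displacement")
  fld <- field_to_grid(sol, ph$labels_supine)
  w <- warp_volume(ph$ct_supine, fld)
  expect_equal(w$data, ph$ct_supine$data, tolerance = 1e-9)
})

test_that("a pure translation field shifts the image by whole voxels", {
  n <- 24
  arr <- array(rnorm(n^3), c(n, n, n))
  v <- volume(arr, c(1, 1, 1))
  fld <- structure(list(d = array(rep(c(5, 0, 0), each = n^3), c(n, n, n, 3)),
                        spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        support = array(TRUE, c(n, n, n))),
                   class = "breastfem_field")
  w <- warp_volume(v, fld)
  # interior voxels: w(x) = v(x - 5) along the first axis
  expect_equal(w$data[8:20, 5:20, 5:20], arr[3:15, 5:20, 5:20],
               tolerance = 1e-6)
})

test_that("field inversion composes to a small residual", {
  n <- 20
  ax <- seq(0, n - 1)
  d <- array(0, c(n, n, n, 3))
  for (k in seq_len(n))
    d[, , k, 1] <- outer(ax, ax, function(x, y) 2 * sin(x / 8) * cos(y / 9))
  d[, , , 3] <- 1.5
  fld <- structure(list(d = d, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        support = array(TRUE, c(n, n, n))),
                   class = "breastfem_field")
  pts <- as.matrix(expand.grid(seq(4, 15), seq(4, 15), seq(4, 15)))
  x <- breastfem:::invert_field_at(fld, pts)
  res <- x + breastfem:::sample_field(fld, x) - pts
  expect_lt(mean(sqrt(rowSums(res^2))), 0.2)
})

test_that("warping the supine breast through the true field overlaps the prone mask", {
  ph <- fixture("small_prone", make_prone_ground_truth(
    small_phantom(), element_size = 6, reposition = FALSE))
  lab <- ph$labels_supine
  breast <- volume((lab$data == LABELS[["adipose"]] |
                      lab$data == LABELS[["gland"]] |
                      lab$data == LABELS[["lesion"]]) * 1.0,
                   lab$spacing, lab$origin)
  w <- warp_volume(breast, ph$field, target = ph$labels_prone,
                   direction = "forward")
  a <- w$data >= 0.5
  b <- ph$labels_prone$data == LABELS[["adipose"]] |
       ph$labels_prone$data == LABELS[["gland"]] |
       ph$labels_prone$data == LABELS[["lesion"]]
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.95)
})

test_that("fusion renders moving green, fixed purple, identical inputs grey", {
  a <- volume(array(runif(8^3), c(8, 8, 8)), c(1, 1, 1))
  z <- volume(array(0, c(8, 8, 8)), c(1, 1, 1))
  fu <- fuse_overlay(a, a)
  expect_equal(fu[, , , 1], fu[, , , 2], tolerance = 1e-12)  # grey
  fu2 <- fuse_overlay(a, z)
  expect_identical(max(fu2[, , , 2]), 0)                      # pure purple
  expect_gt(max(fu2[, , , 1]), 0)
  expect_error(fuse_overlay(a, volume(array(0, c(4, 4, 4)), c(1, 1, 1))),
               "different grids")
})
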