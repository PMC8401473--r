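test_that("target registration error is the 3D Euclidean distance", {
  expect_identical(tre(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(tre(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_error(tre(c(0, 0, NA), c(0, 0, 0)), "non-finite")
  # isometry invariance under a common rigid motion
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  a <- c(3, -1, 7); b <- c(-2, 4, 1); tr <- c(5, 5, 5)
  expect_equal(tre(drop(R %*% a) + tr, drop(R %*% b) + tr), tre(a, b),
               tolerance = 1e-12)
})

test_that("lesion centroids are exact for points and symmetric bodies", {
  lab <- array(0L, c(21, 21, 21))
  lab[11, 11, 11] <- 3L
  lm <- label_map(lab, c(1, 1, 1), origin = c(0, 10, 20))
  expect_equal(lesion_centroid(lm), c(10, 20, 30))
  # filled sphere: centroid at its centre within a tenth of a voxel
  ax <- seq(0, 20)
  for (k in seq_along(ax))
    lab[, , k] <- ifelse(outer(ax, ax, function(x, y)
      (x - 10)^2 + (y - 10)^2 + (ax[k] - 10)^2) <= 36, 3L, 0L)
  lms <- label_map(lab, c(1, 1, 1))
  expect_lt(max(abs(lesion_centroid(lms) - c(10, 10, 10))), 0.1)
  expect_error(lesion_centroid(label_map(array(0L, c(3, 3, 3)), 1)), "empty")
  # hot-spot volume: intensity-weighted centroid above half maximum
  hot <- array(0, c(15, 15, 15))
  hot[8, 8, 8] <- 10; hot[9, 8, 8] <- 10
  vv <- volume(hot, c(2, 2, 2))
  expect_equal(lesion_centroid(vv), c(15, 14, 14))
})

test_that("lesion location ratio spans chest wall to surface", {
  surf <- as.matrix(expand.grid(x = seq(-30, 30, 10), y = seq(-30, 30, 10),
                                z = 0))
  surf[, 3] <- pmax(0, sqrt(pmax(0, 900 - surf[, 1]^2 - surf[, 2]^2)))
  expect_equal(lesion_location_ratio(c(0, 0, 0), 3, 0, surf), 0)
  expect_equal(lesion_location_ratio(c(0, 0, 30), 3, 0, surf), 1)
  expect_equal(lesion_location_ratio(c(0, 0, 15), 3, 0, surf), 0.5)
  expect_error(lesion_location_ratio(c(0, 0, 1), 3, 0,
                                     cbind(c(1, 2), c(1, 2), c(0, 0))),
               "degenerate")
})

test_that("hemisphere phantom midpoint lesion measures a ratio near one half", {
  ph <- make_supine_phantom(phantom_spec(lesion_location_ratio_target = 0.5,
                                         seed = 11))
  # surface vertices from the voxel representation (the stair-stepped mesh
  # overestimates the apex height by up to an element)
  lab <- ph$labels_supine
  breast <- lab$data != 0L & lab$data != LABELS[["chest_wall"]]
  pts <- voxel_to_world(lab, which(breast, arr.ind = TRUE) - 1)
  r <- lesion_location_ratio(ph$lesion_centroid_supine, 3, 0, pts)
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("group comparison flags constructed differences and not identical groups", {
  g <- rep(c("LD", "HD"), each = 5)
  same <- rep(c(4, 5, 6, 5, 5), 2)
  r0 <- group_compare(same, g)
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-9)
  expect_false(r0$significant)
  # textbook Welch t on a clear separation
  x <- c(1, 1, 1, 100, 100, 100.0001)
  gg <- rep(c("a", "b"), each = 3)
  r1 <- group_compare(x, gg)
  sp <- split(x, gg)
  tstat <- (mean(sp$a) - mean(sp$b)) /
    sqrt(var(sp$a) / 3 + var(sp$b) / 3)
  expect_equal(r1$t, tstat, tolerance = 1e-9)
  expect_true(r1$significant)
  expect_error(group_compare(x, rep("a", 6)), "two levels")
})

test_that("density grouping mirrors the low/high direction of the cohort effect", {
  set.seed(21)
  dens <- runif(20, 0.05, 0.45)
  tre_sim <- 3 + 20 * dens + rnorm(20, sd = 0.5)
  grp <- assign_groups(dens, volume_ml = runif(20, 500, 1200))
  r <- group_compare(tre_sim, grp$density_group)
  expect_lt(r$mean1, r$mean2)   # LD mean below HD mean
  expect_true(r$significant)
})

test_that("feature correlations behave at the identity, null and linear limits", {
  set.seed(5)
  tre_v <- runif(50, 2, 20)
  feats <- data.frame(self = tre_v,
                      noise = rnorm(50),
                      linear = 2 * tre_v + rnorm(50, sd = 1e-6),
                      flat = rep(1, 50))
  fc <- feature_correlation(feats, tre_v)
  expect_equal(fc$R[fc$feature == "self"], 1, tolerance = 1e-12)
  expect_lt(abs(fc$R[fc$feature == "noise"]), 0.3)
  expect_gt(fc$p[fc$feature == "noise"], 0.05)
  expect_equal(fc$R[fc$feature == "linear"], 1, tolerance = 1e-6)
  expect_true(is.na(fc$R[fc$feature == "flat"]))
})
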