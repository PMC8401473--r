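test_that("a uniform cube meshes to the exact element and node counts", {
  # 10 mm cube at 2 mm elements: 5^3 = 125 elements, 6^3 = 216 nodes
  mesh <- voxel_to_hex_mesh(block_labels(5, 5, 5, sp = 2), 2)
  expect_equal(nrow(mesh$elements), 125)
  expect_equal(nrow(mesh$nodes), 216)
  expect_equal(mesh_volume(mesh), 1000, tolerance = 1e-9)
  # single-voxel breast at its own size: one element, eight nodes
  m1 <- voxel_to_hex_mesh(cube_labels(10), 10)
  expect_equal(nrow(m1$elements), 1)
  expect_equal(nrow(m1$nodes), 8)
})

test_that("element size below the voxel spacing is rejected", {
  expect_error(voxel_to_hex_mesh(cube_labels(10), 0.5), "voxel spacing")
})

test_that("element tissue tags follow the majority label", {
  ph <- small_phantom()
  mesh <- voxel_to_hex_mesh(ph$labels_supine, 6)
  gl <- mesh$element_tissue == "gland"
  expect_gt(sum(gl), 0)
  # each gland element's centroid must lie inside the (dilated) gland+lesion mask
  cent <- matrix(0, sum(gl), 3)
  els <- mesh$elements[gl, , drop = FALSE]
  for (a in 1:8) cent <- cent + mesh$nodes[els[, a], , drop = FALSE] / 8
  lab <- ph$labels_supine
  vi <- round(world_to_voxel(lab, cent))
  near_gland <- vapply(seq_len(nrow(vi)), function(r) {
    i <- vi[r, 1] + 1; j <- vi[r, 2] + 1; k <- vi[r, 3] + 1
    d <- dim(lab$data)
    win <- lab$data[max(1, i - 1):min(d[1], i + 1),
                    max(1, j - 1):min(d[2], j + 1),
                    max(1, k - 1):min(d[3], k + 1)]
    any(win == LABELS[["gland"]] | win == LABELS[["lesion"]])
  }, TRUE)
  expect_true(all(near_gland))
})

test_that("mesh volume tracks the labelled voxel volume", {
  ph <- small_phantom()
  mesh <- voxel_to_hex_mesh(ph$labels_supine, 3)
  vox <- breast_volume_and_density(ph$labels_supine)$volume_ml * 1000
  expect_lt(abs(mesh_volume(mesh) - vox) / vox, 0.03)
})

test_that("skin extrusion adds prism-volume elements over a flat surface", {
  mesh <- voxel_to_hex_mesh(block_labels(5, 5, 5, sp = 2), 2)
  nfac <- nrow(mesh$surface_facets)
  sk <- add_skin_layer(mesh, 1)
  expect_equal(nrow(sk$elements) - nrow(mesh$elements), nfac)
  expect_identical(unname(table(sk$element_tissue)["skin"]), as.integer(nfac))
  # thickness 0 leaves the mesh untouched
  expect_identical(add_skin_layer(mesh, 0), mesh)
  # every skin element on the flat top face has volume area x thickness
  vols <- fem_element_volumes(sk$nodes, sk$elements)
  top_skin <- which(sk$element_tissue == "skin")
  flat <- vols[top_skin]
  # faces on the flat faces are 2x2 mm -> 4 mm^3 prisms; corner/edge facets
  # are skewed by the averaged normals, so check the median facet
  expect_equal(sort(flat)[ceiling(length(flat) / 2)], 4, tolerance = 0.3)
})

test_that("hemisphere skin volume approximates surface area times thickness", {
  ph <- small_phantom()
  mesh <- voxel_to_hex_mesh(ph$labels_supine, 3)
  sk <- add_skin_layer(mesh, 1)
  vols <- fem_element_volumes(sk$nodes, sk$elements)
  skin_vol <- sum(vols[sk$element_tissue == "skin"])
  R <- ph$truth$breast_radius
  # voxelized hemisphere free surface exceeds the smooth 2 pi R^2; accept 25%
  expect_lt(abs(skin_vol - 2 * pi * R^2) / (2 * pi * R^2), 0.25)
})

test_that("all reference Jacobians stay positive after skin extrusion", {
  sk <- small_mesh()
  expect_gt(min(breastfem:::fem_min_ref_jacobian(sk$nodes, sk$elements)), 0)
})

test_that("surface facets are oriented outward", {
  mesh <- voxel_to_hex_mesh(block_labels(2, 2, 2, sp = 5), 5)
  ctr <- colMeans(mesh$nodes)
  fac <- mesh$surface_facets
  p1 <- mesh$nodes[fac[, 1], , drop = FALSE]
  p2 <- mesh$nodes[fac[, 2], , drop = FALSE]
  p3 <- mesh$nodes[fac[, 3], , drop = FALSE]
  p4 <- mesh$nodes[fac[, 4], , drop = FALSE]
  e1 <- p3 - p1; e2 <- p4 - p2
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  mid <- (p1 + p2 + p3 + p4) / 4
  expect_true(all(rowSums(nrm * sweep(mid, 2, ctr)) > 0))
})

test_that("vtk export writes a readable legacy mesh file", {
  mesh <- small_mesh()
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, f, point_data = list(id = seq_len(nrow(mesh$nodes))))
  ln <- readLines(f)
  expect_identical(ln[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(mesh$nodes)), ln)))
  expect_true(any(grepl(sprintf("^CELLS %d", nrow(mesh$elements)), ln)))
  expect_true(any(grepl("^SCALARS tissue", ln)))
})
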