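# Shared fixtures. Expensive objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a single-hex label map: one breast voxel of the given physical size
cube_labels <- function(size_mm = 10) {
  lab <- array(0L, c(3, 3, 3))
  lab[2, 2, 2] <- 1L
  label_map(lab, spacing = rep(size_mm, 3), origin = c(0, 0, 0))
}

# an all-adipose cuboid of nx x ny x nz voxels at `sp` mm
block_labels <- function(nx, ny, nz, sp = 1) {
  lab <- array(0L, c(nx + 2, ny + 2, nz + 2))
  lab[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- 1L
  label_map(lab, spacing = rep(sp, 3), origin = c(0, 0, 0))
}

# small, fast phantom used across FE tests (radius 30 mm, 3 mm voxels)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(breast_radius = 30, chest_wall_extent = 6, lesion_radius = 4,
         voxel_spacing = 3, seed = 11),
    list(...))
  do.call(phantom_spec, args)
}

small_phantom <- function() fixture("small_phantom", make_supine_phantom(small_spec()))

small_mesh <- function() fixture("small_mesh", {
  ph <- small_phantom()
  add_skin_layer(voxel_to_hex_mesh(ph$labels_supine, 6, nipple = ph$nipple_supine), 1)
})

# default-size phantom (the study conditions) for the acceptance tests
default_phantom <- function() fixture("default_phantom",
                                      make_supine_phantom(phantom_spec(seed = 7)))

default_mesh <- function() fixture("default_mesh", {
  ph <- default_phantom()
  add_skin_layer(voxel_to_hex_mesh(ph$labels_supine, 4, nipple = ph$nipple_supine), 1)
})

# raw assembly access for gradient checks
assemble_raw <- function(mesh, materials, u, tangent = FALSE) {
  mesh <- breastfem:::fem_prepare(mesh)
  str <- mesh$structure
  em <- breastfem:::element_materials(mesh, materials)
  asm <- breastfem:::fem_assemble(mesh$nodes, mesh$elements, u, em$mu, em$K,
                                  tangent, str$nodeptr, str$rank,
                                  if (tangent) str$nnz else 0)
  asm$structure <- str
  asm
}
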