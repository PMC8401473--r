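#' Build a structured hexahedral mesh from a tissue label map
#'
#' Lays a regular grid of 8-node hexahedra (edge length `element_size`) over
#' the breast region (labels adipose / fibro-glandular / lesion) and keeps the
#' cells whose covered voxels are majority breast. Each kept element is tagged
#' with the majority tissue among its breast voxels; ties break toward
#' fibro-glandular, and lesion voxels count as fibro-glandular for tagging
#' (the lesion is not a separate mechanical phase). The face of the grid on
#' the chest-wall side supplies the fixed-node set; the free boundary facets
#' are extracted with outward orientation for the skin extrusion.
#'
#' @param labels a [label_map()]
#' @param element_size hex edge length, mm; must be >= the voxel spacing
#' @param chest_axis axis index (1-3) of the anteroposterior direction
#' @param chest_plane world-mm position of the chest-wall plane along
#'   `chest_axis`; default: the breast-region boundary on the chest side
#' @param nipple optional world-mm nipple landmark; the nearest free-surface
#'   node becomes `nipple_node`
#' @return an object of class `breastfem_mesh` with fields `nodes` (N x 3 mm),
#'   `elements` (M x 8, 1-based), `element_tissue`, `surface_facets` (F x 4,
#'   outward CCW), `chest_wall_nodes`, `nipple_node`, `element_size`
#' @export
voxel_to_hex_mesh <- function(labels, element_size, chest_axis = 3,
                              chest_plane = NULL, nipple = NULL) {
  sp <- labels$spacing
  if (element_size < max(sp) - 1e-9)
    stop("element_size (", element_size, " mm) must not be smaller than the voxel spacing")
  lab <- labels$data
  breast <- lab == LABELS["adipose"] | lab == LABELS["gland"] | lab == LABELS["lesion"]
  if (!any(breast)) stop("label map contains no breast tissue")

  idx <- which(breast, arr.ind = TRUE)
  lo <- labels$origin + (apply(idx, 2, min) - 1) * sp - sp / 2
  hi <- labels$origin + (apply(idx, 2, max) - 1) * sp + sp / 2
  h <- element_size
  ncell <- pmax(1L, as.integer(ceiling((hi - lo) / h - 1e-9)))

  # subsample each cell on an s^3 lattice, label by nearest voxel
  s <- max(3L, as.integer(round(h / min(sp))) + 1L)
  off <- (seq_len(s) - 0.5) / s * h
  cell0 <- as.matrix(expand.grid(i = 0:(ncell[1] - 1), j = 0:(ncell[2] - 1),
                                 k = 0:(ncell[3] - 1)))
  nc <- nrow(cell0)
  sub <- as.matrix(expand.grid(x = off, y = off, z = off))
  counts <- matrix(0L, nc, 5)  # labels 0..4
  d <- dim(lab)
  for (m in seq_len(nrow(sub))) {
    pts <- sweep(sweep(cell0, 2, h, `*`), 2, lo + sub[m, ], `+`)
    vi <- round(sweep(sweep(pts, 2, labels$origin, `-`), 2, sp, `/`))
    inb <- vi[, 1] >= 0 & vi[, 1] < d[1] & vi[, 2] >= 0 & vi[, 2] < d[2] &
           vi[, 3] >= 0 & vi[, 3] < d[3]
    lv <- integer(nc)
    lv[inb] <- lab[cbind(vi[inb, 1] + 1, vi[inb, 2] + 1, vi[inb, 3] + 1)]
    for (L in 0:4) counts[, L + 1] <- counts[, L + 1] + as.integer(lv == L)
  }
  nb <- counts[, 2] + counts[, 3] + counts[, 4]   # adipose + gland + lesion
  keep <- nb > nrow(sub) / 2
  if (!any(keep)) stop("no elements survive majority voting; element_size too coarse?")
  # tissue tag: gland wins ties; lesion counts as gland
  gl <- counts[keep, 3] + counts[keep, 4]
  tissue <- ifelse(gl >= counts[keep, 2], "gland", "adipose")

  cells <- cell0[keep, , drop = FALSE]
  occ <- array(FALSE, ncell)
  occ[cells + 1] <- TRUE

  # node numbering on the (ncell+1)^3 lattice, only nodes touched by kept cells
  nn <- ncell + 1L
  nid_of <- function(i, j, k) i + nn[1] * (j + nn[2] * k)  # 0-based lattice id
  corner <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
  elem_lat <- matrix(0L, nrow(cells), 8)
  for (a in 1:8)
    elem_lat[, a] <- nid_of(cells[, 1] + corner[a, 1], cells[, 2] + corner[a, 2],
                            cells[, 3] + corner[a, 3])
  used <- sort(unique(as.integer(elem_lat)))
  remap <- integer(max(used) + 1)
  remap[used + 1] <- seq_along(used)
  elements <- matrix(remap[elem_lat + 1], nrow(cells), 8)
  ui <- used %% nn[1]
  uj <- (used %/% nn[1]) %% nn[2]
  uk <- used %/% (nn[1] * nn[2])
  nodes <- cbind(lo[1] + ui * h, lo[2] + uj * h, lo[3] + uk * h)

  # boundary facets: cell faces with no occupied neighbour
  # local faces in outward-CCW order (1-based local node ids)
  faces <- list(
    xm = c(1, 5, 8, 4), xp = c(2, 3, 7, 6),
    ym = c(1, 2, 6, 5), yp = c(4, 8, 7, 3),
    zm = c(1, 4, 3, 2), zp = c(5, 6, 7, 8))
  dirs <- rbind(xm = c(-1, 0, 0), xp = c(1, 0, 0), ym = c(0, -1, 0),
                yp = c(0, 1, 0), zm = c(0, 0, -1), zp = c(0, 0, 1))
  facets <- NULL
  has_nb <- function(dv) {
    nbc <- sweep(cells, 2, dv, `+`)
    ok <- nbc[, 1] >= 0 & nbc[, 1] < ncell[1] & nbc[, 2] >= 0 &
          nbc[, 2] < ncell[2] & nbc[, 3] >= 0 & nbc[, 3] < ncell[3]
    out <- logical(nrow(cells))
    out[ok] <- occ[nbc[ok, , drop = FALSE] + 1]
    out
  }
  for (f in names(faces)) {
    bnd <- !has_nb(dirs[f, ])
    if (any(bnd)) facets <- rbind(facets, elements[bnd, faces[[f]], drop = FALSE])
  }

  if (is.null(chest_plane)) chest_plane <- lo[chest_axis]
  tol <- h / 4
  cw <- which(abs(nodes[, chest_axis] - chest_plane) < tol)
  # drop facets lying in the chest-wall plane from the free surface
  on_cw <- matrix(abs(nodes[facets, chest_axis] - chest_plane) < tol, nrow(facets), 4)
  facets <- facets[rowSums(on_cw) < 4, , drop = FALSE]

  cell_elem <- array(0L, ncell)
  cell_elem[cells + 1] <- seq_len(nrow(cells))
  mesh <- structure(
    list(nodes = nodes, elements = elements, element_tissue = tissue,
         surface_facets = facets, chest_wall_nodes = cw,
         chest_axis = chest_axis, chest_plane = chest_plane,
         nipple_node = NA_integer_, element_size = h,
         grid = list(lo = lo, h = h, ncell = ncell, cell_elem = cell_elem)),
    class = "breastfem_mesh")
  if (!is.null(nipple)) mesh <- set_nipple_node(mesh, nipple)
  mesh
}

#' Locate the mesh node for the nipple landmark
#' @param mesh a `breastfem_mesh`
#' @param nipple world-mm coordinates of the nipple landmark
#' @return the mesh with `nipple_node` set to the nearest free-surface node
#' @export
set_nipple_node <- function(mesh, nipple) {
  sn <- unique(as.integer(mesh$surface_facets))
  d2 <- rowSums(sweep(mesh$nodes[sn, , drop = FALSE], 2, as.numeric(nipple), `-`)^2)
  mesh$nipple_node <- sn[which.min(d2)]
  mesh
}

#' @export
print.breastfem_mesh <- function(x, ...) {
  cat("<HexMesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements), " elements (",
      paste(sprintf("%s: %d", names(table(x$element_tissue)),
                    as.integer(table(x$element_tissue))), collapse = ", "),
      "), ", nrow(x$surface_facets), " surface facets, ",
      length(x$chest_wall_nodes), " chest-wall nodes\n", sep = "")
  invisible(x)
}

#' Total reference volume of a mesh (mm^3)
#' @param mesh a `breastfem_mesh`
#' @export
mesh_volume <- function(mesh) {
  sum(fem_element_volumes(mesh$nodes, mesh$elements))
}

#' Extrude a skin layer over the free breast surface
#'
#' Adds one layer of thin hexahedral elements over every free-surface facet,
#' extruded outward along averaged facet normals by `thickness`. Skin is
#' modelled as thin solid hexahedra carrying the same neo-Hookean law as the
#' bulk (with the skin material), which keeps a single element technology
#' throughout. New nodes closer than `thickness / 4` are merged to avoid
#' self-intersection at concave ridges.
#'
#' @param mesh a `breastfem_mesh`
#' @param thickness skin thickness in mm (default 1)
#' @return the mesh with skin elements appended (`element_tissue == "skin"`);
#'   `surface_facets` is updated to the outer skin surface
#' @export
add_skin_layer <- function(mesh, thickness = 1.0) {
  if (thickness == 0) return(mesh)
  if (is.null(mesh$surface_facets) || nrow(mesh$surface_facets) == 0)
    stop("mesh has no surface facets")
  fac <- mesh$surface_facets
  nod <- mesh$nodes
  # facet normals (unit), accumulated to nodes
  p1 <- nod[fac[, 1], , drop = FALSE]; p2 <- nod[fac[, 2], , drop = FALSE]
  p3 <- nod[fac[, 3], , drop = FALSE]; p4 <- nod[fac[, 4], , drop = FALSE]
  e1 <- p3 - p1; e2 <- p4 - p2
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  sn <- sort(unique(as.integer(fac)))
  acc <- matrix(0, length(sn), 3)
  pos <- match(as.integer(fac), sn)
  for (c in 1:4) {
    idx <- pos[((c - 1) * nrow(fac) + 1):(c * nrow(fac))]
    for (ax in 1:3) acc[, ax] <- acc[, ax] + tabulate_add(idx, nrm[, ax], length(sn))
  }
  nn <- acc / sqrt(rowSums(acc^2))
  newpos <- nod[sn, , drop = FALSE] + thickness * nn

  # merge new nodes closer than thickness/4 (hash grid)
  cellkey <- apply(round(newpos / (thickness / 4)), 1, paste, collapse = ",")
  grp <- match(cellkey, unique(cellkey))
  if (max(grp) < length(sn)) {
    for (g in unique(grp[duplicated(grp)])) {
      m <- grp == g
      newpos[m, ] <- matrix(colMeans(newpos[m, , drop = FALSE]),
                            sum(m), 3, byrow = TRUE)
    }
    warning("merged ", length(sn) - length(unique(cellkey)),
            " skin nodes at concavities")
  }
  first <- !duplicated(grp)
  newid <- nrow(nod) + match(grp, unique(grp))
  uniq <- newpos[first, , drop = FALSE]

  top <- matrix(newid[match(as.integer(fac), sn)], nrow(fac), 4)
  skin_elems <- cbind(fac, top)
  mesh$nodes <- rbind(nod, uniq)
  mesh$elements <- rbind(mesh$elements, skin_elems)
  mesh$element_tissue <- c(mesh$element_tissue, rep("skin", nrow(skin_elems)))
  mesh$surface_facets <- top
  mesh$skin_thickness <- thickness
  if (!is.na(mesh$nipple_node) && mesh$nipple_node %in% sn)
    mesh$nipple_node <- newid[match(mesh$nipple_node, sn)]
  mesh
}

# sum `val` into bins `idx` (1..n)
tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Interpolate a nodal vector field at a world point: trilinear inside the
# containing structured cell; points just outside the bulk (stair-stepped
# surface, skin shell) are projected into the nearest occupied cell.
displacement_at_point <- function(mesh, u, point) {
  g <- mesh$grid
  p <- as.numeric(point)
  if (is.null(g)) {
    sn <- unique(as.integer(mesh$surface_facets))
    d2 <- rowSums(sweep(mesh$nodes[sn, , drop = FALSE], 2, p, `-`)^2)
    return(u[sn[which.min(d2)], ])
  }
  ci <- pmin(pmax(floor((p - g$lo) / g$h + 1e-9), 0), g$ncell - 1L)
  if (g$cell_elem[matrix(ci + 1L, 1)] == 0L) {
    occ <- which(g$cell_elem > 0L, arr.ind = TRUE) - 1L
    ctr <- sweep((occ + 0.5) * g$h, 2, g$lo, `+`)
    ci <- occ[which.min(rowSums(sweep(ctr, 2, p, `-`)^2)), ]
  }
  e <- g$cell_elem[matrix(ci + 1L, 1)]
  lo_c <- g$lo + ci * g$h
  t <- pmin(pmax((p - lo_c) / g$h, 0), 1)
  corner <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
  out <- c(0, 0, 0)
  en <- mesh$elements[e, ]
  for (a in 1:8) {
    w <- prod(ifelse(corner[a, ] == 1, t, 1 - t))
    out <- out + w * u[en[a], ]
  }
  out
}

#' Mesh-convergence study for the prone-gravity solve
#'
#' Runs the prone-gravity simulation at a ladder of element sizes and reports
#' the relative change in nipple-displacement magnitude and in the 95th
#' percentile of surface displacement between successive refinements. The
#' flagged size is the coarsest whose change from the next finer mesh is at
#' most `criterion` (default 2%).
#'
#' @param labels a [label_map()]
#' @param materials a [material_params()]
#' @param config a [fem_config()]
#' @param sizes element sizes in mm, descending
#' @param nipple world-mm nipple landmark
#' @param criterion relative-change threshold (fraction, default 0.02)
#' @return data frame with one row per size: nipple displacement (mm), 95th
#'   percentile surface displacement (mm), relative changes, convergence flag
#' @export
mesh_convergence_check <- function(labels, materials, config = fem_config(),
                                   sizes, nipple, criterion = 0.02) {
  stopifnot(length(sizes) >= 2)
  if (is.unsorted(rev(sizes))) stop("sizes must be descending")
  rows <- lapply(sizes, function(h) {
    res <- tryCatch({
      mesh <- voxel_to_hex_mesh(labels, h, nipple = nipple)
      mesh <- add_skin_layer(mesh, config$skin_thickness)
      sol <- solve_gravity(mesh, materials,
                           boundary_conditions(mesh, gravity = config$gravity_prone),
                           config)
      # evaluate at the fixed landmark, not the (size-dependent) nearest node
      un <- sqrt(sum(displacement_at_point(mesh, sol$u, nipple)^2))
      sn <- unique(as.integer(mesh$surface_facets))
      us <- sqrt(rowSums(sol$u[sn, , drop = FALSE]^2))
      list(ok = TRUE, nip = un, p95 = stats::quantile(us, 0.95, names = FALSE),
           nel = nrow(mesh$elements))
    }, error = function(e) list(ok = FALSE, nip = NA_real_, p95 = NA_real_,
                                nel = NA_integer_,
                                msg = conditionMessage(e)))
    data.frame(size = h, nipple_disp = res$nip, surf_p95 = res$p95,
               n_elements = res$nel, failed = !res$ok)
  })
  rep <- do.call(rbind, rows)
  rel <- function(x) c(NA, abs(diff(x)) / abs(x[-1]))
  rep$rel_change_nipple <- rel(rep$nipple_disp)
  rep$rel_change_p95 <- rel(rep$surf_p95)
  rep$converged <- !is.na(rep$rel_change_nipple) & rep$rel_change_nipple <= criterion
  attr(rep, "flagged_size") <- {
    ok <- which(rep$converged)
    if (length(ok)) rep$size[min(ok) - 1] else NA_real_
  }
  rep
}

#' Write a mesh (plus optional point data) as legacy-ASCII VTK
#' @param mesh a `breastfem_mesh`
#' @param path output `.vtk` path
#' @param point_data optional named list of per-node vectors/matrices
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "breastfem hexahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  utils::write.table(cbind(8L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$element_tissue,
                                c("adipose", "gland", "skin"))), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      pd <- point_data[[nm]]
      if (is.matrix(pd) && ncol(pd) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(pd, digits = 10), con, row.names = FALSE,
                           col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(pd), digits = 10), con)
      }
    }
  }
  invisible(path)
}
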