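#' Lesion centroid in world coordinates
#'
#' For a label map, the unweighted centroid of the lesion voxels. For a
#' scalar volume (a warped PET hot spot), the intensity-weighted centroid of
#' the voxels above `threshold` times the maximum intensity.
#'
#' @param x a [label_map()] (lesion label 3) or a [volume()]
#' @param threshold hot-spot threshold as a fraction of the maximum (volumes)
#' @return length-3 world-mm centroid
#' @export
lesion_centroid <- function(x, threshold = 0.5) {
  if (inherits(x, "breastfem_labelmap")) {
    idx <- which(x$data == LABELS[["lesion"]], arr.ind = TRUE)
    if (!nrow(idx)) stop("empty lesion mask")
    return(unname(colMeans(voxel_to_world(x, idx - 1))))
  }
  mx <- max(x$data)
  if (!is.finite(mx) || mx <= 0) stop("volume has no positive hot spot")
  sel <- which(x$data >= threshold * mx, arr.ind = TRUE)
  w <- x$data[sel]
  pts <- voxel_to_world(x, sel - 1)
  unname(colSums(pts * w) / sum(w))
}

#' Target registration error
#'
#' Euclidean distance in mm between the lesion centroid in the fixed (MR)
#' image and in the registered moving (PET) image, in 3D.
#'
#' @param C_MR,C_PET length-3 world-mm points
#' @return TRE in mm
#' @export
tre <- function(C_MR, C_PET) {
  C_MR <- as.numeric(C_MR); C_PET <- as.numeric(C_PET)
  if (any(!is.finite(C_MR)) || any(!is.finite(C_PET)))
    stop("non-finite centroid coordinates")
  sqrt(sum((C_MR - C_PET)^2))
}

#' Lesion location ratio
#'
#' Distance of the lesion centroid to the chest-wall plane divided by the
#' distance of the farthest breast-surface vertex to that plane: close to 0
#' near the chest wall, close to 1 near the breast surface.
#'
#' @param centroid lesion centroid, world mm
#' @param chest_axis axis index (1-3) of the chest-wall plane normal
#' @param chest_plane plane position along `chest_axis`, mm
#' @param surface_points breast-surface vertices (N x 3 mm)
#' @return ratio in `[0, 1]`
#' @export
lesion_location_ratio <- function(centroid, chest_axis, chest_plane,
                                  surface_points) {
  surface_points <- rbind(surface_points)
  if (!nrow(surface_points)) stop("empty breast surface")
  dmax <- max(abs(surface_points[, chest_axis] - chest_plane))
  if (dmax <= 0) stop("degenerate breast surface: no extent off the chest wall")
  min(abs(as.numeric(centroid)[chest_axis] - chest_plane) / dmax, 1)
}

#' Two-group TRE comparison
#'
#' Welch's unpaired two-sample t-test of TRE between two groups (low versus
#' high density at a 0.25 threshold, small versus large volume at the median,
#' or acquisition site).
#'
#' @param tre_values numeric TRE vector, mm
#' @param group two-level factor/character of the same length
#' @return data.frame of class `breastfem_group_test` with group means, SDs,
#'   n, Welch t, df, p and the 0.05 significance flag
#' @export
group_compare <- function(tre_values, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("grouping must have exactly two levels")
  if (any(table(group) < 2)) stop("each group needs at least 2 cases")
  sp <- split(tre_values, group)
  tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = FALSE)
  out <- data.frame(
    group1 = levels(group)[1], group2 = levels(group)[2],
    mean1 = mean(sp[[1]]), mean2 = mean(sp[[2]]),
    sd1 = stats::sd(sp[[1]]), sd2 = stats::sd(sp[[2]]),
    n1 = length(sp[[1]]), n2 = length(sp[[2]]),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, significant = tt$p.value < 0.05)
  class(out) <- c("breastfem_group_test", "data.frame")
  out
}

#' Split cases into density / volume groups
#'
#' Low-density versus high-density at a volumetric-density threshold
#' (default 0.25), and small-volume versus large-volume at the median volume.
#'
#' @param density volumetric densities in `[0, 1]`
#' @param volume_ml breast volumes, mL
#' @param density_threshold LD/HD split point
#' @return data.frame with factors `density_group` (LD/HD) and
#'   `volume_group` (SV/LV)
#' @export
assign_groups <- function(density, volume_ml, density_threshold = 0.25) {
  data.frame(
    density_group = factor(ifelse(density < density_threshold, "LD", "HD"),
                           levels = c("LD", "HD")),
    volume_group = factor(ifelse(volume_ml <= stats::median(volume_ml),
                                 "SV", "LV"), levels = c("SV", "LV")))
}

#' Correlation of image features with TRE
#'
#' Pearson correlation (with test) of each feature column against the TRE.
#' Zero-variance features are reported with `NA` correlation.
#'
#' @param features data.frame of numeric feature columns (e.g. weight,
#'   lesion size, nipple displacement, lesion location ratio, density,
#'   breast volume)
#' @param tre_values numeric TRE vector, one per row of `features`
#' @return data.frame: feature, n, R, p, significant (p < 0.05)
#' @export
feature_correlation <- function(features, tre_values) {
  stopifnot(nrow(features) == length(tre_values), nrow(features) >= 3)
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0 || stats::sd(tre_values) == 0)
      return(data.frame(feature = f, n = length(x), R = NA_real_,
                        p = NA_real_, significant = NA))
    ct <- stats::cor.test(x, tre_values, method = "pearson")
    data.frame(feature = f, n = length(x), R = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < 0.05)
  })
  do.call(rbind, rows)
}

#' Register one phantom case and measure its TRE
#'
#' Runs the full per-case pipeline on a phantom with prone ground truth:
#' rigid pre-registration of the chest-wall landmarks (measuring Vmax),
#' material grid search (unless `materials` is given), supine-to-prone FE
#' simulation, dense-field warping of the PET-like volume into the MR frame,
#' similarity refinement from the chest-wall landmarks, and the 3D TRE of
#' the lesion centroid. A landmark-similarity-only registration (similarity
#' transform fitted to chest-wall landmarks plus nipples, no biomechanics)
#' provides the comparison baseline.
#'
#' @param case a `breastfem_phantom` with prone fields set
#' @param element_size FE element size, mm
#' @param config a [fem_config()]
#' @param materials fixed [material_params()]; `NULL` runs the grid search
#' @param grid a [grid_config()] for the search
#' @param tol grid-search stopping tolerance, mm
#' @return list of class `breastfem_tre_report`: `tre`, `tre_similarity`,
#'   `C_MR`, `C_PET`, `Vmax`, `Vn`, `E_adipose`, `optimization` (state or
#'   NULL), `features` (lesion size, nipple displacement, location ratio,
#'   density, volume)
#' @export
evaluate_case <- function(case, element_size = 4, config = fem_config(),
                          materials = NULL, grid = grid_config(), tol = 1.0) {
  if (is.null(case$mr_prone)) stop("phantom case has no prone ground truth")
  mesh <- voxel_to_hex_mesh(case$labels_supine, element_size,
                            nipple = case$nipple_supine)
  mesh <- add_skin_layer(mesh, config$skin_thickness)

  pre <- rigid_preregister(case$nipple_supine, case$nipple_prone,
                           case$chest_wall_landmarks,
                           case$chest_wall_landmarks_prone)
  opt_state <- NULL
  if (is.null(materials)) {
    opt <- grid_search_optimize(mesh, pre$Vmax, tol = tol, config = config,
                                grid = grid)
    materials <- opt$materials
    opt_state <- opt$state
  }
  sol <- simulate_supine_to_prone(mesh, materials, config)
  Vn <- nipple_displacement(sol)

  field <- field_to_grid(sol, case$labels_supine)
  pet_warp <- warp_volume(case$pet_supine, field, target = case$mr_prone,
                          direction = "forward", post = pre$transform)

  # similarity refinement from the chest-wall landmarks: FE leaves the chest
  # wall in place, so the predicted chest landmarks are the rigidly mapped ones
  pred_cw <- apply_affine(pre$transform, case$chest_wall_landmarks)
  refine <- affine_from_landmarks(pred_cw, case$chest_wall_landmarks_prone,
                                  kind = "similarity")
  C_PET <- drop(apply_affine(refine, rbind(lesion_centroid(pet_warp))))
  C_MR <- lesion_centroid(case$labels_prone)
  tre_fe <- tre(C_MR, C_PET)

  # baseline: landmark similarity only (chest landmarks + nipples)
  sim <- affine_from_landmarks(
    rbind(case$chest_wall_landmarks, case$nipple_supine),
    rbind(case$chest_wall_landmarks_prone, case$nipple_prone),
    kind = "similarity")
  C_PET_sim <- drop(apply_affine(sim, rbind(lesion_centroid(case$pet_supine))))
  tre_sim <- tre(C_MR, C_PET_sim)

  bvd <- breast_volume_and_density(case$labels_supine)
  surf <- mesh$nodes[unique(as.integer(mesh$surface_facets)), , drop = FALSE]
  feats <- list(
    lesion_size = 2 * case$truth$lesion_radius,
    nipple_displacement = pre$Vmax,
    lesion_location_ratio = lesion_location_ratio(
      case$lesion_centroid_supine, mesh$chest_axis, mesh$chest_plane, surf),
    density = bvd$density, volume_ml = bvd$volume_ml)

  structure(list(tre = tre_fe, tre_similarity = tre_sim, C_MR = C_MR,
                 C_PET = C_PET, Vmax = pre$Vmax, Vn = Vn,
                 E_adipose = materials$adipose$E, optimization = opt_state,
                 features = feats),
            class = "breastfem_tre_report")
}

#' @export
print.breastfem_tre_report <- function(x, ...) {
  cat("<TREReport> TRE ", signif(x$tre, 4), " mm (similarity-only ",
      signif(x$tre_similarity, 4), " mm); Vmax ", signif(x$Vmax, 4),
      " mm, Vn ", signif(x$Vn, 4), " mm, E_adipose ",
      signif(x$E_adipose, 4), " kPa\n", sep = "")
  invisible(x)
}
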