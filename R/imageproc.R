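#' Resample a volume onto an isotropic grid
#'
#' Trilinear interpolation onto a grid at `target_spacing`, preserving the
#' physical extent (within one voxel) and the origin. The number of voxels
#' per axis becomes `round(n * spacing / target)`.
#'
#' @param v a [volume()]
#' @param target_spacing isotropic voxel size, mm
#' @return a resampled [volume()]
#' @export
resample_isotropic <- function(v, target_spacing = 1) {
  if (target_spacing <= 0) stop("target_spacing must be positive")
  if (any(!is.finite(v$data))) stop("volume contains non-finite voxels")
  d <- dim(v$data)
  if (all(abs(v$spacing - target_spacing) < 1e-12)) return(v)
  nnew <- pmax(1L, as.integer(round(d * v$spacing / target_spacing)))
  ax <- lapply(1:3, function(k) v$origin[k] + (seq_len(nnew[k]) - 1) * target_spacing)
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- sample_volume(v, grid, clamp = TRUE)
  volume(array(vals, nnew), rep(target_spacing, 3), v$origin, v$axes)
}

#' Resample a label map by nearest-neighbour lookup
#' @param labels a [label_map()]
#' @param target_spacing isotropic voxel size, mm
#' @export
resample_labels <- function(labels, target_spacing = 1) {
  d <- dim(labels$data)
  if (all(abs(labels$spacing - target_spacing) < 1e-12)) return(labels)
  nnew <- pmax(1L, as.integer(round(d * labels$spacing / target_spacing)))
  ax <- lapply(1:3, function(k) labels$origin[k] + (seq_len(nnew[k]) - 1) * target_spacing)
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vi <- round(world_to_voxel(labels, grid))
  for (k in 1:3) vi[, k] <- pmin(pmax(vi[, k], 0), d[k] - 1)
  vals <- labels$data[vi + 1]
  label_map(array(as.integer(vals), nnew), rep(target_spacing, 3),
            labels$origin, labels$axes)
}

#' Crop a volume and its label map to the breast region
#'
#' Minimal bounding box of non-background breast labels (adipose,
#' fibro-glandular, lesion) plus `margin` mm, clamped to the image bounds.
#'
#' @param v a [volume()]
#' @param labels an aligned [label_map()]
#' @param margin margin in mm around the breast bounding box
#' @return list with cropped `volume` and `labels`
#' @export
crop_breast <- function(v, labels, margin = 0) {
  stopifnot(all(dim(v$data) == dim(labels$data)))
  lab <- labels$data
  breast <- lab == LABELS["adipose"] | lab == LABELS["gland"] | lab == LABELS["lesion"]
  if (!any(breast)) stop("empty breast mask; nothing to crop")
  idx <- which(breast, arr.ind = TRUE)
  mvox <- ceiling(margin / v$spacing)
  lo <- pmax(apply(idx, 2, min) - mvox, 1)
  hi <- pmin(apply(idx, 2, max) + mvox, dim(v$data))
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  new_origin <- v$origin + (lo - 1) * v$spacing
  list(volume = volume(sub(v$data), v$spacing, new_origin, v$axes),
       labels = label_map(sub(lab), v$spacing, new_origin, labels$axes))
}

#' Fuzzy c-means segmentation of breast tissue
#'
#' Intensity fuzzy c-means restricted to a breast mask. Memberships follow
#' the standard update `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and
#' centroids are `membership^m`-weighted means; a voxel whose intensity
#' coincides exactly with a centroid gets membership 1 for that cluster.
#' Initial centroids sit at evenly spaced quantiles of the masked intensities
#' (25th/75th percentile for c = 2), which makes the preprocessing stage
#' deterministic. The lowest-centroid cluster is labelled adipose (fat is
#' darker on CT) and the highest fibro-glandular.
#'
#' @param v a [volume()]
#' @param mask logical array (or [label_map()] whose breast labels form the
#'   mask) selecting the voxels to cluster
#' @param c number of clusters (>= 2)
#' @param m fuzzifier exponent (> 1)
#' @param tol convergence tolerance on the maximum centroid shift
#' @param max_iter iteration cap; non-convergence sets a warning flag
#' @return list of class `breastfem_fcm`: `memberships` (n x c, masked voxels
#'   in array order), `centroids` (ascending), `iterations`, `final_shift`,
#'   `objective` (per-iteration values), `converged`, and `labels`
#'   (a [label_map()] with hard assignments adipose / fibro-glandular)
#' @export
fcm_segment <- function(v, mask, c = 2, m = 2.0, tol = 1e-5, max_iter = 300) {
  if (inherits(mask, "breastfem_labelmap"))
    mask <- mask$data == LABELS["adipose"] | mask$data == LABELS["gland"] |
            mask$data == LABELS["lesion"]
  stopifnot(c >= 2, m > 1)
  sel <- which(mask)
  if (!length(sel)) stop("empty mask")
  x <- as.numeric(v$data[sel])
  qs <- stats::quantile(x, (seq_len(c) * 2 - 1) / (2 * c), names = FALSE)
  ctr <- as.numeric(qs)
  if (any(duplicated(ctr))) ctr <- ctr + seq_along(ctr) * 1e-9 * (1 + abs(ctr))
  n <- length(x)
  obj <- numeric(0)
  U <- NULL
  shift <- Inf
  iter <- 0L
  memberships_from <- function(ctr) {
    d2 <- outer(x, ctr, function(a, b) (a - b)^2)
    hit <- d2 == 0
    U <- matrix(0, n, c)
    anyhit <- rowSums(hit) > 0
    if (any(anyhit)) U[anyhit, ] <- hit[anyhit, , drop = FALSE] /
      rowSums(hit[anyhit, , drop = FALSE])
    if (any(!anyhit)) {
      w <- d2[!anyhit, , drop = FALSE]^(-1 / (m - 1))
      U[!anyhit, ] <- w / rowSums(w)
    }
    U
  }
  for (iter in seq_len(max_iter)) {
    U <- memberships_from(ctr)
    um <- U^m
    new_ctr <- colSums(um * x) / colSums(um)
    d2 <- outer(x, new_ctr, function(a, b) (a - b)^2)
    obj <- c(obj, sum((U^m) * d2))
    shift <- max(abs(new_ctr - ctr))
    ctr <- new_ctr
    if (shift < tol) break
  }
  converged <- shift < tol
  if (!converged) warning("fuzzy c-means did not converge in ", max_iter,
                          " iterations (final shift ", signif(shift, 3), ")")
  U <- memberships_from(ctr)
  ord <- order(ctr)
  ctr <- ctr[ord]
  U <- U[, ord, drop = FALSE]
  hard <- max.col(U, ties.method = "first")
  lab <- array(0L, dim(v$data))
  # lowest cluster -> adipose; all higher clusters -> fibro-glandular
  lab[sel] <- ifelse(hard == 1, LABELS["adipose"], LABELS["gland"])
  structure(list(memberships = U, centroids = ctr, iterations = iter,
                 final_shift = shift, objective = obj, converged = converged,
                 voxels = sel,
                 labels = label_map(lab, v$spacing, v$origin, v$axes)),
            class = "breastfem_fcm")
}

#' @export
print.breastfem_fcm <- function(x, ...) {
  cat("<FcmResult> centroids: ", paste(signif(x$centroids, 5), collapse = ", "),
      "; ", x$iterations, " iterations, final shift ",
      signif(x$final_shift, 3), if (!x$converged) " (not converged)", "\n",
      sep = "")
  invisible(x)
}

#' Breast volume and volumetric density
#'
#' Volume is the voxel count of adipose + fibro-glandular + lesion times the
#' voxel volume, reported in mL; volumetric density is the fibro-glandular
#' voxel count divided by the breast voxel count.
#'
#' @param labels a [label_map()]
#' @return list with `volume_ml` and `density`
#' @export
breast_volume_and_density <- function(labels) {
  lab <- labels$data
  nb <- sum(lab == LABELS["adipose"] | lab == LABELS["gland"] |
            lab == LABELS["lesion"])
  if (nb == 0) stop("label map contains no breast voxels")
  ng <- sum(lab == LABELS["gland"])
  vox_mm3 <- prod(labels$spacing)
  list(volume_ml = nb * vox_mm3 / 1000, density = ng / nb)
}
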