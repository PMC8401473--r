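#' Dense displacement field on a voxel grid
#'
#' Interpolates converged nodal displacements onto every voxel of a target
#' grid: trilinear interpolation inside the structured bulk of the mesh,
#' nearest-inside extrapolation within `extrapolate_mm` outside the mesh
#' support (which covers the thin skin shell), zero elsewhere.
#'
#' @param sol a `breastfem_displacement` (its mesh must come from
#'   [voxel_to_hex_mesh()])
#' @param target a [volume()] or [label_map()] defining the output grid
#' @param extrapolate_mm reach of the nearest-inside extrapolation, mm
#' @return object of class `breastfem_field`: 4D array `d` (dims x 3, mm),
#'   `spacing`, `origin`, and `support` (logical array of in-mesh voxels)
#' @export
field_to_grid <- function(sol, target, extrapolate_mm = 2) {
  mesh <- sol$mesh
  if (is.null(mesh$grid)) stop("mesh carries no structured-grid info")
  if (is.null(sol$u) || !nrow(sol$u)) stop("empty displacement field")
  g <- mesh$grid
  d <- dim(target$data)
  ax <- lapply(1:3, function(k) target$origin[k] + (seq_len(d[k]) - 1) * target$spacing[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  rel <- sweep(pts, 2, g$lo, `-`) / g$h
  ci <- floor(rel - 1e-9)
  ci[ci < 0] <- -1L
  inside <- ci[, 1] >= 0 & ci[, 1] < g$ncell[1] & ci[, 2] >= 0 &
            ci[, 2] < g$ncell[2] & ci[, 3] >= 0 & ci[, 3] < g$ncell[3]
  eid <- integer(nrow(pts))
  eid[inside] <- g$cell_elem[ci[inside, , drop = FALSE] + 1]
  hit <- eid > 0
  u <- matrix(0, nrow(pts), 3)
  if (any(hit)) {
    t <- rel[hit, , drop = FALSE] - ci[hit, , drop = FALSE]
    corner <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
                    c(0, 0, 0, 0, 1, 1, 1, 1))
    el <- mesh$elements[eid[hit], , drop = FALSE]
    for (a in 1:8) {
      w <- (if (corner[a, 1]) t[, 1] else 1 - t[, 1]) *
           (if (corner[a, 2]) t[, 2] else 1 - t[, 2]) *
           (if (corner[a, 3]) t[, 3] else 1 - t[, 3])
      u[hit, ] <- u[hit, ] + w * sol$u[el[, a], , drop = FALSE]
    }
  }
  darr <- array(u, c(d, 3))
  supp <- array(hit, d)
  # nearest-inside extrapolation by iterative 6-neighbour fill
  passes <- ceiling(extrapolate_mm / min(target$spacing))
  filled <- supp
  for (p in seq_len(passes)) {
    den <- array(0, d)
    acc <- list(array(0, d), array(0, d), array(0, d))
    for (k in 1:3) for (s in c(-1, 1)) {
      sh_f <- shift_array(filled, k, s)
      den <- den + sh_f
      for (c in 1:3)
        acc[[c]] <- acc[[c]] + shift_array(darr[, , , c], k, s) * sh_f
    }
    newly <- !filled & den > 0
    if (!any(newly)) break
    for (c in 1:3) {
      comp <- darr[, , , c]
      comp[newly] <- acc[[c]][newly] / den[newly]
      darr[, , , c] <- comp
    }
    filled <- filled | newly
  }
  structure(list(d = darr, spacing = target$spacing, origin = target$origin,
                 support = supp),
            class = "breastfem_field")
}

# shift a 3D array by one voxel along axis k (direction s), edge-padded with 0
shift_array <- function(a, k, s) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (s > 0) { idx_dst[[k]] <- 2:d[k]; idx_src[[k]] <- 1:(d[k] - 1) }
  else { idx_dst[[k]] <- 1:(d[k] - 1); idx_src[[k]] <- 2:d[k] }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# sample a breastfem_field at world points -> N x 3 displacements
sample_field <- function(field, pts) {
  t <- sweep(sweep(rbind(pts), 2, field$origin, `-`), 2, field$spacing, `/`)
  cbind(sample_trilinear_idx(field$d[, , , 1], t, clamp = TRUE),
        sample_trilinear_idx(field$d[, , , 2], t, clamp = TRUE),
        sample_trilinear_idx(field$d[, , , 3], t, clamp = TRUE))
}

# invert the forward map y = x + d(x) at query points y by fixed-point
# iteration x <- y - d(x); returns the material points x
invert_field_at <- function(field, y, tol = 0.1, max_iter = 20) {
  x <- y
  for (k in seq_len(max_iter)) {
    dn <- sample_field(field, x)
    xn <- y - dn
    delta <- sqrt(rowSums((xn - x)^2))
    x <- xn
    if (max(delta) < tol) break
  }
  attr(x, "nonconverged") <- sum(delta >= tol)
  x
}

#' Warp a volume through a dense displacement field
#'
#' Backward (pull) warping: each output voxel samples the moving image at the
#' inverse-mapped location. With `direction = "forward"` the field maps
#' moving-image points to target points (`y = x + d(x)`) and is inverted per
#' voxel by fixed-point iteration (tolerance 0.1 mm, 20 iterations); with
#' `direction = "inverse"` the field already maps target points to moving
#' points (`x = y + d(y)`). An optional affine transform `post` is composed
#' after the deformation (`y = post(x + d(x))`).
#'
#' @param moving a [volume()] or [label_map()]
#' @param field a `breastfem_field` (defined on the moving image frame for
#'   `"forward"`, on the target frame for `"inverse"`)
#' @param target a [volume()] defining the output grid (default: the field's)
#' @param direction `"forward"` or `"inverse"`
#' @param post optional 4x4 affine (see [affine_from_landmarks()]) composed
#'   after the deformation
#' @param interp `"linear"` or `"nearest"` (labels)
#' @return warped [volume()] (or [label_map()] when `interp = "nearest"` and
#'   `moving` is a label map); out-of-support voxels are zero-filled
#' @export
warp_volume <- function(moving, field, target = NULL,
                        direction = c("forward", "inverse"), post = NULL,
                        interp = c("linear", "nearest")) {
  direction <- match.arg(direction)
  interp <- match.arg(interp)
  if (is.null(target))
    target <- volume(array(0, dim(field$d)[1:3]), field$spacing, field$origin)
  d <- dim(target$data)
  ax <- lapply(1:3, function(k) target$origin[k] + (seq_len(d[k]) - 1) * target$spacing[k])
  y <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  if (!is.null(post)) y <- apply_affine(affine_inverse(post), y)
  if (direction == "forward") {
    x <- invert_field_at(field, y)
    nc <- attr(x, "nonconverged")
    if (!is.null(nc) && nc > 0)
      warning(nc, " voxels did not converge in field inversion")
  } else {
    x <- y + sample_field(field, y)
  }
  if (interp == "nearest") {
    vi <- round(world_to_voxel(moving, x))
    dm <- dim(moving$data)
    inb <- vi[, 1] >= 0 & vi[, 1] < dm[1] & vi[, 2] >= 0 & vi[, 2] < dm[2] &
           vi[, 3] >= 0 & vi[, 3] < dm[3]
    vals <- numeric(nrow(x))
    vals[inb] <- moving$data[vi[inb, , drop = FALSE] + 1]
    out <- array(vals, d)
    if (inherits(moving, "breastfem_labelmap"))
      return(label_map(array(as.integer(out), d), target$spacing, target$origin,
                       moving$axes))
    return(volume(out, target$spacing, target$origin, moving$axes))
  }
  vals <- sample_volume(moving, x, fill = 0)
  volume(array(vals, d), target$spacing, target$origin, moving$axes)
}

#' Landmark-based rigid / similarity / affine transform
#'
#' Closed-form least squares on paired landmarks. For 3 pairs a full 12-dof
#' affine is under-determined, so the `"affine"` kind requires at least 4
#' non-coplanar pairs; `"similarity"` (rotation, uniform scale, translation;
#' orthogonal-Procrustes solution) and `"rigid"` work from 3 non-collinear
#' pairs. Point sets whose best orthogonal map is a reflection are rejected.
#'
#' @param src,dst N x 3 matrices of paired world-mm points
#' @param kind `"similarity"`, `"rigid"` or `"affine"`
#' @return 4x4 matrix of class `breastfem_affine` (world mm, acts on column
#'   vectors), with attributes `kind` and `rms` (residual)
#' @export
affine_from_landmarks <- function(src, dst, kind = c("similarity", "rigid", "affine")) {
  kind <- match.arg(kind)
  src <- rbind(src); dst <- rbind(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- sweep(src, 2, cs); D <- sweep(dst, 2, cd)
  sv <- svd(crossprod(S))
  if (sum(sv$d > max(sv$d) * 1e-8) < 2) stop("landmarks are collinear")
  if (kind == "affine") {
    if (nrow(src) < 4 || sum(sv$d > max(sv$d) * 1e-8) < 3)
      stop("full affine needs at least 4 non-coplanar landmark pairs")
    L <- t(solve(crossprod(S), crossprod(S, D)))
    if (det(L) <= 0) stop("landmark correspondence requires a reflection; rejected")
    tr <- cd - L %*% cs
  } else {
    H <- crossprod(S, D)               # 3x3 covariance
    dec <- svd(H)
    dsgn <- sign(det(dec$v %*% t(dec$u)))
    if (dsgn < 0 && min(dec$d) > max(dec$d) * 1e-8)
      stop("landmark correspondence requires a reflection; rejected")
    Sg <- diag(c(1, 1, dsgn))
    R <- dec$v %*% Sg %*% t(dec$u)
    s <- if (kind == "similarity") sum(dec$d * diag(Sg)) / sum(S^2) else 1
    L <- s * R
    tr <- cd - L %*% cs
  }
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4] <- tr
  res <- apply_affine(A, src) - dst
  structure(A, class = "breastfem_affine", kind = kind,
            rms = sqrt(mean(rowSums(res^2))))
}

#' Apply a 4x4 affine to world-mm points
#' @param A 4x4 affine matrix
#' @param pts N x 3 points
#' @return N x 3 transformed points
#' @export
apply_affine <- function(A, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(A[1:3, 1:3]), 2, A[1:3, 4], `+`)
}

#' Invert a 4x4 affine
#' @param A 4x4 affine matrix
#' @export
affine_inverse <- function(A) {
  Li <- solve(A[1:3, 1:3])
  out <- diag(4)
  out[1:3, 1:3] <- Li
  out[1:3, 4] <- -Li %*% A[1:3, 4]
  class(out) <- class(A)
  out
}

#' Write / read an affine as a 4x4 world-mm text matrix
#' @param A 4x4 affine
#' @param path text file path
#' @export
write_affine <- function(A, path) {
  utils::write.table(unclass(A), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  A <- as.matrix(utils::read.table(path))
  dimnames(A) <- NULL
  class(A) <- "breastfem_affine"
  A
}

#' Two-colour fusion of a fixed and a warped moving volume
#'
#' The moving image is rendered green and the fixed image purple (red + blue)
#' after robust per-volume rescaling to the 2nd-98th intensity percentiles;
#' identical inputs therefore fuse to grey.
#'
#' @param fixed,warped_moving [volume()]s on the same grid
#' @return 4D array (dims x RGB) of class `breastfem_fusion` with `spacing`
#'   attribute
#' @export
fuse_overlay <- function(fixed, warped_moving) {
  if (!all(dim(fixed$data) == dim(warped_moving$data)) ||
      any(abs(fixed$spacing - warped_moving$spacing) > 1e-9))
    stop("fixed and moving volumes are on different grids")
  resc <- function(a) {
    q <- stats::quantile(a, c(0.02, 0.98), names = FALSE)
    if (q[2] <= q[1]) return(array(0, dim(a)))
    pmin(pmax((a - q[1]) / (q[2] - q[1]), 0), 1)
  }
  f <- resc(fixed$data); m <- resc(warped_moving$data)
  out <- array(0, c(dim(f), 3))
  out[, , , 1] <- f          # red   (fixed -> purple)
  out[, , , 2] <- m          # green (moving)
  out[, , , 3] <- f          # blue  (fixed -> purple)
  structure(out, class = "breastfem_fusion", spacing = fixed$spacing)
}

#' Plot one slice of a fusion volume
#' @param fusion a `breastfem_fusion`
#' @param slice slice index
#' @param axis slicing axis (1-3)
#' @export
plot_fusion_slice <- function(fusion, slice, axis = 3) {
  sl <- switch(as.character(axis),
               "1" = fusion[slice, , , , drop = FALSE],
               "2" = fusion[, slice, , , drop = FALSE],
               "3" = fusion[, , slice, , drop = FALSE])
  sl <- array(sl, dim(sl)[dim(sl) > 1])
  if (length(dim(sl)) != 3) stop("degenerate slice")
  img <- grDevices::rgb(sl[, , 1], sl[, , 2], sl[, , 3])
  dim(img) <- dim(sl)[1:2]
  graphics::plot.new()
  graphics::rasterImage(t(img)[nrow(t(img)):1, , drop = FALSE], 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(NULL)
}
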