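#' Solver configuration
#'
#' Numerical settings for the quasi-static gravity solves. The internal unit
#' system is mm-mN-kPa-kg-s (so kPa = mN/mm^2); gravity is given in m/s^2 and
#' densities in kg/m^3 at this boundary and converted internally.
#'
#' @param newton_tol relative residual tolerance for Newton iterations
#' @param newton_maxit maximum Newton iterations per load increment
#' @param increments initial number of equal gravity increments
#' @param max_subdivisions times an increment may be halved on Newton failure
#' @param gravity_supine,gravity_prone gravity vectors, m/s^2; the sign along
#'   the anteroposterior axis encodes posture (supine presses the breast
#'   toward the chest wall, prone pulls it away)
#' @param chest_fix `"ap"` fixes chest-wall nodes in the anteroposterior axis
#'   only (plus minimal in-plane pinning at two nodes to remove the rigid
#'   modes the stated condition leaves free); `"all"` fixes all three axes
#' @param skin_thickness skin-layer thickness, mm
#' @param ref_tol reference-state fixed point: mean surface mismatch (mm)
#' @param ref_maxit reference-state fixed point: maximum iterations
#' @param ref_damping initial damping factor of the fixed point (halved
#'   automatically when the mismatch grows for 3 consecutive iterations)
#' @param cg_maxit iteration cap of the preconditioned conjugate-gradient
#'   linear solver (meshes above `direct_maxdof`)
#' @param step_cap optional largest nodal displacement (mm) a single Newton
#'   step may apply; larger steps are scaled down (trust-region style).
#'   `NULL` (default) leaves steps uncapped
#' @param direct_maxdof largest displacement-dof count solved by the sparse
#'   Cholesky factorization; larger systems use the two-level preconditioned
#'   conjugate gradients, whose memory stays linear in mesh size and which
#'   handles indefinite tangents (from buckling-prone soft configurations)
#'   without factorization failures
#' @return list of class `breastfem_config`
#' @export
fem_config <- function(newton_tol = 1e-6, newton_maxit = 30, increments = 5,
                       max_subdivisions = 4, cg_maxit = 3000,
                       direct_maxdof = 100000, step_cap = NULL,
                       gravity_supine = c(0, 0, -9.81),
                       gravity_prone = c(0, 0, 9.81),
                       chest_fix = c("ap", "all"), skin_thickness = 1.0,
                       ref_tol = 0.2, ref_maxit = 10, ref_damping = 1.0,
                       verbose = FALSE) {
  structure(list(newton_tol = newton_tol, newton_maxit = newton_maxit,
                 increments = increments, max_subdivisions = max_subdivisions,
                 cg_maxit = cg_maxit, direct_maxdof = direct_maxdof,
                 step_cap = step_cap,
                 gravity_supine = gravity_supine, gravity_prone = gravity_prone,
                 chest_fix = match.arg(chest_fix),
                 skin_thickness = skin_thickness, ref_tol = ref_tol,
                 ref_maxit = ref_maxit, ref_damping = ref_damping,
                 verbose = verbose),
            class = "breastfem_config")
}

#' Boundary conditions for a gravity solve
#'
#' Chest-wall nodes are fixed in the anteroposterior axis (the stated physical
#' condition). Because that alone leaves the in-plane translations and the
#' rotation about the AP axis unconstrained, two chest-wall nodes receive
#' minimal in-plane pins (2 + 1 degrees of freedom) unless `chest_fix = "all"`.
#'
#' @param mesh a `breastfem_mesh`
#' @param gravity 3-vector, m/s^2
#' @param chest_fix see [fem_config()]
#' @return list with `fixed` (logical over the 3N displacement dofs) and
#'   `gravity`
#' @export
boundary_conditions <- function(mesh, gravity, chest_fix = "ap") {
  n <- nrow(mesh$nodes)
  cw <- mesh$chest_wall_nodes
  if (!length(cw)) stop("mesh has no chest-wall nodes")
  fixed <- matrix(FALSE, n, 3)
  if (chest_fix == "all") {
    fixed[cw, ] <- TRUE
  } else {
    ax <- mesh$chest_axis
    fixed[cw, ax] <- TRUE
    ip <- setdiff(1:3, ax)
    pts <- mesh$nodes[cw, ip, drop = FALSE]
    ctr <- colMeans(pts)
    a <- which.min(rowSums(sweep(pts, 2, ctr, `-`)^2))
    b <- which.max(rowSums(sweep(pts, 2, pts[a, ], `-`)^2))
    fixed[cw[a], ip] <- TRUE
    ab <- pts[b, ] - pts[a, ]
    # pin the in-plane axis perpendicular to the dominant AB direction
    fixed[cw[b], ip[which.min(abs(ab))]] <- TRUE
  }
  list(fixed = as.vector(t(fixed)), gravity = as.numeric(gravity))
}

#' Neo-Hookean strain energy density
#'
#' `psi = mu/2 (Ibar1 - 3) + K/2 (J - 1)^2` with the isochoric invariant
#' `Ibar1 = J^(-2/3) tr(F'F)` and `J = det(F)`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`
#' @param mu,K shear and bulk modulus, kPa
#' @return strain energy density, kPa
#' @export
strain_energy <- function(F, mu, K) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (J <= 0) stop("inverted deformation gradient: det(F) = ", signif(J, 4))
  Ibar1 <- J^(-2 / 3) * sum(F * F)
  mu / 2 * (Ibar1 - 3) + K / 2 * (J - 1)^2
}

# precompute and cache the tangent sparsity structure on the mesh, plus a
# geometric nested-dissection node ordering for the direct factorization
fem_prepare <- function(mesh) {
  if (is.null(mesh$structure)) {
    mesh$structure <- fem_structure(mesh$elements, nrow(mesh$nodes))
    mesh$structure$nd <- nd_order(mesh$nodes, mesh$element_size)
  }
  mesh
}

# Trilinear prolongation from a 2x-coarser lattice over the mesh's
# structured grid; rows of fixed dofs are zeroed. Used as the coarse-level
# correction of the two-level preconditioner for large meshes.
build_prolongation <- function(mesh, fixed) {
  g <- mesh$grid
  if (is.null(g)) return(NULL)
  H <- 2 * g$h
  ncc <- pmax(1L, as.integer(ceiling(g$ncell / 2)))
  occf <- which(g$cell_elem > 0, arr.ind = TRUE) - 1L
  occ <- array(FALSE, ncc)
  occ[(occf %/% 2L) + 1L] <- TRUE
  occ_cells <- which(occ, arr.ind = TRUE) - 1L

  nnc <- ncc + 1L
  nid_of <- function(i, j, k) i + nnc[1] * (j + nnc[2] * k)
  corner <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
  cl <- matrix(0L, nrow(occ_cells), 8)
  for (a in 1:8)
    cl[, a] <- nid_of(occ_cells[, 1] + corner[a, 1],
                      occ_cells[, 2] + corner[a, 2],
                      occ_cells[, 3] + corner[a, 3])
  used <- sort(unique(as.integer(cl)))
  remap <- integer(max(used) + 1L)
  remap[used + 1L] <- seq_along(used)

  x <- mesh$nodes
  t <- sweep(x, 2, g$lo, `-`) / H
  ci <- pmin(pmax(floor(t + 1e-9), 0), matrix(rep(ncc - 1L, each = nrow(x)),
                                              ncol = 3))
  miss <- !occ[ci + 1L]
  if (any(miss)) {
    # snap stray (mostly skin) nodes to the nearest occupied coarse cell
    ctr <- (occ_cells + 0.5) %*% diag(rep(H, 3))
    ctr <- sweep(ctr, 2, g$lo, `+`)
    for (m in which(miss)) {
      d2 <- rowSums(sweep(ctr, 2, x[m, ], `-`)^2)
      ci[m, ] <- occ_cells[which.min(d2), ]
    }
  }
  tl <- pmin(pmax(t - ci, 0), 1)
  nfine <- nrow(x)
  ii <- jj <- integer(0)
  ww <- numeric(0)
  for (a in 1:8) {
    w <- (if (corner[a, 1]) tl[, 1] else 1 - tl[, 1]) *
         (if (corner[a, 2]) tl[, 2] else 1 - tl[, 2]) *
         (if (corner[a, 3]) tl[, 3] else 1 - tl[, 3])
    keep <- w > 1e-12
    cn <- remap[nid_of(ci[keep, 1] + corner[a, 1], ci[keep, 2] + corner[a, 2],
                       ci[keep, 3] + corner[a, 3]) + 1L]
    ii <- c(ii, which(keep))
    jj <- c(jj, cn)
    ww <- c(ww, w[keep])
  }
  # expand node-level weights to the three displacement dofs
  rows <- as.integer(3 * (rep(ii, each = 3) - 1) + rep(1:3, length(ii)))
  cols <- as.integer(3 * (rep(jj, each = 3) - 1) + rep(1:3, length(jj)))
  vals <- rep(ww, each = 3)
  drop_r <- fixed[rows]
  P <- Matrix::sparseMatrix(i = rows[!drop_r], j = cols[!drop_r],
                            x = vals[!drop_r],
                            dims = c(3 * nfine, 3 * length(used)))
  P
}

# Conjugate gradients preconditioned by a symmetric two-level cycle:
# forward Gauss-Seidel pre-smoothing, Galerkin coarse correction solved by a
# cached Cholesky factor, backward Gauss-Seidel post-smoothing.
twolevel_pcg <- function(str, xv, b, tol, maxit, P, Acfac) {
  matvec <- function(x) fem_spmv(str$i, str$p, xv, x)
  prec <- function(r) {
    z1 <- fem_gs_forward(str$i, str$p, xv, r)
    r1 <- r - matvec(z1)
    z2 <- z1 + as.numeric(P %*% Matrix::solve(Acfac, Matrix::crossprod(P, r1)))
    r2 <- r - matvec(z2)
    z2 + fem_gs_backward(str$i, str$p, xv, r2)
  }
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(list(x = numeric(length(b)), iters = 0L, relres = 0,
                           curvature_fail = FALSE))
  x <- numeric(length(b))
  r <- b
  z <- prec(r)
  p <- z
  rz <- sum(r * z)
  relres <- 1
  curv <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    Ap <- matvec(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) { curv <- TRUE; break }
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bn
    if (relres <= tol) break
    z <- prec(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, iters = it, relres = relres, curvature_fail = curv)
}

# geometric nested dissection: recursively split the node cloud at the median
# lattice plane of its longest axis; separators are emitted last, which keeps
# the Cholesky fill of the structured hex meshes low without a graph library
nd_order <- function(coords, h) {
  rec <- function(ids) {
    if (length(ids) <= 150) return(ids)
    cc <- coords[ids, , drop = FALSE]
    rng <- apply(cc, 2, function(x) diff(range(x)))
    ax <- which.max(rng)
    ux <- sort(unique(round(cc[, ax], 6)))
    v <- ux[ceiling(length(ux) / 2)]
    sep <- abs(cc[, ax] - v) <= 0.45 * h
    left <- cc[, ax] < v - 0.45 * h
    right <- !sep & !left
    if (!any(left) || !any(right)) return(ids)
    c(rec(ids[left]), rec(ids[right]), ids[sep])
  }
  rec(seq_len(nrow(coords)))
}

# assemble the full tangent as dgCMatrix from the prefilled pattern
tangent_matrix <- function(str, xv, ndof) {
  methods::new("dgCMatrix", i = str$i, p = str$p, x = as.numeric(xv),
               Dim = c(as.integer(ndof), as.integer(ndof)))
}

#' Quasi-static gravity solve
#'
#' Minimises the total potential energy (neo-Hookean strain energy minus
#' gravity work) by Newton iteration with backtracking line search and
#' adaptive incremental loading: the gravity load is ramped in
#' `config$increments` equal steps, an increment is halved when Newton fails
#' (up to `config$max_subdivisions` times) and allowed to grow again after
#' fast convergence.
#'
#' The linearised systems are solved by conjugate gradients with a symmetric
#' Gauss-Seidel preconditioner and an inexact-Newton forcing tolerance, which
#' keeps memory linear in mesh size.
#'
#' @param mesh a `breastfem_mesh` (skin layer already added if wanted)
#' @param materials a [material_params()]
#' @param bc a [boundary_conditions()]
#' @param config a [fem_config()]
#' @param u0 optional N x 3 warm-start displacement
#' @return object of class `breastfem_displacement`: `u` (N x 3 mm),
#'   `converged`, `residual_norm`, `load_steps`, `newton_iters`, `mesh`
#' @export
solve_gravity <- function(mesh, materials, bc, config = fem_config(),
                          u0 = NULL, prefer_cg = FALSE) {
  mesh <- fem_prepare(mesh)
  str <- mesh$structure
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  em <- element_materials(mesh, materials)
  g_mm <- bc$gravity * 1000             # m/s^2 -> mm/s^2
  bf <- outer(em$rho, g_mm)             # mN/mm^3 per element
  fext <- fem_body_force(mesh$nodes, mesh$elements, bf)
  fixed <- bc$fixed
  free <- which(!fixed)
  fext[fixed] <- 0
  fext_norm <- sqrt(sum(fext[free]^2))

  u <- if (!is.null(u0)) as.numeric(t(u0)) else numeric(ndof)
  u[fixed] <- 0
  used_warm <- !is.null(u0)
  total_iters <- 0L
  steps <- 0L
  lam <- 0
  dlam0 <- 1 / config$increments
  dlam <- dlam0
  dlam_min <- dlam0 / 2^config$max_subdivisions

  use_direct <- ndof <= config$direct_maxdof
  # dof-level nested-dissection permutation (direct path)
  if (use_direct) {
    rank_node <- integer(n)
    rank_node[str$nd] <- seq_len(n)
    perm <- order(rep(rank_node, each = 3), rep(1:3, times = n))
    dstate <- new.env(parent = emptyenv())   # Chol factor cache
  }
  tlstate <- new.env(parent = emptyenv())    # two-level preconditioner cache

  quiet_or_null <- function(expr) {
    # evaluate, but treat any warning (e.g. CHOLMOD indefiniteness) as
    # failure without unwinding mid-C
    bad <- FALSE
    f <- withCallingHandlers(
      tryCatch(expr, error = function(e) NULL),
      warning = function(w) {
        bad <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (bad) NULL else f
  }

  step_cap <- if (!is.null(config$step_cap)) config$step_cap else Inf
  eta_cg <- 1e-2   # inexact-Newton forcing term (Eisenstat-Walker style)
  mode_direct <- use_direct && !isTRUE(prefer_cg)
  linsolve <- function(asm, r, refactor) {
    # returns du (or NULL on failure); assembles into dstate on refactor.
    # A failed factorization (indefinite tangent) permanently demotes this
    # solve to the conjugate-gradient path, which tolerates indefiniteness.
    if (mode_direct) {
      if (refactor || is.null(dstate$Chol)) {
        # CHOLMOD factors live outside R's heap accounting; collect stale
        # ones before allocating the next or they pile up un-GC'd
        gc(FALSE)
        fem_apply_bc(str$i, str$p, asm$xv, fixed)
        A <- tangent_matrix(str, asm$xv, ndof)
        Ap <- Matrix::forceSymmetric(A[perm, perm])
        # CHOLMOD reports an indefinite matrix as a *warning*; trap it and
        # drop the (possibly half-updated) factor. Failed supernodal
        # factorizations leak workspace inside CHOLMOD, so exactly ONE
        # attempt is made before demoting to conjugate gradients.
        f <- if (!is.null(dstate$Chol)) {
          g <- quiet_or_null(Matrix::update(dstate$Chol, Ap))
          if (is.null(g)) dstate$Chol <- NULL
          g
        } else {
          quiet_or_null(Matrix::Cholesky(Ap, LDL = FALSE, super = TRUE,
                                         perm = FALSE))
        }
        ok <- !is.null(f)
        if (ok) dstate$Chol <- f
        fem_release_memory()
        if (!ok) {
          # with a live warm start at zero load the failure usually comes
          # from the warm state itself: let the ramp drop it and stay direct
          if (used_warm && lam == 0) return(NULL)
          mode_direct <<- FALSE
          dstate$Chol <- NULL
          gc(FALSE)
          fem_release_memory()
          return(linsolve_cg(asm, r, TRUE))
        }
      }
      du <- numeric(ndof)
      du[perm] <- as.numeric(Matrix::solve(dstate$Chol, -r[perm]))
      du
    } else {
      linsolve_cg(asm, r, refactor)
    }
  }

  linsolve_cg <- function(asm, r, refactor) {
    {
      fem_apply_bc(str$i, str$p, asm$xv, fixed)
      if (is.null(tlstate$tried)) {
        tlstate$tried <- TRUE
        tlstate$P <- build_prolongation(mesh, fixed)
      }
      if (!is.null(tlstate$P) && (refactor || is.null(tlstate$Acfac))) {
        A <- tangent_matrix(str, asm$xv, ndof)
        Ac <- Matrix::forceSymmetric(
          Matrix::crossprod(tlstate$P, A %*% tlstate$P))
        base <- mean(abs(Ac@x))
        tlstate$Acfac <- NULL
        for (sh in base * c(1e-10, 1e-6, 1e-3)) {
          f <- quiet_or_null(Matrix::Cholesky(
            Ac + Matrix::Diagonal(ncol(Ac), sh), LDL = FALSE, super = TRUE))
          if (!is.null(f)) { tlstate$Acfac <- f; break }
        }
        if (is.null(tlstate$Acfac)) tlstate$P <- NULL  # coarse level unusable
      }
      cg <- if (!is.null(tlstate$P) && !is.null(tlstate$Acfac))
        twolevel_pcg(str, asm$xv, -r, eta_cg, config$cg_maxit,
                     tlstate$P, tlstate$Acfac)
      else fem_pcg(str$i, str$p, asm$xv, -r, eta_cg, config$cg_maxit, 1.0)
      tlstate$last_iters <- cg$iters
      tlstate$last_curv <- cg$curvature_fail
      if (cg$curvature_fail && cg$iters <= 1) return(NULL)
      cg$x
    }
  }

  newton <- function(u, lam_t) {
    # returns list(u, ok, iters, rnorm); modified Newton on the direct path
    # (the factor is reused while the residual drops fast)
    target <- max(config$newton_tol * lam_t * fext_norm, 1e-10)
    rn <- Inf
    rn_prev <- Inf
    refactor <- !use_direct || is.null(dstate$Chol)
    for (it in seq_len(config$newton_maxit)) {
      need_tangent <- !use_direct || refactor || is.null(dstate$Chol)
      asm <- fem_assemble(mesh$nodes, mesh$elements, u, em$mu, em$K,
                          need_tangent, str$nodeptr, str$rank,
                          if (need_tangent) str$nnz else 0)
      if (asm$bad) return(list(u = u, ok = FALSE, iters = it, rnorm = Inf))
      r <- asm$grad - lam_t * fext
      r[fixed] <- 0
      rn <- sqrt(sum(r^2))
      if (rn <= target)
        return(list(u = u, ok = TRUE, iters = it, rnorm = rn))
      # forcing term: loose far from the solution, tightening with the
      # observed contraction, never tighter than the Newton target needs;
      # capped at 1e-2 so an occasional residual rise cannot trigger
      # near-useless single-iteration solves
      eta <- if (!is.finite(rn_prev)) 1e-2
             else min(1e-2, max(0.5 * (rn / rn_prev)^2, 1e-4))
      eta_cg <<- min(max(eta, 0.1 * target / rn, 1e-6), 1e-2)
      du <- linsolve(asm, r, refactor)
      fresh <- refactor
      if (is.null(du)) return(list(u = u, ok = FALSE, iters = it, rnorm = rn))
      # trust-region-style cap on the step length: soft configurations
      # otherwise overshoot into buckled, indefinite states
      dmax <- max(abs(du))
      if (dmax > step_cap) du <- du * (step_cap / dmax)
      # backtracking line search with an Armijo sufficient-decrease test:
      # plain energy decrease still admits overshooting steps into buckled,
      # indefinite states; demanding decrease proportional to the step
      # keeps the iterates in well-behaved territory
      e0 <- asm$energy - lam_t * sum(fext * u)
      gdu <- sum(r * du)               # directional derivative (negative)
      alpha <- 1
      ok_step <- FALSE
      for (ls in 1:12) {
        u_try <- u + alpha * du
        et <- fem_assemble(mesh$nodes, mesh$elements, u_try, em$mu, em$K,
                           FALSE, str$nodeptr, str$rank, 0)
        ene <- if (et$bad) Inf else et$energy - lam_t * sum(fext * u_try)
        if (is.finite(ene) &&
            ene <= e0 + 0.1 * alpha * gdu + 1e-10 * abs(e0) + 1e-12) {
          u <- u_try
          ok_step <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (isTRUE(config$verbose))
        cat(sprintf("    newton it=%d rn=%.3g target=%.3g alpha=%.3g fresh=%d %s eta=%.1e mem=%.0fMB\n",
                    it, rn, target, alpha, fresh,
                    if (mode_direct) "direct" else
                      sprintf("cg=%d%s", tlstate$last_iters,
                              if (isTRUE(tlstate$last_curv)) "!" else ""),
                    eta_cg, sum(gc(FALSE)[, 2])))
      if (!ok_step) {
        if (fresh) return(list(u = u, ok = FALSE, iters = it, rnorm = rn))
        refactor <- TRUE        # stale factor: rebuild and retry
        next
      }
      # refactor when progress stalls or the step needed damping
      refactor <- alpha < 1 || rn > 0.3 * rn_prev
      rn_prev <- rn
    }
    list(u = u, ok = FALSE, iters = config$newton_maxit, rnorm = rn)
  }

  if (fext_norm == 0) {
    res <- list(u = u * 0, ok = TRUE, iters = 1L, rnorm = 0)
    u <- u * 0
    total_iters <- 1L
    steps <- 1L
    lam <- 1
  } else {
    while (lam < 1 - 1e-12) {
      lam_t <- min(lam + dlam, 1)
      if (isTRUE(config$verbose))
        cat(sprintf("  increment: lam %.4g -> %.4g\n", lam, lam_t))
      res <- newton(u, lam_t)
      total_iters <- total_iters + res$iters
      if (res$ok) {
        u <- res$u
        lam <- lam_t
        steps <- steps + 1L
        # grow the step after easy increments; near-linear problems then
        # finish in two or three increments
        if (res$iters <= 5) dlam <- min(dlam * 2, 1)
      } else if (lam == 0 && used_warm) {
        # a bad warm start can make every increment unsolvable; drop it
        u <- numeric(ndof)
        used_warm <- FALSE
        dlam <- dlam0
      } else {
        dlam <- dlam / 2
        if (dlam < dlam_min - 1e-15)
          stop("gravity solve failed to converge (load factor ", signif(lam, 4),
               ", last residual ", signif(res$rnorm, 4), ")")
      }
    }
  }
  out <- structure(list(u = matrix(u, n, 3, byrow = TRUE), converged = TRUE,
                        residual_norm = res$rnorm, load_steps = steps,
                        newton_iters = total_iters, mesh = mesh,
                        used_cg = !mode_direct),
                   class = "breastfem_displacement")
  if (use_direct) rm(dstate)
  rm(tlstate)
  gc(FALSE)
  fem_release_memory()
  out
}

#' @export
print.breastfem_displacement <- function(x, ...) {
  mag <- sqrt(rowSums(x$u^2))
  cat("<DisplacementField> ", nrow(x$u), " nodes; |u| max ",
      signif(max(mag), 4), " mm, mean ", signif(mean(mag), 4),
      " mm; ", x$load_steps, " load steps, ", x$newton_iters,
      " Newton iterations, residual ", signif(x$residual_norm, 3), "\n",
      sep = "")
  invisible(x)
}

#' Estimate the load-free reference configuration
#'
#' All images are acquired under gravity, so the imaged supine geometry is a
#' loaded state. The load-free geometry is recovered by the fixed-point
#' iteration `X <- X - damping * (forward(X) - x_obs)`: forward-solving the
#' current reference guess under supine gravity and subtracting the surface
#' mismatch, until the mean mismatch over surface nodes falls below
#' `config$ref_tol` (mm). The damping factor is halved when the mismatch grows
#' for 3 consecutive iterations; persistent divergence is an error.
#'
#' @param mesh the observed (gravity-loaded) supine `breastfem_mesh`
#' @param materials a [material_params()]
#' @param gravity_supine supine gravity vector, m/s^2
#' @param config a [fem_config()]
#' @param init_nodes optional warm-start guess for the load-free node
#'   positions (e.g. the estimate from a nearby material trial)
#' @return the estimated load-free mesh, with attributes `ref_iterations`,
#'   `ref_mismatch` (mm) and `ref_u` (forward displacement at convergence)
#' @export
estimate_reference_state <- function(mesh, materials,
                                     gravity_supine = fem_config()$gravity_supine,
                                     config = fem_config(),
                                     init_nodes = NULL) {
  mesh <- fem_prepare(mesh)
  x_obs <- mesh$nodes
  if (sqrt(sum(gravity_supine^2)) == 0) {
    attr(mesh, "ref_iterations") <- 0L
    attr(mesh, "ref_mismatch") <- 0
    return(mesh)
  }
  surf <- unique(as.integer(mesh$surface_facets))
  damping <- config$ref_damping
  ref <- mesh
  if (!is.null(init_nodes)) ref$nodes <- init_nodes
  prev <- Inf
  worse <- 0L
  mism <- NA_real_
  sol <- NULL
  uw <- NULL
  prev_nodes <- NULL
  k <- 0L
  while (k < config$ref_maxit) {
    k <- k + 1L
    bc <- boundary_conditions(ref, gravity_supine, config$chest_fix)
    sol <- tryCatch(solve_gravity(ref, materials, bc, config, u0 = uw),
                    error = function(e) NULL)
    if (isTRUE(config$verbose))
      cat(sprintf("  ref-state it=%d %s damping=%.3g\n", k,
                  if (is.null(sol)) "SOLVE FAILED" else
                    sprintf("iters=%d used_cg=%d", sol$newton_iters,
                            isTRUE(sol$used_cg)), damping))
    if (is.null(sol)) {
      # update made the geometry unsolvable: revert it and damp harder
      if (is.null(prev_nodes)) {
        if (!is.null(init_nodes)) {
          # bad warm-start geometry: restart from the observed mesh
          ref$nodes <- x_obs
          init_nodes <- NULL
          uw <- NULL
          next
        }
        stop("forward solve failed on the observed geometry")
      }
      ref$nodes <- prev_nodes
      prev_nodes <- NULL
      damping <- damping / 2
      if (damping < 0.05)
        stop("reference-state iteration diverges; try a smaller damping factor")
      next
    }
    uw <- sol$u
    err <- (ref$nodes + sol$u) - x_obs
    mism <- mean(sqrt(rowSums(err[surf, , drop = FALSE]^2)))
    if (mism < config$ref_tol) break
    if (mism >= prev) {
      worse <- worse + 1L
      if (worse >= 3L) {
        damping <- damping / 2
        worse <- 0L
        if (damping < 0.05)
          stop("reference-state iteration diverges; try a smaller damping factor")
      }
    } else worse <- 0L
    prev <- mism
    prev_nodes <- ref$nodes
    ref$nodes <- ref$nodes - damping * err
  }
  attr(ref, "ref_iterations") <- k
  attr(ref, "ref_mismatch") <- mism
  attr(ref, "ref_u") <- sol$u
  ref
}

#' Simulate the supine-to-prone breast deformation
#'
#' Composition of the two gravity steps: the load-free reference geometry is
#' estimated from the observed supine mesh under supine gravity, then the
#' reference is loaded under prone gravity. The returned field maps each
#' supine node position to its prone position.
#'
#' @inheritParams estimate_reference_state
#' @param warm optional environment carrying warm starts between repeated
#'   simulations on the same mesh (as in the material grid search); fields
#'   `ref_nodes` and `u_prone` are read and updated
#' @return a `breastfem_displacement` whose `u` is the supine-to-prone nodal
#'   displacement (mm); carries the reference mesh as `reference` and the
#'   prone solve as `prone_solution`
#' @export
simulate_supine_to_prone <- function(mesh, materials, config = fem_config(),
                                     warm = NULL) {
  ref <- estimate_reference_state(mesh, materials, config$gravity_supine,
                                  config,
                                  init_nodes = if (!is.null(warm)) warm$ref_nodes)
  bc <- boundary_conditions(ref, config$gravity_prone, config$chest_fix)
  sol <- solve_gravity(ref, materials, bc, config,
                       u0 = if (!is.null(warm)) warm$u_prone)
  u_total <- (ref$nodes + sol$u) - mesh$nodes
  if (!is.null(warm)) {
    warm$ref_nodes <- ref$nodes
    warm$u_prone <- sol$u
  }
  out <- sol
  out$u <- u_total
  out$reference <- ref
  out$prone_solution <- sol
  out$mesh <- mesh
  out
}

#' Nipple displacement magnitude of a supine-to-prone simulation
#' @param sol a `breastfem_displacement` from [simulate_supine_to_prone()]
#' @return displacement magnitude in mm
#' @export
nipple_displacement <- function(sol) {
  nn <- sol$mesh$nipple_node
  if (is.na(nn)) stop("mesh has no nipple node; see set_nipple_node()")
  sqrt(sum(sol$u[nn, ]^2))
}
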