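# Independent small-strain linear-elastic hex FE solver used as an oracle for
# the small-gravity limit of the hyperelastic solver. Same mesh and boundary
# conditions, but a separate formulation: engineering-strain B-matrices,
# deviatoric term at 2x2x2 Gauss points, volumetric term at the element
# centre (selective reduced integration, mirroring the nonlinear solver's
# treatment of near-incompressibility), assembled densely and solved with
# base R. Only suitable for small meshes.

linear_hex_shape <- function(xi, eta, zeta) {
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  N <- (1 + xi * sx) * (1 + eta * sy) * (1 + zeta * sz) / 8
  dN <- cbind(sx * (1 + eta * sy) * (1 + zeta * sz),
              sy * (1 + xi * sx) * (1 + zeta * sz),
              sz * (1 + xi * sx) * (1 + eta * sy)) / 8
  list(N = N, dN = dN)
}

linear_solve_gravity <- function(mesh, materials, bc) {
  em <- breastfem:::element_materials(mesh, materials)
  nn <- nrow(mesh$nodes)
  ndof <- 3 * nn
  K <- matrix(0, ndof, ndof)
  f <- numeric(ndof)
  g <- bc$gravity * 1000
  gp1 <- 1 / sqrt(3)
  gps <- as.matrix(expand.grid(c(-gp1, gp1), c(-gp1, gp1), c(-gp1, gp1)))

  dev_D <- function(mu) {
    # deviatoric stiffness in Voigt order (xx, yy, zz, xy, yz, xz)
    D <- matrix(0, 6, 6)
    D[1:3, 1:3] <- -2 * mu / 3
    diag(D)[1:3] <- 4 * mu / 3
    diag(D)[4:6] <- mu
    D
  }
  vol_D <- function(Kb) {
    D <- matrix(0, 6, 6)
    D[1:3, 1:3] <- Kb
    D
  }
  bmat <- function(dNdX) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dNdX[a, 1]
      B[2, c0 + 2] <- dNdX[a, 2]
      B[3, c0 + 3] <- dNdX[a, 3]
      B[4, c0 + 1] <- dNdX[a, 2]; B[4, c0 + 2] <- dNdX[a, 1]
      B[5, c0 + 2] <- dNdX[a, 3]; B[5, c0 + 3] <- dNdX[a, 2]
      B[6, c0 + 1] <- dNdX[a, 3]; B[6, c0 + 3] <- dNdX[a, 1]
    }
    B
  }

  for (e in seq_len(nrow(mesh$elements))) {
    en <- mesh$elements[e, ]
    Xe <- mesh$nodes[en, ]
    Ke <- matrix(0, 24, 24)
    fe <- numeric(24)
    at_gp <- function(xi) {
      sh <- linear_hex_shape(xi[1], xi[2], xi[3])
      J <- t(Xe) %*% sh$dN
      dNdX <- sh$dN %*% solve(J)
      list(dNdX = dNdX, detJ = det(J), N = sh$N)
    }
    Dd <- dev_D(em$mu[e])
    for (k in 1:8) {
      q <- at_gp(gps[k, ])
      B <- bmat(q$dNdX)
      Ke <- Ke + q$detJ * t(B) %*% Dd %*% B
      bfe <- em$rho[e] * g
      for (a in 1:8)
        fe[3 * (a - 1) + 1:3] <- fe[3 * (a - 1) + 1:3] + q$detJ * q$N[a] * bfe
    }
    qc <- at_gp(c(0, 0, 0))
    Bc <- bmat(qc$dNdX)
    Ke <- Ke + 8 * qc$detJ * t(Bc) %*% vol_D(em$K[e]) %*% Bc
    idx <- as.vector(t(outer(en - 1, 1:3, function(a, c) 3 * a + c)))
    K[idx, idx] <- K[idx, idx] + Ke
    f[idx] <- f[idx] + fe
  }
  free <- !bc$fixed
  u <- numeric(ndof)
  u[free] <- solve(K[free, free], f[free])
  matrix(u, nn, 3, byrow = TRUE)
}
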