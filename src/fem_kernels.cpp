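// Assembly kernels for the total-Lagrangian neo-Hookean hexahedral solver.
//
// Strain energy per integration point:
//   psi = mu/2 * (Ibar1 - 3) + K/2 * (J - 1)^2,  Ibar1 = J^(-2/3) tr(F'F)
// Selective reduced integration: the isochoric term is integrated at the full
// 2x2x2 Gauss rule, the volumetric term at the element centre only, which
// prevents volumetric locking at nu = 0.49.
//
// The tangent sparsity pattern is fixed for a given mesh; fem_structure()
// builds it once (dgCMatrix i/p plus an element -> entry rank map), and
// fem_assemble() then refills only the numeric values each Newton iteration.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Return freed heap pages to the OS. The Newton loops churn many
// hundred-MB temporaries; glibc's dynamic mmap threshold otherwise retains
// them in the arena and long sessions accumulate gigabytes of dead heap.
// [[Rcpp::export]]
void fem_release_memory() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

static const double GP = 0.5773502691896257645091488; // 1/sqrt(3)

// node order: (-,-,-),(+,-,-),(+,+,-),(-,+,-),(-,-,+),(+,-,+),(+,+,+),(-,+,+)
static const double XN[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
static const double YN[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
static const double ZN[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

static inline void shape_grad_nat(double xi, double eta, double zeta,
                                  double dN[8][3], double N[8]) {
  for (int a = 0; a < 8; ++a) {
    N[a] = 0.125 * (1 + xi * XN[a]) * (1 + eta * YN[a]) * (1 + zeta * ZN[a]);
    dN[a][0] = 0.125 * XN[a] * (1 + eta * YN[a]) * (1 + zeta * ZN[a]);
    dN[a][1] = 0.125 * YN[a] * (1 + xi * XN[a]) * (1 + zeta * ZN[a]);
    dN[a][2] = 0.125 * ZN[a] * (1 + xi * XN[a]) * (1 + eta * YN[a]);
  }
}

static inline double det3(const double A[3][3]) {
  return A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
       - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
       + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
}

static inline void inv3(const double A[3][3], double Ai[3][3], double det) {
  double id = 1.0 / det;
  Ai[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ai[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) * id;
  Ai[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ai[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) * id;
  Ai[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ai[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) * id;
  Ai[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ai[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) * id;
  Ai[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
}

// Build the symmetric node adjacency and the dgCMatrix pattern of the 3N x 3N
// tangent, plus for every element the rank of each (row-node, col-node) pair
// inside the column node's sorted neighbour list.
// [[Rcpp::export]]
List fem_structure(IntegerMatrix elems, int nnode) {
  int M = elems.nrow();
  std::vector<std::vector<int>> nbr(nnode);
  for (int q = 0; q < nnode; ++q) nbr[q].reserve(32);
  for (int e = 0; e < M; ++e)
    for (int p = 0; p < 8; ++p) {
      int a = elems(e, p) - 1;
      for (int q = 0; q < 8; ++q) nbr[elems(e, q) - 1].push_back(a);
    }
  std::vector<int> deg(nnode);
  for (int q = 0; q < nnode; ++q) {
    std::sort(nbr[q].begin(), nbr[q].end());
    nbr[q].erase(std::unique(nbr[q].begin(), nbr[q].end()), nbr[q].end());
    deg[q] = (int)nbr[q].size();
  }
  IntegerVector nodeptr(nnode + 1);
  long long tot = 0;
  for (int q = 0; q < nnode; ++q) { nodeptr[q] = (int)tot; tot += deg[q]; }
  nodeptr[nnode] = (int)tot;
  long long nnz = 9LL * tot;
  if (nnz > INT_MAX) stop("tangent pattern too large");

  IntegerMatrix rank(M, 64);
  for (int e = 0; e < M; ++e)
    for (int q = 0; q < 8; ++q) {
      int cn = elems(e, q) - 1;
      const std::vector<int> &v = nbr[cn];
      for (int p = 0; p < 8; ++p) {
        int a = elems(e, p) - 1;
        int r = (int)(std::lower_bound(v.begin(), v.end(), a) - v.begin());
        rank(e, q * 8 + p) = r;
      }
    }

  IntegerVector pi((int)nnz), pp(3 * nnode + 1);
  long long pos = 0;
  for (int q = 0; q < nnode; ++q)
    for (int c = 0; c < 3; ++c) {
      pp[3 * q + c] = (int)pos;
      for (int a : nbr[q]) {
        pi[pos++] = 3 * a;
        pi[pos++] = 3 * a + 1;
        pi[pos++] = 3 * a + 2;
      }
    }
  pp[3 * nnode] = (int)pos;
  return List::create(_["i"] = pi, _["p"] = pp, _["nodeptr"] = nodeptr,
                      _["rank"] = rank, _["nnz"] = (double)nnz);
}

// isochoric first Piola stress P = mu c (F - I1/3 F^{-T}), c = J^{-2/3}
static inline void iso_stress(const double F[3][3], const double G[3][3],
                              double J, double mu, double I1, double P[3][3]) {
  double c = std::pow(J, -2.0 / 3.0);
  for (int i = 0; i < 3; ++i)
    for (int a = 0; a < 3; ++a)
      P[i][a] = mu * c * (F[i][a] - I1 / 3.0 * G[a][i]);
}

// Strain energy, internal-force gradient and (optionally) tangent values in
// the fem_structure() pattern. u is a 3N vector, dof = 3*(node-1) + axis.
// Returns bad = TRUE with energy = Inf when any integration point has J <= 0.
// [[Rcpp::export]]
List fem_assemble(NumericMatrix nodes, IntegerMatrix elems, NumericVector u,
                  NumericVector mu, NumericVector Kb,
                  bool want_tangent, IntegerVector nodeptr, IntegerMatrix rank,
                  double nnz) {
  int M = elems.nrow(), N = nodes.nrow();
  NumericVector grad(3 * N);
  NumericVector xv(want_tangent ? (R_xlen_t)nnz : 0);
  double energy = 0, minJ = R_PosInf;
  bool bad = false;

  // gauss points: 8 full + centre
  double gp[9][3];
  for (int k = 0; k < 8; ++k) {
    gp[k][0] = GP * XN[k]; gp[k][1] = GP * YN[k]; gp[k][2] = GP * ZN[k];
  }
  gp[8][0] = gp[8][1] = gp[8][2] = 0.0;
  double dNn[9][8][3], Nn[9][8];
  for (int k = 0; k < 9; ++k) shape_grad_nat(gp[k][0], gp[k][1], gp[k][2], dNn[k], Nn[k]);

  std::vector<int> degc(nodeptr.size() - 1);
  for (int q = 0; q + 1 < (int)nodeptr.size(); ++q) degc[q] = nodeptr[q + 1] - nodeptr[q];

  double Ke[24][24];
  for (int e = 0; e < M && !bad; ++e) {
    double Xe[8][3], ue[8][3];
    int nid[8];
    for (int a = 0; a < 8; ++a) {
      nid[a] = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = nodes(nid[a], i);
        ue[a][i] = u[3 * nid[a] + i];
      }
    }
    double fe[8][3] = {{0}};
    if (want_tangent) std::fill(&Ke[0][0], &Ke[0][0] + 576, 0.0);

    for (int k = 0; k < 9; ++k) {
      bool volpt = (k == 8);
      double w = volpt ? 8.0 : 1.0;
      // reference jacobian A = dX/dxi
      double Amat[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Amat[i][j] += Xe[a][i] * dNn[k][a][j];
      double detA = det3(Amat);
      if (detA <= 0) { bad = true; break; }
      double Ai[3][3];
      inv3(Amat, Ai, detA);
      double dNdX[8][3];
      for (int a = 0; a < 8; ++a)
        for (int kk = 0; kk < 3; ++kk) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += dNn[k][a][j] * Ai[j][kk];
          dNdX[a][kk] = s;
        }
      // deformation gradient
      double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int J = 0; J < 3; ++J) F[i][J] += ue[a][i] * dNdX[a][J];
      double J = det3(F);
      if (J <= 0) { bad = true; break; }
      if (J < minJ) minJ = J;
      double G[3][3];
      inv3(F, G, J); // G = F^{-1}
      double P[3][3];
      double wv = w * detA;
      double I1 = 0;
      for (int i = 0; i < 3; ++i)
        for (int a = 0; a < 3; ++a) I1 += F[i][a] * F[i][a];
      double cJ = std::pow(J, -2.0 / 3.0);
      if (!volpt) {
        energy += wv * 0.5 * mu[e] * (cJ * I1 - 3.0);
        iso_stress(F, G, J, mu[e], I1, P);
      } else {
        energy += wv * 0.5 * Kb[e] * (J - 1.0) * (J - 1.0);
        double s = Kb[e] * (J - 1.0) * J;
        for (int i = 0; i < 3; ++i)
          for (int a = 0; a < 3; ++a) P[i][a] = s * G[a][i];
      }
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int Jd = 0; Jd < 3; ++Jd) s += P[i][Jd] * dNdX[a][Jd];
          fe[a][i] += wv * s;
        }
      if (want_tangent) {
        // rank-structured contraction: per node a, pa = F ga, qa = F^{-T} ga
        double pa[8][3], qa[8][3];
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            double sp = 0, sq = 0;
            for (int A2 = 0; A2 < 3; ++A2) {
              sp += F[i][A2] * dNdX[a][A2];
              sq += G[A2][i] * dNdX[a][A2];
            }
            pa[a][i] = sp;
            qa[a][i] = sq;
          }
        if (!volpt) {
          double mc = wv * mu[e] * cJ;
          double c2 = 2.0 / 3.0, c3 = (2.0 / 9.0) * I1, c4 = I1 / 3.0;
          for (int a = 0; a < 8; ++a)
            for (int b = a; b < 8; ++b) {
              double gg = dNdX[a][0] * dNdX[b][0] + dNdX[a][1] * dNdX[b][1] +
                          dNdX[a][2] * dNdX[b][2];
              for (int i = 0; i < 3; ++i)
                for (int j = 0; j < 3; ++j) {
                  double v = mc * (((i == j) ? gg : 0.0)
                                   - c2 * (pa[a][i] * qa[b][j] + qa[a][i] * pa[b][j])
                                   + c3 * qa[a][i] * qa[b][j]
                                   + c4 * qa[b][i] * qa[a][j]);
                  Ke[3 * a + i][3 * b + j] += v;
                  if (b > a) Ke[3 * b + j][3 * a + i] += v;
                }
            }
        } else {
          double c1 = wv * Kb[e] * (2.0 * J - 1.0) * J;
          double c2 = wv * Kb[e] * (J - 1.0) * J;
          for (int a = 0; a < 8; ++a)
            for (int b = a; b < 8; ++b)
              for (int i = 0; i < 3; ++i)
                for (int j = 0; j < 3; ++j) {
                  double v = c1 * qa[a][i] * qa[b][j] - c2 * qa[b][i] * qa[a][j];
                  Ke[3 * a + i][3 * b + j] += v;
                  if (b > a) Ke[3 * b + j][3 * a + i] += v;
                }
        }
      }
    }
    if (bad) break;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) grad[3 * nid[a] + i] += fe[a][i];
    if (want_tangent) {
      for (int q = 0; q < 8; ++q) {
        int cn = nid[q];
        long long base = 9LL * nodeptr[cn];
        int dg = degc[cn];
        for (int p = 0; p < 8; ++p) {
          int r = rank(e, q * 8 + p);
          for (int c = 0; c < 3; ++c) {
            long long colbase = base + (long long)c * 3 * dg + 3 * r;
            for (int rr = 0; rr < 3; ++rr)
              xv[colbase + rr] += Ke[3 * p + rr][3 * q + c];
          }
        }
      }
    }
  }
  if (bad) energy = R_PosInf;
  return List::create(_["energy"] = energy, _["grad"] = grad,
                      _["xv"] = xv, _["bad"] = bad, _["minJ"] = minJ);
}

// Preconditioned conjugate gradient for the reduced tangent system.
// A is a full-pattern symmetric sparse matrix in CSC (i 0-based, p, x);
// preconditioner: SSOR (omega = 1 -> symmetric Gauss-Seidel),
//   M = w/(2-w) (D/w + L) D^{-1} (D/w + L)^T.
// Truncates on non-positive curvature (the partial iterate is still a
// descent direction for the Newton line search). Returns x, iterations,
// relative residual and a curvature flag.
// [[Rcpp::export]]
List fem_pcg(IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
             NumericVector b, double tol, int maxit, double omega) {
  int n = b.size();
  std::vector<double> diag(n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) diag[j] = Ax[k];
  const double wfac = (2.0 - omega) / omega;

  std::vector<double> x(n, 0.0), r(b.begin(), b.end()), z(n), p(n), Apv(n), t(n);
  auto matvec = [&](const std::vector<double> &v, std::vector<double> &out) {
    std::fill(out.begin(), out.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double vj = v[j];
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) out[Ai[k]] += Ax[k] * vj;
    }
  };
  auto precond = [&](const std::vector<double> &rin, std::vector<double> &zout) {
    // forward: (D/w + L) t = r   (L strict lower, column-oriented)
    std::copy(rin.begin(), rin.end(), t.begin());
    for (int j = 0; j < n; ++j) {
      double tj = t[j] / (diag[j] / omega);
      t[j] = tj;
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
        int i = Ai[k];
        if (i > j) t[i] -= Ax[k] * tj;
      }
    }
    // scale by D
    for (int j = 0; j < n; ++j) t[j] *= diag[j];
    // backward: (D/w + U) z = t, U = L^T; row-oriented via symmetric columns
    for (int j = n - 1; j >= 0; --j) {
      double s = t[j];
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
        int i = Ai[k];
        if (i > j) s -= Ax[k] * zout[i];   // A[i][j] = A[j][i] (upper row j)
      }
      zout[j] = s / (diag[j] / omega);
    }
    for (int j = 0; j < n; ++j) zout[j] *= wfac;
  };

  double bn = 0;
  for (int j = 0; j < n; ++j) bn += b[j] * b[j];
  bn = std::sqrt(bn);
  if (bn == 0)
    return List::create(_["x"] = NumericVector(n), _["iters"] = 0,
                        _["relres"] = 0.0, _["curvature_fail"] = false);
  precond(r, z);
  std::copy(z.begin(), z.end(), p.begin());
  double rz = 0;
  for (int j = 0; j < n; ++j) rz += r[j] * z[j];
  bool curv = false;
  int it = 0;
  double relres = 1.0;
  for (it = 1; it <= maxit; ++it) {
    matvec(p, Apv);
    double pAp = 0;
    for (int j = 0; j < n; ++j) pAp += p[j] * Apv[j];
    if (pAp <= 0) { curv = true; break; }
    double alpha = rz / pAp;
    double rn = 0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p[j];
      r[j] -= alpha * Apv[j];
      rn += r[j] * r[j];
    }
    relres = std::sqrt(rn) / bn;
    if (relres <= tol) break;
    precond(r, z);
    double rz_new = 0;
    for (int j = 0; j < n; ++j) rz_new += r[j] * z[j];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iters"] = it, _["relres"] = relres,
                      _["curvature_fail"] = curv);
}

// Sparse matrix-vector product for the full-pattern symmetric CSC tangent.
// [[Rcpp::export]]
NumericVector fem_spmv(IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                       NumericVector x) {
  int n = Ap.size() - 1;
  NumericVector y(n);
  for (int j = 0; j < n; ++j) {
    double xj = x[j];
    if (xj == 0) continue;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) y[Ai[k]] += Ax[k] * xj;
  }
  return y;
}

// Forward Gauss-Seidel solve (D + L) z = r on the full symmetric CSC matrix.
// [[Rcpp::export]]
NumericVector fem_gs_forward(IntegerVector Ai, IntegerVector Ap,
                             NumericVector Ax, NumericVector r) {
  int n = Ap.size() - 1;
  NumericVector z(n);
  std::vector<double> t(r.begin(), r.end());
  std::vector<double> diag(n, 1.0);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) diag[j] = Ax[k];
  for (int j = 0; j < n; ++j) {
    double zj = t[j] / diag[j];
    z[j] = zj;
    if (zj != 0)
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
        int i = Ai[k];
        if (i > j) t[i] -= Ax[k] * zj;
      }
  }
  return z;
}

// Backward Gauss-Seidel solve (D + U) z = r, U = L^T by symmetry.
// [[Rcpp::export]]
NumericVector fem_gs_backward(IntegerVector Ai, IntegerVector Ap,
                              NumericVector Ax, NumericVector r) {
  int n = Ap.size() - 1;
  NumericVector z(n);
  std::vector<double> diag(n, 1.0);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) diag[j] = Ax[k];
  for (int j = n - 1; j >= 0; --j) {
    double s = r[j];
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
      int i = Ai[k];
      if (i > j) s -= Ax[k] * z[i];   // A[j][i] of the upper row j
    }
    z[j] = s / diag[j];
  }
  return z;
}

// Impose homogeneous Dirichlet conditions on the assembled tangent in place:
// rows/columns of fixed dofs are zeroed and their diagonal set to the mean
// diagonal scale (keeps the preconditioner well scaled).
// [[Rcpp::export]]
void fem_apply_bc(IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                  LogicalVector fixed) {
  int n = Ap.size() - 1;
  double dsum = 0;
  int dcnt = 0;
  for (int j = 0; j < n; ++j)
    if (!fixed[j])
      for (int k = Ap[j]; k < Ap[j + 1]; ++k)
        if (Ai[k] == j) { dsum += Ax[k]; ++dcnt; }
  double dscale = dcnt ? dsum / dcnt : 1.0;
  for (int j = 0; j < n; ++j) {
    bool fj = fixed[j];
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
      int i = Ai[k];
      if (fj || fixed[i]) Ax[k] = (i == j) ? dscale : 0.0;
    }
  }
}

// Consistent nodal body force: f[3*(a-1)+i] = sum_e sum_gp w detJ N_a bf(e,i)
// (force per unit reference volume, constant per element).
// [[Rcpp::export]]
NumericVector fem_body_force(NumericMatrix nodes, IntegerMatrix elems,
                             NumericMatrix bf) {
  int M = elems.nrow(), N = nodes.nrow();
  NumericVector f(3 * N);
  double dNn[8][8][3], Nn[8][8];
  for (int k = 0; k < 8; ++k)
    shape_grad_nat(GP * XN[k], GP * YN[k], GP * ZN[k], dNn[k], Nn[k]);
  for (int e = 0; e < M; ++e) {
    double Xe[8][3];
    int nid[8];
    for (int a = 0; a < 8; ++a) {
      nid[a] = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) Xe[a][i] = nodes(nid[a], i);
    }
    for (int k = 0; k < 8; ++k) {
      double Amat[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Amat[i][j] += Xe[a][i] * dNn[k][a][j];
      double detA = det3(Amat);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          f[3 * nid[a] + i] += detA * Nn[k][a] * bf(e, i);
    }
  }
  return f;
}

// Reference volume of every element (2x2x2 Gauss).
// [[Rcpp::export]]
NumericVector fem_element_volumes(NumericMatrix nodes, IntegerMatrix elems) {
  int M = elems.nrow();
  NumericVector vol(M);
  double dNn[8][8][3], Nn[8][8];
  for (int k = 0; k < 8; ++k)
    shape_grad_nat(GP * XN[k], GP * YN[k], GP * ZN[k], dNn[k], Nn[k]);
  for (int e = 0; e < M; ++e) {
    double Xe[8][3];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) Xe[a][i] = nodes(elems(e, a) - 1, i);
    double v = 0;
    for (int k = 0; k < 8; ++k) {
      double Amat[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Amat[i][j] += Xe[a][i] * dNn[k][a][j];
      v += det3(Amat);
    }
    vol[e] = v;
  }
  return vol;
}

// Minimum reference-configuration Jacobian over all integration points,
// per element (mesh quality check after skin extrusion).
// [[Rcpp::export]]
NumericVector fem_min_ref_jacobian(NumericMatrix nodes, IntegerMatrix elems) {
  int M = elems.nrow();
  NumericVector out(M);
  double gp[9][3];
  for (int k = 0; k < 8; ++k) {
    gp[k][0] = GP * XN[k]; gp[k][1] = GP * YN[k]; gp[k][2] = GP * ZN[k];
  }
  gp[8][0] = gp[8][1] = gp[8][2] = 0;
  double dNn[9][8][3], Nn[9][8];
  for (int k = 0; k < 9; ++k) shape_grad_nat(gp[k][0], gp[k][1], gp[k][2], dNn[k], Nn[k]);
  for (int e = 0; e < M; ++e) {
    double Xe[8][3];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) Xe[a][i] = nodes(elems(e, a) - 1, i);
    double mn = R_PosInf;
    for (int k = 0; k < 9; ++k) {
      double Amat[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Amat[i][j] += Xe[a][i] * dNn[k][a][j];
      double d = det3(Amat);
      if (d < mn) mn = d;
    }
    out[e] = mn;
  }
  return out;
}

// Per-integration-point J = det(F) for a converged displacement (8 full
// Gauss points + centre), returned as an M x 9 matrix.
// [[Rcpp::export]]
NumericMatrix fem_jacobians(NumericMatrix nodes, IntegerMatrix elems,
                            NumericVector u) {
  int M = elems.nrow();
  NumericMatrix out(M, 9);
  double gp[9][3];
  for (int k = 0; k < 8; ++k) {
    gp[k][0] = GP * XN[k]; gp[k][1] = GP * YN[k]; gp[k][2] = GP * ZN[k];
  }
  gp[8][0] = gp[8][1] = gp[8][2] = 0;
  double dNn[9][8][3], Nn[9][8];
  for (int k = 0; k < 9; ++k) shape_grad_nat(gp[k][0], gp[k][1], gp[k][2], dNn[k], Nn[k]);
  for (int e = 0; e < M; ++e) {
    double Xe[8][3], ue[8][3];
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = nodes(n, i);
        ue[a][i] = u[3 * n + i];
      }
    }
    for (int k = 0; k < 9; ++k) {
      double Amat[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Amat[i][j] += Xe[a][i] * dNn[k][a][j];
      double Ai[3][3];
      inv3(Amat, Ai, det3(Amat));
      double dNdX[8][3];
      for (int a = 0; a < 8; ++a)
        for (int kk = 0; kk < 3; ++kk) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += dNn[k][a][j] * Ai[j][kk];
          dNdX[a][kk] = s;
        }
      double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int J = 0; J < 3; ++J) F[i][J] += ue[a][i] * dNdX[a][J];
      out(e, k) = det3(F);
    }
  }
  return out;
}
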