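// Element-level kernels for static linear elasticity on TET4 / TET10 meshes.
// Units: mm (coordinates), MPa (moduli, stresses), N (forces).
// Voigt order used throughout: xx, yy, zz, xy, yz, xz with engineering shear.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void iso_dmatrix(double E, double nu, arma::mat &D) {
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu  = E / (2.0 * (1.0 + nu));
  D.zeros(6, 6);
  D(0, 0) = D(1, 1) = D(2, 2) = lam + 2.0 * mu;
  D(0, 1) = D(0, 2) = D(1, 2) = lam;
  D(1, 0) = D(2, 0) = D(2, 1) = lam;
  D(3, 3) = D(4, 4) = D(5, 5) = mu;
}

// Barycentric gradients c_k (rows) and 6*volume for a straight tetrahedron.
// Returns signed volume.
static double tet_geometry(const arma::mat &X, arma::mat &grad) {
  // X: 4 x 3 corner coordinates.  L_k(x) affine with grad L_k constant.
  arma::mat J(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int d = 0; d < 3; ++d)
      J(i, d) = X(i + 1, d) - X(0, d);
  const double detJ = arma::det(J);
  arma::mat Jinv = arma::inv(J);
  grad.set_size(4, 3);
  // grad of L2..L4 are rows of Jinv^T; grad L1 = -(sum of others)
  for (int k = 0; k < 3; ++k)
    for (int d = 0; d < 3; ++d)
      grad(k + 1, d) = Jinv(d, k);
  for (int d = 0; d < 3; ++d)
    grad(0, d) = -(grad(1, d) + grad(2, d) + grad(3, d));
  return detJ / 6.0;
}

// TET10 node numbering (VTK quadratic tetra):
// 0..3 corners, 4:(0,1) 5:(1,2) 6:(0,2) 7:(0,3) 8:(1,3) 9:(2,3)
static const int EDGE_A[6] = {0, 1, 0, 0, 1, 2};
static const int EDGE_B[6] = {1, 2, 2, 3, 3, 3};

// dN/dx for TET10 at barycentric point L (length 4), given constant grad L.
static void tet10_dndx(const double *L, const arma::mat &grad, arma::mat &dndx) {
  dndx.zeros(10, 3);
  for (int k = 0; k < 4; ++k)
    for (int d = 0; d < 3; ++d)
      dndx(k, d) = (4.0 * L[k] - 1.0) * grad(k, d);
  for (int e = 0; e < 6; ++e) {
    const int a = EDGE_A[e], b = EDGE_B[e];
    for (int d = 0; d < 3; ++d)
      dndx(4 + e, d) = 4.0 * (L[a] * grad(b, d) + L[b] * grad(a, d));
  }
}

static void fill_b(const arma::mat &dndx, arma::mat &B) {
  const int nn = dndx.n_rows;
  B.zeros(6, 3 * nn);
  for (int i = 0; i < nn; ++i) {
    const double dx = dndx(i, 0), dy = dndx(i, 1), dz = dndx(i, 2);
    B(0, 3 * i + 0) = dx;
    B(1, 3 * i + 1) = dy;
    B(2, 3 * i + 2) = dz;
    B(3, 3 * i + 0) = dy; B(3, 3 * i + 1) = dx;
    B(4, 3 * i + 1) = dz; B(4, 3 * i + 2) = dy;
    B(5, 3 * i + 0) = dz; B(5, 3 * i + 2) = dx;
  }
}

// 4-point degree-2 quadrature on the reference tetrahedron (weights sum to 1).
static const double QA = 0.5854101966249685;
static const double QB = 0.1381966011250105;

// Emits only the lower triangle (i >= j) of the symmetric stiffness, for
// use with Matrix::sparseMatrix(symmetric = TRUE).
// [[Rcpp::export]]
List fem_assemble_triplets(const NumericMatrix &nodes, const IntegerMatrix &elems,
                           const NumericVector &Evec, const NumericVector &nuvec) {
  const int m = elems.nrow();
  const int nn = elems.ncol();            // 4 or 10
  if (nn != 4 && nn != 10) stop("elements must have 4 or 10 nodes");
  const int nd = 3 * nn;
  const R_xlen_t total = (R_xlen_t)m * nd * (nd + 1) / 2;
  IntegerVector ti(total), tj(total);
  NumericVector tx(total);

  arma::mat X(4, 3), grad, D(6, 6), B, Ke, dndx;
  R_xlen_t pos = 0;
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d)
        X(i, d) = nodes(elems(e, i) - 1, d);
    const double V = tet_geometry(X, grad);
    if (V <= 0) stop("element %d has non-positive volume", e + 1);
    iso_dmatrix(Evec[e], nuvec[e], D);
    if (nn == 4) {
      fill_b(grad, B);
      Ke = V * (B.t() * D * B);
    } else {
      Ke.zeros(nd, nd);
      double L[4];
      for (int q = 0; q < 4; ++q) {
        for (int k = 0; k < 4; ++k) L[k] = (k == q) ? QA : QB;
        tet10_dndx(L, grad, dndx);
        fill_b(dndx, B);
        Ke += (0.25 * V) * (B.t() * D * B);
      }
    }
    for (int a = 0; a < nn; ++a) {
      const int ga = elems(e, a);
      for (int b = 0; b < nn; ++b) {
        const int gb = elems(e, b);
        for (int da = 0; da < 3; ++da) {
          const int gi = 3 * (ga - 1) + da + 1;
          for (int db = 0; db < 3; ++db) {
            const int gj = 3 * (gb - 1) + db + 1;
            if (gi < gj) continue;
            ti[pos] = gi;
            tj[pos] = gj;
            tx[pos] = Ke(3 * a + da, 3 * b + db);
            ++pos;
          }
        }
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Element stress at the centroid from nodal displacements u (length 3*nnodes).
// [[Rcpp::export]]
NumericMatrix fem_element_stress(const NumericMatrix &nodes, const IntegerMatrix &elems,
                                 const NumericVector &u,
                                 const NumericVector &Evec, const NumericVector &nuvec) {
  const int m = elems.nrow();
  const int nn = elems.ncol();
  NumericMatrix out(m, 6);
  arma::mat X(4, 3), grad, D(6, 6), B, dndx;
  arma::vec ue(3 * nn), eps, sig;
  const double Lc[4] = {0.25, 0.25, 0.25, 0.25};
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d)
        X(i, d) = nodes(elems(e, i) - 1, d);
    tet_geometry(X, grad);
    if (nn == 4) {
      fill_b(grad, B);
    } else {
      tet10_dndx(Lc, grad, dndx);
      fill_b(dndx, B);
    }
    for (int i = 0; i < nn; ++i)
      for (int d = 0; d < 3; ++d)
        ue(3 * i + d) = u[3 * (elems(e, i) - 1) + d];
    iso_dmatrix(Evec[e], nuvec[e], D);
    eps = B * ue;
    sig = D * eps;
    for (int c = 0; c < 6; ++c) out(e, c) = sig(c);
  }
  return out;
}

// Signed 6*volume (Jacobian determinant) per element, from corner nodes.
// [[Rcpp::export]]
NumericVector fem_tet_volumes(const NumericMatrix &nodes, const IntegerMatrix &elems) {
  const int m = elems.nrow();
  NumericVector out(m);
  arma::mat X(4, 3), grad;
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d)
        X(i, d) = nodes(elems(e, i) - 1, d);
    out[e] = tet_geometry(X, grad);
  }
  return out;
}
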