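// Finite-strain hexahedral element kernels: compressible neo-Hookean
// material with F-bar volumetric treatment (centroid sampling) against
// locking at nearly incompressible Poisson ratios.
//
// Strain energy:  Psi = mu/2 (tr C - 3) - mu ln J + lambda/2 (ln J)^2
// Cauchy stress:  sigma = mu/J (B - I) + lambda ln(J)/J I
// Spatial tangent: c_ijkl = lam' d_ij d_kl + mu'' (d_ik d_jl + d_il d_jk),
//                  lam' = lambda/J, mu'' = (mu - lambda ln J)/J,
// evaluated at the F-bar modified deformation.  Residual and tangent use
// the standard spatial B operator (de Souza Neto F-bar, with the nonlocal
// tangent contribution dropped: approximate but symmetric Newton).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double GP = 0.5773502691896257; // 1/sqrt(3)

// corner signs of the standard trilinear hex ordering
const int SGN[8][3] = {{-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
                       {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};

inline void shape_grad(double xi, double eta, double zeta, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    const double sx = SGN[a][0], sy = SGN[a][1], sz = SGN[a][2];
    dN[a][0] = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta);
    dN[a][1] = 0.125 * (1 + sx * xi) * sy * (1 + sz * zeta);
    dN[a][2] = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz;
  }
}

inline double det3(const double M[3][3]) {
  return M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
         M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
         M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
}

inline bool inv3(const double M[3][3], double Mi[3][3], double &det) {
  det = det3(M);
  if (det == 0.0 || !std::isfinite(det)) return false;
  const double id = 1.0 / det;
  Mi[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) * id;
  Mi[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) * id;
  Mi[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) * id;
  Mi[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) * id;
  Mi[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) * id;
  Mi[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) * id;
  Mi[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) * id;
  Mi[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) * id;
  Mi[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) * id;
  return true;
}

// deformation data at one quadrature point of one element
struct QPData {
  double dNdX[8][3]; // reference shape gradients
  double detJxi;     // reference Jacobian determinant
  double F[3][3];    // deformation gradient
  double J;          // det F
};

inline bool qp_kinematics(const double Xe[8][3], const double ue[8][3],
                          double xi, double eta, double zeta, QPData &q) {
  double dN[8][3];
  shape_grad(xi, eta, zeta, dN);
  double Jx[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int a = 0; a < 8; ++a)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k) Jx[j][k] += Xe[a][j] * dN[a][k];
  double Jinv[3][3], dj;
  if (!inv3(Jx, Jinv, dj) || dj <= 0) return false;
  q.detJxi = dj;
  for (int a = 0; a < 8; ++a)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += dN[a][k] * Jinv[k][j];
      q.dNdX[a][j] = s;
    }
  for (int i = 0; i < 3; ++i)
    for (int J = 0; J < 3; ++J) {
      double s = (i == J) ? 1.0 : 0.0;
      for (int a = 0; a < 8; ++a) s += ue[a][i] * q.dNdX[a][J];
      q.F[i][J] = s;
    }
  q.J = det3(q.F);
  return std::isfinite(q.J);
}

} // namespace

// [[Rcpp::export]]
List fem_assemble(NumericMatrix coords, IntegerMatrix conn, NumericMatrix u,
                  double mu, double lambda, bool fbar = true,
                  bool want_tangent = true, bool want_indices = true) {
  const int nel = conn.nrow();
  const int nn = coords.nrow();
  NumericVector fint(3 * nn);
  IntegerVector Ki, Kj;
  NumericVector Kx;
  if (want_tangent) {
    if (want_indices) {
      Ki = IntegerVector(nel * 576);
      Kj = IntegerVector(nel * 576);
    }
    Kx = NumericVector(nel * 576);
  }
  double energy = 0.0;
  int bad_element = -1;

  for (int e = 0; e < nel; ++e) {
    double Xe[8][3], ue[8][3];
    int ids[8];
    for (int a = 0; a < 8; ++a) {
      ids[a] = conn(e, a);
      for (int j = 0; j < 3; ++j) {
        Xe[a][j] = coords(ids[a], j);
        ue[a][j] = u(ids[a], j);
      }
    }
    QPData qc;
    double Jc = 1.0;
    double dNdx0[8][3] = {{0}};
    if (fbar) {
      if (!qp_kinematics(Xe, ue, 0, 0, 0, qc) || qc.J <= 0) {
        bad_element = e;
        break;
      }
      Jc = qc.J;
      // centroid spatial gradients: the volumetric stiffness of the F-bar
      // element acts through the centroid divergence
      double Finv0[3][3], d0;
      inv3(qc.F, Finv0, d0);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int J = 0; J < 3; ++J) s += qc.dNdX[a][J] * Finv0[J][i];
          dNdx0[a][i] = s;
        }
    }
    double fe[8][3] = {{0}};
    double ke[24][24] = {{0}};
    bool ok = true;
    for (int qa = 0; qa < 2 && ok; ++qa)
      for (int qb = 0; qb < 2 && ok; ++qb)
        for (int qc2 = 0; qc2 < 2 && ok; ++qc2) {
          QPData q;
          if (!qp_kinematics(Xe, ue, (2 * qa - 1) * GP, (2 * qb - 1) * GP,
                             (2 * qc2 - 1) * GP, q) ||
              q.J <= 0) {
            ok = false;
            break;
          }
          const double Jb = fbar ? Jc : q.J;
          const double scale = fbar ? std::cbrt(Jc / q.J) : 1.0;
          double Fb[3][3];
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) Fb[i][j] = scale * q.F[i][j];
          const double lnJ = std::log(Jb);
          // Cauchy stress from F-bar
          double sig[3][3];
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) {
              double B = 0;
              for (int k = 0; k < 3; ++k) B += Fb[i][k] * Fb[j][k];
              sig[i][j] = mu / Jb * (B - (i == j ? 1.0 : 0.0)) +
                          (i == j ? lambda * lnJ / Jb : 0.0);
            }
          // spatial shape gradients via the actual F
          double Finv[3][3], dF;
          inv3(q.F, Finv, dF);
          double dNdx[8][3];
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i) {
              double s = 0;
              for (int J = 0; J < 3; ++J) s += q.dNdX[a][J] * Finv[J][i];
              dNdx[a][i] = s;
            }
          const double w = q.detJxi * q.J; // deformed volume weight
          // strain energy (reference volume)
          {
            double trC = 0;
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) trC += Fb[i][j] * Fb[i][j];
            energy += q.detJxi *
                      (0.5 * mu * (trC - 3.0) - mu * lnJ +
                       0.5 * lambda * lnJ * lnJ);
          }
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i) {
              double s = 0;
              for (int j = 0; j < 3; ++j) s += sig[i][j] * dNdx[a][j];
              fe[a][i] += w * s;
            }
          if (want_tangent) {
            const double lamp = lambda / Jb;
            const double mupp = (mu - lambda * lnJ) / Jb;
            // with F-bar, the volumetric (lambda) stiffness couples the
            // centroid divergences; without it, the quadrature-point ones
            const double (*dNv)[3] = fbar ? dNdx0 : dNdx;
            for (int a = 0; a < 8; ++a)
              for (int b = 0; b < 8; ++b) {
                double gab = 0; // dNa . dNb
                for (int j = 0; j < 3; ++j) gab += dNdx[a][j] * dNdx[b][j];
                double geo = 0; // dNa . sigma . dNb
                for (int j = 0; j < 3; ++j)
                  for (int l = 0; l < 3; ++l)
                    geo += dNdx[a][j] * sig[j][l] * dNdx[b][l];
                for (int i = 0; i < 3; ++i)
                  for (int k = 0; k < 3; ++k) {
                    double v = lamp * dNv[a][i] * dNv[b][k] +
                               mupp * dNdx[a][k] * dNdx[b][i];
                    if (i == k) v += mupp * gab + geo;
                    ke[3 * a + i][3 * b + k] += w * v;
                  }
              }
          }
        }
    if (!ok) {
      bad_element = e;
      break;
    }
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) fint[3 * ids[a] + i] += fe[a][i];
    if (want_tangent) {
      R_xlen_t base = (R_xlen_t)e * 576;
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 8; ++b)
            for (int k = 0; k < 3; ++k) {
              const R_xlen_t p =
                  base + ((3 * a + i) * 24 + 3 * b + k);
              if (want_indices) {
                Ki[p] = 3 * ids[a] + i + 1;
                Kj[p] = 3 * ids[b] + k + 1;
              }
              Kx[p] = ke[3 * a + i][3 * b + k];
            }
    }
  }
  if (bad_element >= 0)
    return List::create(Named("ok") = false,
                        Named("bad_element") = bad_element + 1);
  List out = List::create(Named("ok") = true, Named("f") = fint,
                          Named("energy") = energy);
  if (want_tangent) {
    if (want_indices) {
      out["Ki"] = Ki;
      out["Kj"] = Kj;
    }
    out["Kx"] = Kx;
  }
  return out;
}

// Per-quadrature-point Cauchy stress, deformed position, J and energy
// density for a converged displacement state.
// [[Rcpp::export]]
List fem_qp_stress(NumericMatrix coords, IntegerMatrix conn, NumericMatrix u,
                   double mu, double lambda, bool fbar = true) {
  const int nel = conn.nrow();
  NumericMatrix sig_out(nel * 8, 6); // xx yy zz xy xz yz
  NumericMatrix xqp(nel * 8, 3);
  NumericVector Jout(nel * 8), psi(nel * 8);
  for (int e = 0; e < nel; ++e) {
    double Xe[8][3], ue[8][3];
    int ids[8];
    for (int a = 0; a < 8; ++a) {
      ids[a] = conn(e, a);
      for (int j = 0; j < 3; ++j) {
        Xe[a][j] = coords(ids[a], j);
        ue[a][j] = u(ids[a], j);
      }
    }
    QPData qc;
    double Jc = 1.0;
    if (fbar) {
      if (!qp_kinematics(Xe, ue, 0, 0, 0, qc) || qc.J <= 0)
        stop("inverted element %d in stress recovery", e + 1);
      Jc = qc.J;
    }
    int qi = 0;
    for (int qc2 = 0; qc2 < 2; ++qc2)
      for (int qb = 0; qb < 2; ++qb)
        for (int qa = 0; qa < 2; ++qa) {
          const double xi = (2 * qa - 1) * GP, eta = (2 * qb - 1) * GP,
                       zeta = (2 * qc2 - 1) * GP;
          QPData q;
          if (!qp_kinematics(Xe, ue, xi, eta, zeta, q) || q.J <= 0)
            stop("inverted element %d in stress recovery", e + 1);
          const double Jb = fbar ? Jc : q.J;
          const double scale = fbar ? std::cbrt(Jc / q.J) : 1.0;
          double Fb[3][3];
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) Fb[i][j] = scale * q.F[i][j];
          const double lnJ = std::log(Jb);
          double sig[3][3];
          double trC = 0;
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) {
              double B = 0;
              for (int k = 0; k < 3; ++k) B += Fb[i][k] * Fb[j][k];
              sig[i][j] = mu / Jb * (B - (i == j ? 1.0 : 0.0)) +
                          (i == j ? lambda * lnJ / Jb : 0.0);
              trC += Fb[i][j] * Fb[i][j];
            }
          const int row = e * 8 + qi;
          sig_out(row, 0) = sig[0][0];
          sig_out(row, 1) = sig[1][1];
          sig_out(row, 2) = sig[2][2];
          sig_out(row, 3) = sig[0][1];
          sig_out(row, 4) = sig[0][2];
          sig_out(row, 5) = sig[1][2];
          // deformed position of the quadrature point
          for (int j = 0; j < 3; ++j) {
            double s = 0;
            for (int a = 0; a < 8; ++a) {
              const double sx = SGN[a][0], sy = SGN[a][1], sz = SGN[a][2];
              const double N = 0.125 * (1 + sx * xi) * (1 + sy * eta) *
                               (1 + sz * zeta);
              s += N * (Xe[a][j] + ue[a][j]);
            }
            xqp(row, j) = s;
          }
          Jout[row] = q.J;
          psi[row] = 0.5 * mu * (trC - 3.0) - mu * lnJ +
                     0.5 * lambda * lnJ * lnJ;
          ++qi;
        }
  }
  return List::create(Named("sigma") = sig_out, Named("x") = xqp,
                      Named("J") = Jout, Named("psi") = psi);
}

// Minimum corner Jacobian of each element (mesh validity check).
// [[Rcpp::export]]
NumericVector fem_min_jacobians(NumericMatrix coords, IntegerMatrix conn) {
  const int nel = conn.nrow();
  NumericVector out(nel);
  for (int e = 0; e < nel; ++e) {
    double Xe[8][3], ue[8][3] = {{0}};
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j) Xe[a][j] = coords(conn(e, a), j);
    double jmin = R_PosInf;
    for (int a = 0; a < 8; ++a) {
      QPData q;
      if (!qp_kinematics(Xe, ue, SGN[a][0] * 0.999, SGN[a][1] * 0.999,
                         SGN[a][2] * 0.999, q)) {
        jmin = -1;
        break;
      }
      jmin = std::min(jmin, q.detJxi);
    }
    out[e] = jmin;
  }
  return out;
}
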