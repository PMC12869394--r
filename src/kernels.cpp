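// Element kernels for the immersed FSI solver: VMS-stabilized incompressible
// Navier-Stokes residual/Jacobian, immersed hyperelastic solid residual and
// consistent tangent (reference-configuration pull-back of the current-
// configuration integrals), bounding-box-grid point location with Newton
// inversion of the isoparametric map, and interface-band marking.
//
// Local DOF convention: velocity dof of (node A, component i) is dim*A + i
// (0-based); global pressure dofs are offset by dim*nnode at the R level.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int Q_QUAD4 = 0, Q_HEX8 = 1, Q_TRI3 = 2, Q_TET4 = 3;

static int type_id(const std::string& t) {
  if (t == "quad4") return Q_QUAD4;
  if (t == "hex8") return Q_HEX8;
  if (t == "tri3") return Q_TRI3;
  if (t == "tet4") return Q_TET4;
  stop("unsupported element type: %s", t);
}
static int type_dim(int tid) { return (tid == Q_QUAD4 || tid == Q_TRI3) ? 2 : 3; }
static int type_nen(int tid) {
  switch (tid) { case Q_QUAD4: return 4; case Q_HEX8: return 8;
                 case Q_TRI3: return 3; default: return 4; }
}

// shape values and parametric gradients
static void shape(int tid, const double* xi, double* N, double dN[8][3]) {
  switch (tid) {
  case Q_QUAD4: {
    const double sx[4] = {-1, 1, 1, -1}, sy[4] = {-1, -1, 1, 1};
    for (int a = 0; a < 4; ++a) {
      N[a] = 0.25 * (1 + sx[a] * xi[0]) * (1 + sy[a] * xi[1]);
      dN[a][0] = 0.25 * sx[a] * (1 + sy[a] * xi[1]);
      dN[a][1] = 0.25 * (1 + sx[a] * xi[0]) * sy[a];
    }
    break; }
  case Q_HEX8: {
    const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1},
                 sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1},
                 sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
    for (int a = 0; a < 8; ++a) {
      double A = 1 + sx[a] * xi[0], B = 1 + sy[a] * xi[1], C = 1 + sz[a] * xi[2];
      N[a] = 0.125 * A * B * C;
      dN[a][0] = 0.125 * sx[a] * B * C;
      dN[a][1] = 0.125 * A * sy[a] * C;
      dN[a][2] = 0.125 * A * B * sz[a];
    }
    break; }
  case Q_TRI3: {
    N[0] = 1 - xi[0] - xi[1]; N[1] = xi[0]; N[2] = xi[1];
    dN[0][0] = -1; dN[0][1] = -1; dN[1][0] = 1; dN[1][1] = 0;
    dN[2][0] = 0; dN[2][1] = 1;
    break; }
  default: {
    N[0] = 1 - xi[0] - xi[1] - xi[2]; N[1] = xi[0]; N[2] = xi[1]; N[3] = xi[2];
    for (int j = 0; j < 3; ++j) { dN[0][j] = -1; }
    dN[1][0] = 1; dN[1][1] = 0; dN[1][2] = 0;
    dN[2][0] = 0; dN[2][1] = 1; dN[2][2] = 0;
    dN[3][0] = 0; dN[3][1] = 0; dN[3][2] = 1;
    break; }
  }
}

// quadrature: 2-pt Gauss per axis for tensor elements, symmetric simplex rules
static int quad_rule(int tid, double qp[8][3], double* qw) {
  const double g = 1.0 / std::sqrt(3.0);
  switch (tid) {
  case Q_QUAD4: {
    const double s[2] = {-g, g}; int n = 0;
    for (int j = 0; j < 2; ++j) for (int i = 0; i < 2; ++i) {
      qp[n][0] = s[i]; qp[n][1] = s[j]; qp[n][2] = 0; qw[n++] = 1.0;
    }
    return 4; }
  case Q_HEX8: {
    const double s[2] = {-g, g}; int n = 0;
    for (int k = 0; k < 2; ++k) for (int j = 0; j < 2; ++j) for (int i = 0; i < 2; ++i) {
      qp[n][0] = s[i]; qp[n][1] = s[j]; qp[n][2] = s[k]; qw[n++] = 1.0;
    }
    return 8; }
  case Q_TRI3: {
    const double a = 1.0 / 6.0, b = 2.0 / 3.0;
    double pts[3][2] = {{a, a}, {b, a}, {a, b}};
    for (int n = 0; n < 3; ++n) {
      qp[n][0] = pts[n][0]; qp[n][1] = pts[n][1]; qp[n][2] = 0; qw[n] = a;
    }
    return 3; }
  default: {
    const double a = (5.0 - std::sqrt(5.0)) / 20.0, b = (5.0 + 3.0 * std::sqrt(5.0)) / 20.0;
    double pts[4][3] = {{a, a, a}, {b, a, a}, {a, b, a}, {a, a, b}};
    for (int n = 0; n < 4; ++n) {
      qp[n][0] = pts[n][0]; qp[n][1] = pts[n][1]; qp[n][2] = pts[n][2];
      qw[n] = 1.0 / 24.0;
    }
    return 4; }
  }
}

static inline double det_small(const double J[3][3], int d) {
  if (d == 2) return J[0][0] * J[1][1] - J[0][1] * J[1][0];
  return J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
       - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
       + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
}
static inline void inv_small(const double J[3][3], double Ji[3][3], int d, double detJ) {
  if (d == 2) {
    Ji[0][0] = J[1][1] / detJ;  Ji[0][1] = -J[0][1] / detJ;
    Ji[1][0] = -J[1][0] / detJ; Ji[1][1] = J[0][0] / detJ;
  } else {
    Ji[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) / detJ;
    Ji[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) / detJ;
    Ji[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) / detJ;
    Ji[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) / detJ;
    Ji[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) / detJ;
    Ji[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) / detJ;
    Ji[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) / detJ;
    Ji[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) / detJ;
    Ji[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) / detJ;
  }
}

// ---------------------------------------------------------------------------
// VMS fluid assembly
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_assemble_fluid(const arma::mat& nodes, const arma::imat& elem,
                        std::string elem_type,
                        const arma::mat& v, const arma::mat& a,
                        const arma::vec& p, const arma::vec& sfield,
                        const arma::mat& fnod,
                        double rho, double mu, double dt,
                        double CI, double CT,
                        double cv, double ca, double cp,
                        bool want_jac) {
  const int tid = type_id(elem_type);
  const int d = type_dim(tid), nen = type_nen(tid);
  const int nel = elem.n_rows, nn = nodes.n_rows;
  const int nle = nen * (d + 1);           // local dofs: velocities then pressures

  double qp[8][3], qw[8];
  const int nqp = quad_rule(tid, qp, qw);
  // precompute shape values at qps
  double Nq[8][8], dNq[8][8][3];
  for (int q = 0; q < nqp; ++q) {
    double dN[8][3];
    shape(tid, qp[q], Nq[q], dN);
    for (int A = 0; A < nen; ++A) for (int j = 0; j < d; ++j) dNq[q][A][j] = dN[A][j];
  }

  arma::vec Rm(d * nn, arma::fill::zeros), Rc(nn, arma::fill::zeros);
  std::vector<int> Ti, Tj; std::vector<double> Tx;
  if (want_jac) { Ti.reserve((size_t)nel * nle * nle); Tj.reserve((size_t)nel * nle * nle); Tx.reserve((size_t)nel * nle * nle); }

  std::vector<double> Ke(nle * nle), Re(nle);

  for (int e = 0; e < nel; ++e) {
    int conn[8];
    for (int A = 0; A < nen; ++A) conn[A] = elem(e, A);
    double X[8][3], ve[8][3], ae[8][3], fe[8][3], pe[8], se[8];
    for (int A = 0; A < nen; ++A) {
      for (int j = 0; j < d; ++j) {
        X[A][j] = nodes(conn[A], j);
        ve[A][j] = v(conn[A], j);
        ae[A][j] = a(conn[A], j);
        fe[A][j] = fnod(conn[A], j);
      }
      pe[A] = p(conn[A]); se[A] = sfield(conn[A]);
    }
    std::fill(Ke.begin(), Ke.end(), 0.0);
    std::fill(Re.begin(), Re.end(), 0.0);

    for (int q = 0; q < nqp; ++q) {
      const double* N = Nq[q];
      double J[3][3] = {{0}}, Ji[3][3];
      for (int A = 0; A < nen; ++A)
        for (int i = 0; i < d; ++i) for (int j = 0; j < d; ++j)
          J[i][j] += X[A][i] * dNq[q][A][j];
      double detJ = det_small(J, d);
      if (detJ <= 0) stop("assembly error: non-positive Jacobian in fluid element %d", e + 1);
      inv_small(J, Ji, d, detJ);
      double dNdx[8][3];
      for (int A = 0; A < nen; ++A)
        for (int j = 0; j < d; ++j) {
          double s = 0;
          for (int k = 0; k < d; ++k) s += dNq[q][A][k] * Ji[k][j];
          dNdx[A][j] = s;
        }
      // metric tensor G = Ji^T Ji
      double G[3][3] = {{0}}, trG = 0, GG = 0;
      for (int i = 0; i < d; ++i) for (int j = 0; j < d; ++j) {
        double s = 0;
        for (int k = 0; k < d; ++k) s += Ji[k][i] * Ji[k][j];
        G[i][j] = s; GG += s * s;
      }
      for (int i = 0; i < d; ++i) trG += G[i][i];

      double vq[3] = {0, 0, 0}, aq[3] = {0, 0, 0}, gp[3] = {0, 0, 0};
      double f[3] = {0, 0, 0};
      double gv[3][3] = {{0}};
      double pq = 0, sq = 0;
      for (int A = 0; A < nen; ++A) {
        pq += N[A] * pe[A]; sq += N[A] * se[A];
        for (int i = 0; i < d; ++i) {
          vq[i] += N[A] * ve[A][i];
          aq[i] += N[A] * ae[A][i];
          f[i] += N[A] * fe[A][i];
          gp[i] += dNdx[A][i] * pe[A];
          for (int j = 0; j < d; ++j) gv[i][j] += ve[A][i] * dNdx[A][j];
        }
      }
      double Gv[3] = {0, 0, 0}, vGv = 0;
      for (int i = 0; i < d; ++i) {
        for (int j = 0; j < d; ++j) Gv[i] += G[i][j] * vq[j];
      }
      for (int i = 0; i < d; ++i) vGv += vq[i] * Gv[i];
      double nu = mu / rho;
      double taum = 1.0 / std::sqrt(sq * CT / (dt * dt) + vGv + CI * nu * nu * GG);
      double tauc = 1.0 / (taum * trG);
      double dtm[3], dtc[3];
      for (int k = 0; k < d; ++k) {
        dtm[k] = -taum * taum * taum * Gv[k];
        dtc[k] = taum * taum * tauc * Gv[k];
      }
      double conv[3] = {0, 0, 0}, rm[3], rc = 0;
      for (int i = 0; i < d; ++i) {
        for (int j = 0; j < d; ++j) conv[i] += gv[i][j] * vq[j];
        rc += gv[i][i];
      }
      for (int i = 0; i < d; ++i)
        rm[i] = rho * (aq[i] + conv[i] - f[i]) + gp[i];

      double vgradN[8], rmdN[8], gvdN[8][3];
      for (int A = 0; A < nen; ++A) {
        double s1 = 0, s2 = 0;
        for (int j = 0; j < d; ++j) { s1 += vq[j] * dNdx[A][j]; s2 += rm[j] * dNdx[A][j]; }
        vgradN[A] = s1; rmdN[A] = s2;
        for (int k = 0; k < d; ++k) {
          double s3 = 0;
          for (int j = 0; j < d; ++j) s3 += dNdx[A][j] * gv[j][k];
          gvdN[A][k] = s3;            // (grad v)^T grad N_A
        }
      }
      double Srm[3];                  // S_i = sum_j rm_j gv[i][j]  (cross term)
      for (int i = 0; i < d; ++i) {
        double s = 0;
        for (int j = 0; j < d; ++j) s += rm[j] * gv[i][j];
        Srm[i] = s;
      }

      const double w = qw[q] * detJ;
      for (int A = 0; A < nen; ++A) {
        for (int i = 0; i < d; ++i) {
          double visc = 0;
          for (int j = 0; j < d; ++j) visc += (gv[i][j] + gv[j][i]) * dNdx[A][j];
          double r =
              N[A] * rho * (aq[i] + conv[i] - f[i])
            - dNdx[A][i] * pq
            + mu * visc
            + taum * vgradN[A] * rm[i]
            + dNdx[A][i] * rho * tauc * rc
            + N[A] * taum * Srm[i]
            - (taum * taum / rho) * rmdN[A] * rm[i];
          Re[d * A + i] += w * r;
        }
        Re[d * nen + A] += w * (N[A] * rc + (taum / rho) * rmdN[A]);
      }

      if (want_jac) {
        for (int A = 0; A < nen; ++A) {
          double dNAdNB;
          for (int B = 0; B < nen; ++B) {
            dNAdNB = 0;
            for (int j = 0; j < d; ++j) dNAdNB += dNdx[A][j] * dNdx[B][j];
            for (int k = 0; k < d; ++k) {
              const double dtm_v = dtm[k] * N[B], dtc_v = dtc[k] * N[B];
              // pieces independent of i
              const double sum_dNA_drm =       // sum_j dN_A_j drm_j/dv_Bk  (/rho)
                rho * (dNdx[A][k] * vgradN[B] + N[B] * gvdN[A][k]);
              for (int i = 0; i < d; ++i) {
                const double dik = (i == k) ? 1.0 : 0.0;
                const double dconv = dik * vgradN[B] + gv[i][k] * N[B];
                const double drm_v = rho * dconv;
                // cross-term v-derivative:
                // dT6 = N_A [ dtm_v Srm_i + taum( rho(vgradN_B gv[i][k]
                //       + N_B sum_j gv[j][k] gv[i][j]) + dik rmdN_B ) ]
                double sum_gvgv = 0;
                for (int j = 0; j < d; ++j) sum_gvgv += gv[j][k] * gv[i][j];
                double kv =
                    N[A] * rho * dconv
                  + mu * (dik * dNAdNB + dNdx[B][i] * dNdx[A][k])
                  + dtm_v * vgradN[A] * rm[i] + taum * N[B] * dNdx[A][k] * rm[i]
                  + taum * vgradN[A] * drm_v
                  + dNdx[A][i] * rho * (dtc_v * rc + tauc * dNdx[B][k])
                  + N[A] * (dtm_v * Srm[i]
                            + taum * (rho * (vgradN[B] * gv[i][k] + N[B] * sum_gvgv)
                                      + dik * rmdN[B]));
                // Reynolds v-derivative
                kv += -(1.0 / rho) * (2 * taum * dtm_v * rm[i] * rmdN[A]
                                      + taum * taum * (drm_v * rmdN[A] + rm[i] * sum_dNA_drm));
                double ka =
                    N[A] * rho * N[B] * dik
                  + taum * vgradN[A] * rho * N[B] * dik
                  + N[A] * taum * rho * N[B] * gv[i][k]
                  - taum * taum * N[B] * (dik * rmdN[A] + rm[i] * dNdx[A][k]);
                Ke[(d * A + i) * nle + (d * B + k)] += w * (cv * kv + ca * ka);
              }
              // continuity rows (once per (A, B, k))
              double cvk =
                  N[A] * dNdx[B][k]
                + (1.0 / rho) * dtm_v * rmdN[A]
                + taum * (dNdx[A][k] * vgradN[B] + N[B] * gvdN[A][k]);
              double cak = taum * N[B] * dNdx[A][k];
              Ke[(d * nen + A) * nle + (d * B + k)] += w * (cv * cvk + ca * cak);
            }
            // pressure columns
            for (int i = 0; i < d; ++i) {
              double sum_gvB = 0;                 // sum_j dN_B_j gv[i][j]
              for (int j = 0; j < d; ++j) sum_gvB += dNdx[B][j] * gv[i][j];
              double kp =
                  -dNdx[A][i] * N[B]
                + taum * vgradN[A] * dNdx[B][i]
                + N[A] * taum * sum_gvB
                - (taum * taum / rho) * (dNdx[B][i] * rmdN[A] + rm[i] * dNAdNB);
              Ke[(d * A + i) * nle + (d * nen + B)] += w * cp * kp;
            }
            Ke[(d * nen + A) * nle + (d * nen + B)] += w * cp * (taum / rho) * dNAdNB;
          }
        }
      }
    }

    for (int la = 0; la < nle; ++la)
      if (!std::isfinite(Re[la]))
        stop("assembly error: non-finite residual in fluid element %d", e + 1);

    // scatter
    int gdof[ /*nle*/ 36];
    for (int A = 0; A < nen; ++A) {
      for (int i = 0; i < d; ++i) gdof[d * A + i] = d * conn[A] + i;
      gdof[d * nen + A] = d * nn + conn[A];
    }
    for (int A = 0; A < nen; ++A) {
      for (int i = 0; i < d; ++i) Rm(d * conn[A] + i) += Re[d * A + i];
      Rc(conn[A]) += Re[d * nen + A];
    }
    if (want_jac) {
      for (int la = 0; la < nle; ++la)
        for (int lb = 0; lb < nle; ++lb) {
          double val = Ke[la * nle + lb];
          if (val != 0.0) { Ti.push_back(gdof[la]); Tj.push_back(gdof[lb]); Tx.push_back(val); }
        }
    }
  }

  List out = List::create(_["Rm"] = Rm, _["Rc"] = Rc);
  if (want_jac) {
    out["i"] = IntegerVector(Ti.begin(), Ti.end());
    out["j"] = IntegerVector(Tj.begin(), Tj.end());
    out["x"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Immersed hyperelastic solid assembly
// ---------------------------------------------------------------------------

// material ids: 1 compressible neo-Hookean (mu, lambda),
//               2 uncoupled neo-Hookean (C0, kappa),
//               3 circumferential fiber (mu_s) with nodal reference direction

static void pk1_and_tangent(int mat, const double* par, const double F[3][3],
                            const double eref[3], int d,
                            double P[3][3], double Amat[3][3][3][3],
                            bool want_tan, int e) {
  double Jd = det_small(F, d);
  if (Jd <= 0) stop("element inversion: det F <= 0 in solid element %d", e + 1);
  double Fi[3][3];
  inv_small(F, Fi, d, Jd);
  // F^{-T}_{iJ} = Fi[J][i]
  auto FiT = [&](int i, int J) { return Fi[J][i]; };

  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) P[i][j] = 0;

  if (mat == 1) {
    const double mu = par[0], lam = par[1];
    const double lnJ = std::log(Jd);
    for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J)
      P[i][J] = mu * F[i][J] + (lam * lnJ - mu) * FiT(i, J);
    if (want_tan) {
      for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J)
        for (int k = 0; k < d; ++k) for (int L = 0; L < d; ++L)
          Amat[i][J][k][L] =
              mu * ((i == k) && (J == L) ? 1.0 : 0.0)
            + (mu - lam * lnJ) * FiT(i, L) * FiT(k, J)
            + lam * FiT(i, J) * FiT(k, L);
    }
  } else if (mat == 2) {
    const double C0 = par[0], kap = par[1];
    double I1 = 0;
    for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J) I1 += F[i][J] * F[i][J];
    if (d == 2) I1 += 1.0;   // plane-strain: F_zz = 1
    const double Jm23 = std::pow(Jd, -2.0 / 3.0);
    for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J)
      P[i][J] = C0 * Jm23 * (F[i][J] - (I1 / 3.0) * FiT(i, J))
              + 0.5 * kap * (Jd * Jd - 1.0) * FiT(i, J);
    if (want_tan) {
      for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J)
        for (int k = 0; k < d; ++k) for (int L = 0; L < d; ++L) {
          double t = -(2.0 / 3.0) * Jm23 * FiT(k, L) * (F[i][J] - (I1 / 3.0) * FiT(i, J))
                   + Jm23 * (((i == k) && (J == L) ? 1.0 : 0.0)
                             - (2.0 / 3.0) * F[k][L] * FiT(i, J)
                             + (I1 / 3.0) * FiT(i, L) * FiT(k, J));
          Amat[i][J][k][L] = C0 * t
            + 0.5 * kap * (2.0 * Jd * Jd * FiT(k, L) * FiT(i, J)
                           - (Jd * Jd - 1.0) * FiT(i, L) * FiT(k, J));
        }
    }
  } else { // fiber
    const double mus = par[0];
    double Fe[3] = {0, 0, 0};
    for (int i = 0; i < d; ++i)
      for (int J = 0; J < d; ++J) Fe[i] += F[i][J] * eref[J];
    for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J)
      P[i][J] = mus * Fe[i] * eref[J];
    if (want_tan) {
      for (int i = 0; i < d; ++i) for (int J = 0; J < d; ++J)
        for (int k = 0; k < d; ++k) for (int L = 0; L < d; ++L)
          Amat[i][J][k][L] = (i == k) ? mus * eref[J] * eref[L] : 0.0;
    }
  }
}

// [[Rcpp::export]]
List cpp_assemble_solid(const arma::mat& nodes0, const arma::imat& elem,
                        std::string elem_type,
                        const arma::mat& u, const arma::mat& ud,
                        const arma::mat& udd,
                        int mat, const arma::vec& par, const arma::mat& e_theta,
                        double rho0, double rhof, double muf,
                        const arma::vec& fbody,
                        double fu, double fv, double fa,
                        bool want_jac) {
  const int tid = type_id(elem_type);
  const int d = type_dim(tid), nen = type_nen(tid);
  const int nel = elem.n_rows, nn = nodes0.n_rows;
  const int nle = nen * d;
  const bool has_fiber = (mat == 3);

  double qp[8][3], qw[8];
  const int nqp = quad_rule(tid, qp, qw);
  double Nq[8][8], dNq[8][8][3];
  for (int q = 0; q < nqp; ++q) {
    double dN[8][3];
    shape(tid, qp[q], Nq[q], dN);
    for (int A = 0; A < nen; ++A) for (int j = 0; j < d; ++j) dNq[q][A][j] = dN[A][j];
  }

  arma::vec Rs(d * nn, arma::fill::zeros);
  std::vector<int> Ti, Tj; std::vector<double> Tx;
  std::vector<double> Ke(nle * nle), Re(nle);
  double f[3] = {0, 0, 0};
  for (int i = 0; i < d; ++i) f[i] = fbody(i);
  double parv[4] = {0, 0, 0, 0};
  for (arma::uword i = 0; i < par.n_elem && i < 4; ++i) parv[i] = par(i);

  for (int e = 0; e < nel; ++e) {
    int conn[8];
    for (int A = 0; A < nen; ++A) conn[A] = elem(e, A);
    double X[8][3], ue[8][3], ude[8][3], udde[8][3], eth[8][3];
    for (int A = 0; A < nen; ++A)
      for (int j = 0; j < d; ++j) {
        X[A][j] = nodes0(conn[A], j);
        ue[A][j] = u(conn[A], j);
        ude[A][j] = ud(conn[A], j);
        udde[A][j] = udd(conn[A], j);
        eth[A][j] = has_fiber ? e_theta(conn[A], j) : 0.0;
      }
    std::fill(Ke.begin(), Ke.end(), 0.0);
    std::fill(Re.begin(), Re.end(), 0.0);

    for (int q = 0; q < nqp; ++q) {
      const double* N = Nq[q];
      double J0[3][3] = {{0}}, J0i[3][3];
      for (int A = 0; A < nen; ++A)
        for (int i = 0; i < d; ++i) for (int j = 0; j < d; ++j)
          J0[i][j] += X[A][i] * dNq[q][A][j];
      double detJ0 = det_small(J0, d);
      if (detJ0 <= 0) stop("invalid mesh: non-positive reference Jacobian in solid element %d", e + 1);
      inv_small(J0, J0i, d, detJ0);
      double dNdX[8][3];
      for (int A = 0; A < nen; ++A)
        for (int j = 0; j < d; ++j) {
          double s = 0;
          for (int k = 0; k < d; ++k) s += dNq[q][A][k] * J0i[k][j];
          dNdX[A][j] = s;
        }
      // deformation gradient, rates, interpolants
      double F[3][3] = {{0}}, gradud[3][3] = {{0}};
      double uddq[3] = {0, 0, 0}, eref[3] = {0, 0, 0};
      for (int i = 0; i < d; ++i) F[i][i] = 1.0;
      for (int A = 0; A < nen; ++A)
        for (int i = 0; i < d; ++i) {
          uddq[i] += N[A] * udde[A][i];
          if (has_fiber) eref[i] += N[A] * eth[A][i];
          for (int j = 0; j < d; ++j) {
            F[i][j] += ue[A][i] * dNdX[A][j];
            gradud[i][j] += ude[A][i] * dNdX[A][j];
          }
        }
      if (has_fiber) {
        double nrm = 0;
        for (int i = 0; i < d; ++i) nrm += eref[i] * eref[i];
        nrm = std::sqrt(nrm);
        for (int i = 0; i < d; ++i) eref[i] /= nrm;
      }
      double Jd = det_small(F, d);
      if (Jd <= 0) stop("element inversion: det F <= 0 in solid element %d", e + 1);
      double Fi[3][3];
      inv_small(F, Fi, d, Jd);
      // spatial gradients g_A = F^{-T} GradN_A ; L = grad_x(ud)
      double gx[8][3], L[3][3] = {{0}}, eps[3][3];
      for (int A = 0; A < nen; ++A)
        for (int j = 0; j < d; ++j) {
          double s = 0;
          for (int K = 0; K < d; ++K) s += dNdX[A][K] * Fi[K][j];
          gx[A][j] = s;
        }
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j) {
          double s = 0;
          for (int K = 0; K < d; ++K) s += gradud[i][K] * Fi[K][j];
          L[i][j] = s;
        }
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j) eps[i][j] = 0.5 * (L[i][j] + L[j][i]);

      double P[3][3], Amat[3][3][3][3];
      pk1_and_tangent(mat, parv, F, eref, d, P, Amat, want_jac, e);

      const double w = qw[q] * detJ0;
      const double rhoterm = rho0 - rhof * Jd;
      for (int A = 0; A < nen; ++A)
        for (int i = 0; i < d; ++i) {
          double internal = 0, visc = 0;
          for (int Jj = 0; Jj < d; ++Jj) internal += P[i][Jj] * dNdX[A][Jj];
          for (int j = 0; j < d; ++j) visc += eps[i][j] * gx[A][j];
          Re[d * A + i] += w * (N[A] * rhoterm * (uddq[i] - f[i])
                                + internal
                                - 2.0 * muf * Jd * visc);
        }

      if (want_jac) {
        for (int A = 0; A < nen; ++A)
          for (int B = 0; B < nen; ++B) {
            double gAgB = 0;
            for (int j = 0; j < d; ++j) gAgB += gx[A][j] * gx[B][j];
            for (int i = 0; i < d; ++i)
              for (int k = 0; k < d; ++k) {
                const double dik = (i == k) ? 1.0 : 0.0;
                // material stiffness
                double kmat = 0;
                for (int Jj = 0; Jj < d; ++Jj)
                  for (int Ll = 0; Ll < d; ++Ll)
                    kmat += dNdX[A][Jj] * Amat[i][Jj][k][Ll] * dNdX[B][Ll];
                // inertia geometric (d(rho0 - rhof J)/du)
                double kgeo_in = -rhof * Jd * gx[B][k] * N[A] * (uddq[i] - f[i]);
                // viscous geometric
                double epsgA_i = 0, LgA_k = 0, epsgB_i = 0;
                for (int j = 0; j < d; ++j) {
                  epsgA_i += eps[i][j] * gx[A][j];
                  LgA_k += L[j][k] * gx[A][j];
                  epsgB_i += eps[i][j] * gx[B][j];
                }
                double kgeo_v = -2.0 * muf * Jd *
                  (gx[B][k] * epsgA_i
                   - 0.5 * (L[i][k] * gAgB + gx[B][i] * LgA_k)
                   - epsgB_i * gx[A][k]);
                // viscous velocity part
                double kvel = -muf * Jd * (dik * gAgB + gx[B][i] * gx[A][k]);
                // inertia mass part
                double kacc = N[A] * rhoterm * N[B] * dik;
                Ke[(d * A + i) * nle + (d * B + k)] +=
                  w * (fu * (kmat + kgeo_in + kgeo_v) + fv * kvel + fa * kacc);
              }
          }
      }
    }

    for (int la = 0; la < nle; ++la)
      if (!std::isfinite(Re[la]))
        stop("assembly error: non-finite residual in solid element %d", e + 1);

    for (int A = 0; A < nen; ++A)
      for (int i = 0; i < d; ++i) Rs(d * conn[A] + i) += Re[d * A + i];
    if (want_jac) {
      for (int A = 0; A < nen; ++A)
        for (int i = 0; i < d; ++i)
          for (int B = 0; B < nen; ++B)
            for (int k = 0; k < d; ++k) {
              double val = Ke[(d * A + i) * nle + (d * B + k)];
              if (val != 0.0) {
                Ti.push_back(d * conn[A] + i);
                Tj.push_back(d * conn[B] + k);
                Tx.push_back(val);
              }
            }
    }
  }

  List out = List::create(_["Rs"] = Rs);
  if (want_jac) {
    out["i"] = IntegerVector(Ti.begin(), Ti.end());
    out["j"] = IntegerVector(Tj.begin(), Tj.end());
    out["x"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Point location: bounding-box grid + Newton inversion of the isoparametric map
// ---------------------------------------------------------------------------

struct Locator {
  arma::mat nodes;
  arma::imat elem;
  int tid, d, nen;
  double lo[3], hi[3];
  int nc[3];
  double cell[3];
  std::vector<std::vector<int>> bins;
  arma::mat bb_lo, bb_hi;   // per-element bounding boxes
};

static std::vector<Locator*> g_locators;

static int cell_index(const Locator& L, const int* c) {
  int idx = c[0];
  if (L.d > 1) idx += L.nc[0] * c[1];
  if (L.d > 2) idx += L.nc[0] * L.nc[1] * c[2];
  return idx;
}

// [[Rcpp::export]]
int cpp_build_locator(const arma::mat& nodes, const arma::imat& elem,
                      std::string elem_type) {
  Locator* L = new Locator();
  L->nodes = nodes; L->elem = elem;
  L->tid = type_id(elem_type);
  L->d = type_dim(L->tid); L->nen = type_nen(L->tid);
  const int nel = elem.n_rows, d = L->d;
  L->bb_lo.set_size(nel, d); L->bb_hi.set_size(nel, d);
  for (int j = 0; j < d; ++j) { L->lo[j] = arma::datum::inf; L->hi[j] = -arma::datum::inf; }
  for (int e = 0; e < nel; ++e)
    for (int j = 0; j < d; ++j) {
      double mn = arma::datum::inf, mx = -arma::datum::inf;
      for (int A = 0; A < L->nen; ++A) {
        double v = nodes(elem(e, A), j);
        mn = std::min(mn, v); mx = std::max(mx, v);
      }
      L->bb_lo(e, j) = mn; L->bb_hi(e, j) = mx;
      L->lo[j] = std::min(L->lo[j], mn); L->hi[j] = std::max(L->hi[j], mx);
    }
  int target = std::max(1, (int)std::floor(std::pow((double)nel, 1.0 / d)));
  int ntot = 1;
  for (int j = 0; j < d; ++j) {
    L->nc[j] = std::max(1, target);
    double ext = L->hi[j] - L->lo[j];
    if (ext <= 0) { L->nc[j] = 1; ext = 1.0; }
    L->cell[j] = ext / L->nc[j] * (1 + 1e-12);
    ntot *= L->nc[j];
  }
  L->bins.assign(ntot, {});
  for (int e = 0; e < nel; ++e) {
    int c0[3] = {0, 0, 0}, c1[3] = {0, 0, 0};
    for (int j = 0; j < d; ++j) {
      c0[j] = std::min(L->nc[j] - 1, std::max(0, (int)std::floor((L->bb_lo(e, j) - L->lo[j]) / L->cell[j])));
      c1[j] = std::min(L->nc[j] - 1, std::max(0, (int)std::floor((L->bb_hi(e, j) - L->lo[j]) / L->cell[j])));
    }
    int c[3];
    for (c[0] = c0[0]; c[0] <= c1[0]; ++c[0])
      for (c[1] = c0[1]; c[1] <= (d > 1 ? c1[1] : c0[1]); ++c[1])
        for (c[2] = c0[2]; c[2] <= (d > 2 ? c1[2] : c0[2]); ++c[2])
          L->bins[cell_index(*L, c)].push_back(e);
  }
  g_locators.push_back(L);
  return (int)g_locators.size() - 1;
}

// Newton inversion; returns true if converged, xi holds result
static bool invert_map(const Locator& L, int e, const double* x, double* xi) {
  const int d = L.d, nen = L.nen;
  double Xc[8][3];
  for (int A = 0; A < nen; ++A)
    for (int j = 0; j < d; ++j) Xc[A][j] = L.nodes(L.elem(e, A), j);
  // start at element center
  if (L.tid == Q_QUAD4 || L.tid == Q_HEX8) { xi[0] = xi[1] = xi[2] = 0; }
  else { xi[0] = xi[1] = xi[2] = 1.0 / (d + 1); }
  double N[8], dN[8][3];
  for (int it = 0; it < 30; ++it) {
    shape(L.tid, xi, N, dN);
    double r[3] = {0, 0, 0}, J[3][3] = {{0}}, Ji[3][3];
    for (int j = 0; j < d; ++j) r[j] = -x[j];
    for (int A = 0; A < nen; ++A)
      for (int i = 0; i < d; ++i) {
        r[i] += N[A] * Xc[A][i];
        for (int j = 0; j < d; ++j) J[i][j] += Xc[A][i] * dN[A][j];
      }
    double detJ = det_small(J, d);
    if (detJ == 0 || !std::isfinite(detJ)) return false;
    inv_small(J, Ji, d, detJ);
    double dxi[3] = {0, 0, 0}, nrm = 0;
    for (int i = 0; i < d; ++i) {
      for (int j = 0; j < d; ++j) dxi[i] += Ji[i][j] * r[j];
      xi[i] -= dxi[i]; nrm += dxi[i] * dxi[i];
    }
    if (nrm < 1e-24) return true;   // parametric increment below 1e-12
  }
  return false;
}

static double outside_dist(const Locator& L, const double* xi, double tol) {
  // parametric distance beyond the reference element (0 if inside)
  double dmax = 0;
  if (L.tid == Q_QUAD4 || L.tid == Q_HEX8) {
    for (int j = 0; j < L.d; ++j)
      dmax = std::max(dmax, std::abs(xi[j]) - 1.0);
  } else {
    double s = 0;
    for (int j = 0; j < L.d; ++j) { dmax = std::max(dmax, -xi[j]); s += xi[j]; }
    dmax = std::max(dmax, s - 1.0);
  }
  return std::max(0.0, dmax);
}

// [[Rcpp::export]]
List cpp_locate(int handle, const arma::mat& x, double tol,
                bool extrapolate, double max_extrap) {
  const Locator& L = *g_locators[handle];
  const int np = x.n_rows, d = L.d;
  IntegerVector eout(np);
  LogicalVector failed(np);
  arma::mat xiout(np, d, arma::fill::zeros);
  for (int pIdx = 0; pIdx < np; ++pIdx) {
    double xp[3] = {0, 0, 0};
    for (int j = 0; j < d; ++j) xp[j] = x(pIdx, j);
    // candidates from the containing cell
    bool inbox = true;
    int c[3] = {0, 0, 0};
    for (int j = 0; j < d; ++j) {
      if (xp[j] < L.lo[j] - tol || xp[j] > L.hi[j] + tol) { inbox = false; break; }
      c[j] = std::min(L.nc[j] - 1, std::max(0, (int)std::floor((xp[j] - L.lo[j]) / L.cell[j])));
    }
    int found = -1;
    double xi_best[3] = {0, 0, 0};
    if (inbox) {
      std::vector<int> cand = L.bins[cell_index(L, c)];
      std::sort(cand.begin(), cand.end());
      for (int e : cand) {
        bool inbb = true;
        for (int j = 0; j < d; ++j)
          if (xp[j] < L.bb_lo(e, j) - tol || xp[j] > L.bb_hi(e, j) + tol) { inbb = false; break; }
        if (!inbb) continue;
        double xi[3];
        if (!invert_map(L, e, xp, xi)) continue;
        if (outside_dist(L, xi, tol) <= tol) {
          found = e;
          for (int j = 0; j < d; ++j) xi_best[j] = xi[j];
          break;
        }
      }
    }
    if (found < 0 && extrapolate) {
      // nearest elements by bbox distance, then smallest parametric excess
      double best = arma::datum::inf;
      int nel = L.elem.n_rows;
      std::vector<std::pair<double, int>> order(nel);
      for (int e = 0; e < nel; ++e) {
        double dd = 0;
        for (int j = 0; j < d; ++j) {
          double lo = L.bb_lo(e, j), hi = L.bb_hi(e, j);
          double t = (xp[j] < lo) ? lo - xp[j] : (xp[j] > hi ? xp[j] - hi : 0.0);
          dd += t * t;
        }
        order[e] = {dd, e};
      }
      std::partial_sort(order.begin(), order.begin() + std::min(nel, 24), order.end());
      for (int r = 0; r < std::min(nel, 24); ++r) {
        int e = order[r].second;
        double xi[3];
        if (!invert_map(L, e, xp, xi)) continue;
        double ex = outside_dist(L, xi, tol);
        if (ex < best) {
          best = ex; found = e;
          for (int j = 0; j < d; ++j) xi_best[j] = xi[j];
        }
      }
      if (found >= 0 && best > max_extrap) { failed[pIdx] = true; found = -1; }
    }
    if (found >= 0) {
      eout[pIdx] = found + 1;
      for (int j = 0; j < d; ++j) xiout(pIdx, j) = xi_best[j];
    } else {
      eout[pIdx] = 0;
      if (extrapolate) failed[pIdx] = true;
    }
  }
  return List::create(_["elem"] = eout, _["xi"] = xiout, _["failed"] = failed);
}

// ---------------------------------------------------------------------------
// Interface band marking for the s-field
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_mark_near(const arma::mat& pts, const arma::mat& src,
                            double radius) {
  const int np = pts.n_rows, ns = src.n_rows, d = pts.n_cols;
  LogicalVector out(np);
  if (ns == 0 || radius <= 0) return out;
  double lo[3], nc_d[3];
  int nc[3];
  for (int j = 0; j < d; ++j) {
    lo[j] = src.col(j).min() - radius;
    double hi = src.col(j).max() + radius;
    nc[j] = std::max(1, (int)std::ceil((hi - lo[j]) / radius));
    nc_d[j] = nc[j];
  }
  auto cidx = [&](const int* c) {
    int idx = c[0];
    if (d > 1) idx += nc[0] * c[1];
    if (d > 2) idx += nc[0] * nc[1] * c[2];
    return idx;
  };
  int ntot = 1;
  for (int j = 0; j < d; ++j) ntot *= nc[j];
  std::vector<std::vector<int>> bins(ntot);
  for (int s = 0; s < ns; ++s) {
    int c[3] = {0, 0, 0};
    for (int j = 0; j < d; ++j)
      c[j] = std::min(nc[j] - 1, std::max(0, (int)std::floor((src(s, j) - lo[j]) / radius)));
    bins[cidx(c)].push_back(s);
  }
  const double r2 = radius * radius;
  for (int pIdx = 0; pIdx < np; ++pIdx) {
    int c[3] = {0, 0, 0};
    bool off = false;
    for (int j = 0; j < d; ++j) {
      double t = (pts(pIdx, j) - lo[j]) / radius;
      if (t < -1 || t > nc_d[j] + 1) { off = true; break; }
      c[j] = (int)std::floor(t);
    }
    if (off) continue;
    bool hit = false;
    int cc[3];
    for (int dx = -1; dx <= 1 && !hit; ++dx)
      for (int dy = (d > 1 ? -1 : 0); dy <= (d > 1 ? 1 : 0) && !hit; ++dy)
        for (int dz = (d > 2 ? -1 : 0); dz <= (d > 2 ? 1 : 0) && !hit; ++dz) {
          cc[0] = c[0] + dx; cc[1] = c[1] + dy; cc[2] = c[2] + dz;
          bool ok = true;
          for (int j = 0; j < d; ++j)
            if (cc[j] < 0 || cc[j] >= nc[j]) { ok = false; break; }
          if (!ok) continue;
          for (int s : bins[cidx(cc)]) {
            double dd = 0;
            for (int j = 0; j < d; ++j) {
              double t = pts(pIdx, j) - src(s, j);
              dd += t * t;
            }
            if (dd <= r2) { hit = true; break; }
          }
        }
    out[pIdx] = hit;
  }
  return out;
}
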