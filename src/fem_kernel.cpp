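// Element kernels for the total-Lagrangian assembly: internal forces,
// per-element incompressibility constraint residuals, and the numerical
// consistent tangent (central differences of the element residual with
// respect to its own nodal displacements; the displacement-multiplier
// coupling blocks are analytic because the residual is linear in the
// multiplier).
//
// Units: mm / N / MPa / s. Voigt order (11, 22, 33, 12, 23, 13) with
// engineering shear strains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct MusclePar {
  double c, b, T0M, A, a, muSO, muFG, kappa, rho;
};

static inline double f_pe(double lf, const MusclePar& p) {
  double d = lf - 1.0;
  return d > 0.0 ? 2.0 * p.a * p.A * std::exp(p.a * d * d) * d : 0.0;
}
static inline double f_lce(double lf) {
  if (lf < 0.5 || lf > 1.5) return 0.0;
  double v = -4.0 * (lf - 1.0) * (lf - 1.0) + 1.0;
  return v > 0.0 ? v : 0.0;
}
static inline double f_vce(double r) {
  if (r <= -10.0) return 0.0;
  if (r > 2.0) return M_PI / (4.0 * std::atan(5.0)) + 1.0;
  return -(1.0 / std::atan(5.0)) * std::atan(-0.5 * r) + 1.0;
}

// Evaluate one element's internal force (12), constraint residual W*V and
// auxiliary outputs at local displacements Ue. Returns false on J <= 0.
static bool elem_eval(const arma::mat& Ge, double V, int kind,
                      double stvk_lambda, double stvk_mu,
                      const arma::vec3& Nm, double lamf_prev, double dt,
                      double aSO, double aFG, const MusclePar& mp,
                      double lam, const arma::mat& Ue,
                      arma::vec::fixed<12>& f, double& W,
                      double& Jout, double& lamf_out, double& T_out,
                      arma::vec::fixed<12>& dWdu, bool want_dW) {
  arma::mat33 F = arma::eye(3, 3) + Ue.t() * Ge;   // dx/dX
  double J = arma::det(F);
  Jout = J;
  if (!(J > 0.0) || !std::isfinite(J)) return false;
  arma::mat33 C = F.t() * F;
  arma::mat33 Cinv;
  if (!arma::inv(Cinv, C)) return false;
  Cinv = 0.5 * (Cinv + Cinv.t());

  arma::mat33 S;
  double lamf = 1.0, T = 0.0;
  if (kind == 0) {                                  // muscle
    double Jm23 = std::pow(J, -2.0 / 3.0);
    double trC = C(0, 0) + C(1, 1) + C(2, 2);
    double It = Jm23 * trC;
    double CNN = arma::as_scalar(Nm.t() * C * Nm);
    lamf = std::sqrt(Jm23 * CNN);
    double rate = (lamf - lamf_prev) / dt;
    double fl = f_lce(lamf), fv = f_vce(rate), fp = f_pe(lamf, mp);
    T = mp.T0M * (mp.muSO * (fp + fl * fv * aSO) +
                  mp.muFG * (fp + fl * fv * aFG));
    arma::mat33 NN = Nm * Nm.t();
    S = mp.kappa * J * Cinv +
        2.0 * mp.b * mp.c * std::exp(mp.b * (It - 3.0)) *
          (Jm23 * arma::eye(3, 3) - It / 3.0 * Cinv) +
        T * (Jm23 / lamf * NN - lamf / 3.0 * Cinv) +
        (lam + mp.rho * (J * J - 1.0)) * 2.0 * J * J * Cinv;
  } else {                                          // St. Venant-Kirchhoff
    arma::mat33 E = 0.5 * (C - arma::eye(3, 3));
    double trE = E(0, 0) + E(1, 1) + E(2, 2);
    S = stvk_lambda * trE * arma::eye(3, 3) + 2.0 * stvk_mu * E;
  }
  lamf_out = lamf;
  T_out = T;

  arma::vec::fixed<6> s;
  s(0) = S(0, 0); s(1) = S(1, 1); s(2) = S(2, 2);
  s(3) = S(0, 1); s(4) = S(1, 2); s(5) = S(0, 2);

  // f = V * B' s without forming B: row of B for dof (a,k):
  //   [F(k,0)G(a,0), F(k,1)G(a,1), F(k,2)G(a,2),
  //    F(k,0)G(a,1)+F(k,1)G(a,0), F(k,1)G(a,2)+F(k,2)G(a,1),
  //    F(k,0)G(a,2)+F(k,2)G(a,0)]
  for (int a = 0; a < 4; ++a) {
    double g0 = Ge(a, 0), g1 = Ge(a, 1), g2 = Ge(a, 2);
    for (int k = 0; k < 3; ++k) {
      double F0 = F(k, 0), F1 = F(k, 1), F2 = F(k, 2);
      f(3 * a + k) = V * (F0 * g0 * s(0) + F1 * g1 * s(1) + F2 * g2 * s(2) +
                          (F0 * g1 + F1 * g0) * s(3) +
                          (F1 * g2 + F2 * g1) * s(4) +
                          (F0 * g2 + F2 * g0) * s(5));
    }
  }
  W = V * (J * J - 1.0);

  if (want_dW) {
    // dW/du_{a,k} = V * 2 J^2 * (Ge Finv)(a,k)
    arma::mat33 Finv = arma::inv(F);
    arma::mat M = Ge * Finv;                        // 4 x 3
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k)
        dWdu(3 * a + k) = V * 2.0 * J * J * M(a, k);
  }
  return true;
}

// [[Rcpp::export]]
List fem_assemble_cpp(const arma::mat& G, const arma::vec& V,
                      const arma::imat& conn, const arma::ivec& kind,
                      const arma::mat& stvk, const arma::mat& Nm,
                      const arma::vec& lamf_prev, double dt,
                      double aSO, double aFG, const arma::vec& muspar,
                      const arma::ivec& lam_id, const arma::vec& lam,
                      const arma::vec& u, double h, bool want_tangent) {
  const int m = conn.n_rows;
  const int ndof = u.n_elem;
  const int nlam = lam.n_elem;
  MusclePar mp;
  mp.c = muspar(0); mp.b = muspar(1); mp.T0M = muspar(2);
  mp.A = muspar(3); mp.a = muspar(4); mp.muSO = muspar(5);
  mp.muFG = muspar(6); mp.kappa = muspar(7); mp.rho = muspar(8);

  arma::vec fint(ndof, arma::fill::zeros);
  arma::vec wres(nlam, arma::fill::zeros);
  arma::vec Jel(m), lamf(m), Tel(m);
  Jel.fill(1.0); lamf.fill(1.0); Tel.zeros();

  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (want_tangent) {
    Ti.reserve((size_t)m * 170);
    Tj.reserve((size_t)m * 170);
    Tx.reserve((size_t)m * 170);
  }

  arma::mat Ue(4, 3), Up(4, 3);
  arma::vec::fixed<12> f0, fp_, fm_, dWdu, dW0;
  int bad_elem = 0;
  double bad_J = 1.0;

  for (int e = 0; e < m; ++e) {
    arma::mat Ge = G.rows(4 * e, 4 * e + 3);
    int li = lam_id(e);
    double le = (li >= 0) ? lam(li) : 0.0;
    bool mus = (kind(e) == 0);
    arma::vec3 N;
    N(0) = Nm(e, 0); N(1) = Nm(e, 1); N(2) = Nm(e, 2);
    int dof[12];
    for (int a = 0; a < 4; ++a) {
      int n = conn(e, a);
      for (int k = 0; k < 3; ++k) {
        dof[3 * a + k] = 3 * n + k;
        Ue(a, k) = u(3 * n + k);
      }
    }
    double W, J, lf, T;
    if (!elem_eval(Ge, V(e), kind(e), stvk(e, 0), stvk(e, 1), N,
                   lamf_prev(e), dt, aSO, aFG, mp, le, Ue,
                   f0, W, J, lf, T, dW0, mus)) {
      bad_elem = e + 1; bad_J = J;
      break;
    }
    Jel(e) = J; lamf(e) = lf; Tel(e) = T;
    for (int d = 0; d < 12; ++d) fint(dof[d]) += f0(d);
    if (li >= 0) wres(li) += W;

    if (!want_tangent) continue;

    // 12 x 12 displacement block by central differences of the residual
    double Wp, Wm, Jd, lfd, Td;
    for (int d = 0; d < 12; ++d) {
      int a = d / 3, k = d % 3;
      Up = Ue;
      Up(a, k) = Ue(a, k) + h;
      if (!elem_eval(Ge, V(e), kind(e), stvk(e, 0), stvk(e, 1), N,
                     lamf_prev(e), dt, aSO, aFG, mp, le, Up,
                     fp_, Wp, Jd, lfd, Td, dWdu, false)) {
        bad_elem = e + 1; bad_J = Jd; break;
      }
      Up(a, k) = Ue(a, k) - h;
      if (!elem_eval(Ge, V(e), kind(e), stvk(e, 0), stvk(e, 1), N,
                     lamf_prev(e), dt, aSO, aFG, mp, le, Up,
                     fm_, Wm, Jd, lfd, Td, dWdu, false)) {
        bad_elem = e + 1; bad_J = Jd; break;
      }
      for (int r = 0; r < 12; ++r) {
        Ti.push_back(dof[r]);
        Tj.push_back(dof[d]);
        Tx.push_back((fp_(r) - fm_(r)) / (2.0 * h));
      }
    }
    if (bad_elem) break;

    if (li >= 0) {
      // coupling blocks (exactly symmetric: residual linear in multiplier,
      // and dW/du equals the constraint-stress column)
      int lr = ndof + li;
      for (int d = 0; d < 12; ++d) {
        Ti.push_back(dof[d]); Tj.push_back(lr); Tx.push_back(dW0(d));
        Ti.push_back(lr); Tj.push_back(dof[d]); Tx.push_back(dW0(d));
      }
    }
  }

  List out = List::create(
    _["fint"] = fint, _["wres"] = wres, _["J"] = Jel,
    _["lamf"] = lamf, _["T"] = Tel, _["bad_elem"] = bad_elem,
    _["bad_J"] = bad_J);
  if (want_tangent) {
    out["ti"] = IntegerVector(Ti.begin(), Ti.end());
    out["tj"] = IntegerVector(Tj.begin(), Tj.end());
    out["tx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}
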