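// Constitutive kernels and element assembly for the stationary polynomial
// hyperelastic model W = (1-g) * sum_{1<=i+j<=2} Cij0 (J1-3)^i (J2-3)^j
//                      + kappa/2 (sqrt(J3) - 1)^2
// with J1 = tr(B), J2 = (J1^2 - tr(B^2)) / (2 J3), J3 = det(B), B = F F^T.
// Total-Lagrangian form on the reference mesh; P = dW/dF, A = d2W/dF2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct HyperPar {
  double C100, C010, C110, C200, C020, g, kap;
};

HyperPar unpack(const arma::vec &p) {
  HyperPar h;
  h.C100 = p(0); h.C010 = p(1); h.C110 = p(2);
  h.C200 = p(3); h.C020 = p(4); h.g = p(5); h.kap = p(6);
  return h;
}

// Energy density, dW/dB (S) and d2W/dB2 (D) at a given B.
// Returns false if B is not usable (det <= 0 or non-finite).
bool point_SD(const arma::mat33 &B, const HyperPar &par, bool want_D,
              double &W, arma::mat33 &S, arma::mat &D) {
  const double J3 = arma::det(B);
  if (!std::isfinite(J3) || J3 <= 1e-12) return false;
  const arma::mat33 I3(arma::fill::eye);
  arma::mat33 Binv;
  if (!arma::inv_sympd(Binv, arma::symmatu(B))) {
    if (!arma::inv(Binv, B)) return false;
  }
  const double J1 = arma::trace(B);
  const double trB2 = arma::accu(B % B);
  const double J2 = (J1 * J1 - trB2) / (2.0 * J3);
  const double a1 = J1 - 3.0, a2 = J2 - 3.0;
  const double om = 1.0 - par.g;
  const double sJ3 = std::sqrt(J3);

  W = om * (par.C100 * a1 + par.C010 * a2 + par.C110 * a1 * a2 +
            par.C200 * a1 * a1 + par.C020 * a2 * a2) +
      0.5 * par.kap * (sJ3 - 1.0) * (sJ3 - 1.0);
  if (!std::isfinite(W)) return false;

  const double W1 = om * (par.C100 + par.C110 * a2 + 2.0 * par.C200 * a1);
  const double W2 = om * (par.C010 + par.C110 * a1 + 2.0 * par.C020 * a2);
  const double W3 = 0.5 * par.kap * (1.0 - 1.0 / sJ3);

  const arma::mat33 G = (J1 * I3 - B) / J3 - J2 * Binv;
  const arma::mat33 H = J3 * Binv;
  S = W1 * I3 + W2 * G + W3 * H;

  if (want_D) {
    const double W11 = om * 2.0 * par.C200;
    const double W12 = om * par.C110;
    const double W22 = om * 2.0 * par.C020;
    const double W33 = par.kap / 4.0 * std::pow(J3, -1.5);
    // D stored as 9x9: row index ij = i + 3*j, col index kl = k + 3*l
    D.set_size(9, 9);
    for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k) for (int l = 0; l < 3; ++l) {
        const double isym = 0.5 * ((i == k) * (j == l) + (i == l) * (j == k));
        const double dBinv = -0.5 * (Binv(i, k) * Binv(j, l) +
                                     Binv(i, l) * Binv(j, k));
        double dG = (i == j) * (k == l) / J3
                  - (J1 / J3) * (i == j) * Binv(k, l)
                  - isym / J3
                  + B(i, j) * Binv(k, l) / J3
                  - Binv(i, j) * G(k, l)
                  - J2 * dBinv;
        double dH = J3 * (Binv(i, j) * Binv(k, l) + dBinv);
        double v = I3(i, j) * (W11 * I3(k, l) + W12 * G(k, l))
                 + G(i, j) * (W12 * I3(k, l) + W22 * G(k, l))
                 + H(i, j) * W33 * H(k, l)
                 + W2 * dG + W3 * dH;
        D(i + 3 * j, k + 3 * l) = v;
      }
  }
  return true;
}

// First Piola-Kirchhoff stress P = 2 S F and tangent A[(i,A),(j,B)] as 9x9
// (dof index i + 3*A), A = 4 D_ik,jn F_nB F_kA + 2 S_ij delta_AB.
bool point_PA(const arma::mat33 &F, const HyperPar &par, bool want_A,
              double &W, arma::mat33 &P, arma::mat &A) {
  const arma::mat33 B = F * F.t();
  arma::mat33 S;
  arma::mat D;
  if (!point_SD(B, par, want_A, W, S, D)) return false;
  P = 2.0 * S * F;
  if (want_A) {
    A.set_size(9, 9);
    for (int i = 0; i < 3; ++i) for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 3; ++j) for (int b = 0; b < 3; ++b) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) for (int n = 0; n < 3; ++n)
          s += D(i + 3 * k, j + 3 * n) * F(n, b) * F(k, a);
        A(i + 3 * a, j + 3 * b) = 4.0 * s + 2.0 * S(i, j) * (a == b);
      }
  }
  return true;
}

} // namespace

// Pointwise evaluation: energy density (Pa), stress P (3x3) and, optionally,
// the 9x9 tangent dP/dF (column-major pairing (i,A) -> i + 3A).
// [[Rcpp::export]]
List cpp_hyper_point(const arma::mat &F, const arma::vec &par, bool want_tangent) {
  HyperPar h = unpack(par);
  double W;
  arma::mat33 P;
  arma::mat A;
  arma::mat33 Fm(F);
  bool ok = point_PA(Fm, h, want_tangent, W, P, A);
  if (!ok) return List::create(_["ok"] = false);
  List out = List::create(_["ok"] = true, _["W"] = W,
                          _["P"] = wrap(arma::mat(P)));
  if (want_tangent) out["A"] = wrap(A);
  return out;
}

// Assemble total strain energy, internal force vector and (optionally) the
// tangent stiffness triplets over all tetrahedra. One quadrature point per
// element (the deformation gradient is constant on a linear tetrahedron).
// tets are 0-based here; returned triplet indices are 1-based dof indices.
// [[Rcpp::export]]
List cpp_hyper_assemble(const arma::mat &nodes, const arma::imat &tets,
                        const arma::vec &u, const arma::vec &par,
                        bool want_tangent) {
  HyperPar h = unpack(par);
  const int M = tets.n_rows;
  const int ndof = 3 * nodes.n_rows;
  arma::vec fint(ndof, arma::fill::zeros);
  double energy = 0.0;

  arma::uvec ti, tj;
  arma::vec tx;
  if (want_tangent) {
    ti.set_size((size_t)M * 144);
    tj.set_size((size_t)M * 144);
    tx.set_size((size_t)M * 144);
  }
  size_t pos = 0;

  for (int e = 0; e < M; ++e) {
    arma::ivec4 nd;
    for (int a = 0; a < 4; ++a) nd(a) = tets(e, a);
    arma::mat33 J;  // edge matrix, columns x_a - x_1, a = 2..4
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        J(i, a) = nodes(nd(a + 1), i) - nodes(nd(0), i);
    const double detJ = arma::det(J);
    if (detJ <= 0.0) stop("degenerate or inverted reference tetrahedron");
    const double vol = detJ / 6.0;
    arma::mat33 Jinv = arma::inv(J);
    arma::mat gradN(4, 3);  // rows: shape-function gradients
    for (int i = 0; i < 3; ++i) {
      gradN(1, i) = Jinv(0, i);
      gradN(2, i) = Jinv(1, i);
      gradN(3, i) = Jinv(2, i);
    }
    for (int i = 0; i < 3; ++i)
      gradN(0, i) = -(gradN(1, i) + gradN(2, i) + gradN(3, i));

    arma::mat33 F(arma::fill::eye);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int Jd = 0; Jd < 3; ++Jd)
          F(i, Jd) += u(3 * nd(a) + i) * gradN(a, Jd);

    double W;
    arma::mat33 P;
    arma::mat A;
    if (!point_PA(F, h, want_tangent, W, P, A))
      return List::create(_["ok"] = false, _["element"] = e + 1);

    energy += vol * W;
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double r = 0.0;
        for (int Jd = 0; Jd < 3; ++Jd) r += P(i, Jd) * gradN(a, Jd);
        fint(3 * nd(a) + i) += vol * r;
      }

    if (want_tangent) {
      for (int a = 0; a < 4; ++a) for (int i = 0; i < 3; ++i)
        for (int b = 0; b < 4; ++b) for (int j = 0; j < 3; ++j) {
          double k = 0.0;
          for (int Jd = 0; Jd < 3; ++Jd)
            for (int Bd = 0; Bd < 3; ++Bd)
              k += A(i + 3 * Jd, j + 3 * Bd) * gradN(a, Jd) * gradN(b, Bd);
          ti(pos) = 3 * nd(a) + i + 1;
          tj(pos) = 3 * nd(b) + j + 1;
          tx(pos) = vol * k;
          ++pos;
        }
    }
  }

  List out = List::create(_["ok"] = true, _["energy"] = energy,
                          _["fint"] = wrap(fint));
  if (want_tangent) {
    out["ti"] = wrap(arma::conv_to<arma::vec>::from(ti));
    out["tj"] = wrap(arma::conv_to<arma::vec>::from(tj));
    out["tx"] = wrap(tx);
  }
  return out;
}

// Linear elastic stiffness split K = lambda * K_lam + mu * K_mu for
// constant-strain tetrahedra, returned as two triplet value vectors sharing
// one index pattern. Lets the optimizer reassemble K(E, nu) in O(nnz).
// [[Rcpp::export]]
List cpp_linear_stiffness_parts(const arma::mat &nodes, const arma::imat &tets) {
  const int M = tets.n_rows;
  arma::uvec ti((size_t)M * 144), tj((size_t)M * 144);
  arma::vec xlam((size_t)M * 144), xmu((size_t)M * 144);
  size_t pos = 0;
  for (int e = 0; e < M; ++e) {
    arma::ivec4 nd;
    for (int a = 0; a < 4; ++a) nd(a) = tets(e, a);
    arma::mat33 J;
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        J(i, a) = nodes(nd(a + 1), i) - nodes(nd(0), i);
    const double detJ = arma::det(J);
    if (detJ <= 0.0) stop("degenerate or inverted tetrahedron");
    const double vol = detJ / 6.0;
    arma::mat33 Jinv = arma::inv(J);
    arma::mat gradN(4, 3);
    for (int i = 0; i < 3; ++i) {
      gradN(1, i) = Jinv(0, i);
      gradN(2, i) = Jinv(1, i);
      gradN(3, i) = Jinv(2, i);
      gradN(0, i) = -(Jinv(0, i) + Jinv(1, i) + Jinv(2, i));
    }
    // K_lam[(a,i),(b,j)] = V gN_a,i gN_b,j
    // K_mu [(a,i),(b,j)] = V (gN_a,j gN_b,i + delta_ij sum_k gN_a,k gN_b,k)
    for (int a = 0; a < 4; ++a) for (int i = 0; i < 3; ++i)
      for (int b = 0; b < 4; ++b) for (int j = 0; j < 3; ++j) {
        double dot = 0.0;
        for (int k = 0; k < 3; ++k) dot += gradN(a, k) * gradN(b, k);
        ti(pos) = 3 * nd(a) + i + 1;
        tj(pos) = 3 * nd(b) + j + 1;
        xlam(pos) = vol * gradN(a, i) * gradN(b, j);
        xmu(pos) = vol * (gradN(a, j) * gradN(b, i) + (i == j) * dot);
        ++pos;
      }
  }
  return List::create(
      _["ti"] = wrap(arma::conv_to<arma::vec>::from(ti)),
      _["tj"] = wrap(arma::conv_to<arma::vec>::from(tj)),
      _["xlam"] = wrap(xlam), _["xmu"] = wrap(xmu));
}
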