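// Element assembly kernels for the corneal FEM: internal force and
// consistent tangent of 8-node trilinear hexahedra with mean-dilatation
// (B-bar) treatment, follower pressure loads with load stiffness, and the
// Gauss-point constitutive update (Mooney-Rivlin matrix + Holzapfel fiber
// families, quasi-incompressible penalty).  Mirrors the R reference
// implementation in R/constitutive.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int VI[6] = {0, 1, 2, 0, 1, 0};
static const int VJ[6] = {0, 1, 2, 1, 2, 2};

// Voigt vector of a symmetric matrix (order 11,22,33,12,23,13)
static inline arma::vec6 to_voigt(const arma::mat33 &A) {
  arma::vec6 v;
  for (int I = 0; I < 6; ++I) v(I) = A(VI[I], VJ[I]);
  return v;
}

// Voigt matrix of the symmetrized product (A (x) A)
static void voigt_sym_outer(const arma::mat33 &A, arma::mat66 &D) {
  for (int I = 0; I < 6; ++I)
    for (int J = 0; J < 6; ++J) {
      int i = VI[I], j = VJ[I], k = VI[J], l = VJ[J];
      D(I, J) = 0.5 * (A(i, k) * A(j, l) + A(i, l) * A(j, k));
    }
}

struct MatParams {
  double a1, a2, k1, k2, k0;
  bool active2, tension_only;
};

// fiber energy derivatives: d1 = dpsi/dI4, d2 = d2psi/dI4^2
static inline void fiber_dpsi(double I4, double k1, double k2,
                              bool tension_only, double &d1, double &d2) {
  double w = I4 - 1.0;
  if (tension_only && w <= 0.0) { d1 = d2 = 0.0; return; }
  double ex = k2 * w * w;
  if (ex > 500.0) stop("fiber overextension: I4 = %f", I4);
  double e = std::exp(ex);
  d1 = k1 * w * e;
  d2 = k1 * e * (1.0 + 2.0 * k2 * w * w);
}

// Cauchy stress (Voigt) and spatial tangent D = c_tau / J at deformation F
static void constitutive(const arma::mat33 &F, const MatParams &p,
                         const arma::vec3 &m0, const arma::vec3 &n0,
                         arma::vec6 &sigv, arma::mat66 &D, bool wantD,
                         double &Jout) {
  double J = arma::det(F);
  if (!(J > 0.0)) stop("non-positive det(F) in constitutive update");
  Jout = J;
  double Jm13 = std::pow(J, -1.0 / 3.0);
  arma::mat33 Fb = Jm13 * F;
  arma::mat33 bb = Fb * Fb.t();
  arma::mat33 bb2 = bb * bb;
  double I1 = arma::trace(bb);
  arma::vec3 m = Fb * m0, n = Fb * n0;
  double I4 = arma::dot(m, m);
  double I6 = arma::dot(n, n);

  double p4a, p4b, p6a = 0.0, p6b = 0.0;
  fiber_dpsi(I4, p.k1, p.k2, p.tension_only, p4a, p4b);
  if (p.active2) fiber_dpsi(I6, p.k1, p.k2, p.tension_only, p6a, p6b);

  arma::mat33 mm = m * m.t();
  arma::mat33 nn = n * n.t();
  arma::mat33 S = (p.a1 + I1 * p.a2) * bb - p.a2 * bb2 + p4a * mm + p6a * nn;
  double trS = arma::trace(S);
  arma::mat33 dev = S;
  dev.diag() -= trS / 3.0;
  arma::mat33 sig = (2.0 / J) * dev;
  sig.diag() += p.k0 * (J - 1.0);
  sigv = to_voigt(sig);

  if (!wantD) return;

  // fictitious Kirchhoff stress tau~ = 2 S, its deviator
  double tr_tau = 2.0 * trS;
  arma::mat33 tau_iso = 2.0 * dev;

  arma::vec6 vb = to_voigt(bb);
  arma::vec6 v4 = to_voigt(mm);
  arma::vec6 v6 = to_voigt(nn);
  arma::mat66 sy;
  voigt_sym_outer(bb, sy);
  arma::mat66 ct = 4.0 * (p.a2 * (vb * vb.t() - sy) +
                          p4b * (v4 * v4.t()) + p6b * (v6 * v6.t()));

  arma::vec6 one = {1, 1, 1, 0, 0, 0};
  arma::mat66 Is = arma::diagmat(arma::vec6({1, 1, 1, 0.5, 0.5, 0.5}));
  arma::mat66 P = Is - (one * one.t()) / 3.0;
  arma::mat66 W = arma::diagmat(arma::vec6({1, 1, 1, 2, 2, 2}));
  arma::vec6 vt = to_voigt(tau_iso);
  arma::mat66 c_iso = P * W * ct * W * P + (2.0 / 3.0) * tr_tau * P -
    (2.0 / 3.0) * (one * vt.t() + vt * one.t());

  double p1 = p.k0 * (J - 1.0);
  arma::mat66 c_vol = (J * p1 + J * J * p.k0) * (one * one.t()) -
    2.0 * J * p1 * Is;

  D = (c_vol + c_iso) / J;
}

// trilinear shape gradients wrt local coords at gp: dN (8 x 3)
static void hex_dN(double xi, double eta, double zet, mat &dN) {
  static const double cx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  static const double cy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  static const double cz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = cx[a] * (1 + eta * cy[a]) * (1 + zet * cz[a]) / 8.0;
    dN(a, 1) = cy[a] * (1 + xi * cx[a]) * (1 + zet * cz[a]) / 8.0;
    dN(a, 2) = cz[a] * (1 + xi * cx[a]) * (1 + eta * cy[a]) / 8.0;
  }
}

// [[Rcpp::export(name = ".asm_system")]]
List asm_system(const arma::mat &nodes, const arma::mat &u,
                const arma::imat &elems, const arma::mat &mat_par,
                const arma::mat &fibers, const arma::ivec &active2,
                Nullable<NumericMatrix> Fpre_, bool bbar, bool tension_only,
                bool want_tangent, bool want_state) {
  const int E = elems.n_rows, N = nodes.n_rows;
  const double g = 1.0 / std::sqrt(3.0);
  mat dN(8, 3);
  arma::cube dNg(8, 3, 8);
  int gp = 0;
  for (int kz = 0; kz < 2; ++kz)
    for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx) {
        hex_dN(kx ? g : -g, ky ? g : -g, kz ? g : -g, dN);
        dNg.slice(gp++) = dN;
      }

  bool has_pre = Fpre_.isNotNull();
  arma::mat Fpre;
  if (has_pre) Fpre = as<arma::mat>(Fpre_.get());   // E x 72

  vec fint(3 * N, arma::fill::zeros);
  IntegerVector Ki, Kj;
  NumericVector Kv;
  if (want_tangent) {
    Ki = IntegerVector(E * 576);
    Kj = IntegerVector(E * 576);
    Kv = NumericVector(E * 576);
  }
  NumericMatrix Ftot_out, sig_out;
  NumericMatrix Jout;
  if (want_state) {
    Ftot_out = NumericMatrix(E, 72);
    sig_out = NumericMatrix(E, 48);
    Jout = NumericMatrix(E, 8);
  }

  mat Xe(8, 3), xe(8, 3);
  arma::mat33 JacX, Jac, Finc, Ft, Fm;
  arma::mat66 D;
  arma::vec6 sigv;
  mat gradN(8, 3), gradNr(8, 3);
  mat Ke(24, 24);
  vec fe(24);

  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      Xe.row(a) = nodes.row(n);
      xe.row(a) = nodes.row(n) + u.row(n);
    }
    MatParams p;
    p.a1 = mat_par(e, 0); p.a2 = mat_par(e, 1); p.k1 = mat_par(e, 2);
    p.k2 = mat_par(e, 3); p.k0 = mat_par(e, 4);
    p.active2 = active2(e) != 0;
    p.tension_only = tension_only;
    arma::vec3 m0 = {fibers(e, 0), fibers(e, 1), fibers(e, 2)};
    arma::vec3 n0 = {fibers(e, 3), fibers(e, 4), fibers(e, 5)};

    // pass 1: kinematics per GP, element-average dilatation and gradients
    arma::cube Fg(3, 3, 8);
    vec Jg(8), wcur(8), wref(8);
    arma::cube gNg(8, 3, 8);
    mat gbar(8, 3, arma::fill::zeros);
    double Jbar_num = 0.0, Jbar_den = 0.0;
    for (int q = 0; q < 8; ++q) {
      const mat &d = dNg.slice(q);
      JacX = Xe.t() * d;        // dX/dxi
      Jac = xe.t() * d;         // dx/dxi
      double detX = arma::det(JacX), detx = arma::det(Jac);
      if (detX <= 0.0 || detx <= 0.0)
        stop("element inversion during update (element %d)", e + 1);
      Finc = Jac * arma::inv(JacX);
      Ft = Finc;
      if (has_pre) {
        arma::mat33 Fp;
        for (int c = 0; c < 3; ++c)
          for (int r = 0; r < 3; ++r)
            Fp(r, c) = Fpre(e, q * 9 + c * 3 + r);
        Ft = Finc * Fp;
      }
      Fg.slice(q) = Ft;
      Jg(q) = arma::det(Ft);
      wref(q) = detX;
      wcur(q) = detx;
      gNg.slice(q) = d * arma::inv(Jac);   // grad_x N (8 x 3)
      gbar += gNg.slice(q) * detx;
      Jbar_num += Jg(q) * detX;
      Jbar_den += detX;
    }
    double vol_cur = arma::accu(wcur);
    gbar /= vol_cur;
    double Jbar = Jbar_num / Jbar_den;

    fe.zeros();
    if (want_tangent) Ke.zeros();

    for (int q = 0; q < 8; ++q) {
      Ft = Fg.slice(q);
      double Jq = Jg(q);
      Fm = Ft;
      if (bbar) Fm = std::pow(Jbar / Jq, 1.0 / 3.0) * Ft;
      double Jused;
      constitutive(Fm, p, m0, n0, sigv, D, want_tangent, Jused);

      if (want_state) {
        for (int c = 0; c < 3; ++c)
          for (int r = 0; r < 3; ++r)
            Ftot_out(e, q * 9 + c * 3 + r) = Ft(r, c);
        for (int I = 0; I < 6; ++I) sig_out(e, q * 6 + I) = sigv(I);
        Jout(e, q) = Jused;
      }

      const mat &gN = gNg.slice(q);
      double w = wcur(q);
      // internal force f = B-bar^T sigma * w; mean dilatation adds
      // (gbar_i - g_i)/3 to every normal row of displacement component i
      double str = sigv(0) + sigv(1) + sigv(2);
      for (int a = 0; a < 8; ++a) {
        double gx = gN(a, 0), gy = gN(a, 1), gz = gN(a, 2);
        double e1 = bbar ? (gbar(a, 0) - gx) / 3.0 : 0.0;
        double e2 = bbar ? (gbar(a, 1) - gy) / 3.0 : 0.0;
        double e3 = bbar ? (gbar(a, 2) - gz) / 3.0 : 0.0;
        fe(3 * a + 0) += w * (gx * sigv(0) + e1 * str +
                              gy * sigv(3) + gz * sigv(5));
        fe(3 * a + 1) += w * (gy * sigv(1) + e2 * str +
                              gx * sigv(3) + gz * sigv(4));
        fe(3 * a + 2) += w * (gz * sigv(2) + e3 * str +
                              gy * sigv(4) + gx * sigv(5));
      }

      if (want_tangent) {
        // form full B-bar matrix (6 x 24)
        mat B(6, 24, arma::fill::zeros);
        for (int a = 0; a < 8; ++a) {
          double gx = gN(a, 0), gy = gN(a, 1), gz = gN(a, 2);
          double e1 = bbar ? (gbar(a, 0) - gx) / 3.0 : 0.0;
          double e2 = bbar ? (gbar(a, 1) - gy) / 3.0 : 0.0;
          double e3 = bbar ? (gbar(a, 2) - gz) / 3.0 : 0.0;
          B(0, 3 * a + 0) = gx + e1; B(1, 3 * a + 0) = e1; B(2, 3 * a + 0) = e1;
          B(0, 3 * a + 1) = e2; B(1, 3 * a + 1) = gy + e2; B(2, 3 * a + 1) = e2;
          B(0, 3 * a + 2) = e3; B(1, 3 * a + 2) = e3; B(2, 3 * a + 2) = gz + e3;
          B(3, 3 * a + 0) = gy; B(3, 3 * a + 1) = gx;
          B(4, 3 * a + 1) = gz; B(4, 3 * a + 2) = gy;
          B(5, 3 * a + 0) = gz; B(5, 3 * a + 2) = gx;
        }
        Ke += w * (B.t() * D * B);
        // geometric (initial stress) term
        arma::mat33 sig;
        for (int I = 0; I < 6; ++I) {
          sig(VI[I], VJ[I]) = sigv(I);
          sig(VJ[I], VI[I]) = sigv(I);
        }
        mat gs = gN * sig;      // 8 x 3
        mat G = gs * gN.t();    // 8 x 8 : gradN_a . sig . gradN_b
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double v = w * G(a, b);
            Ke(3 * a, 3 * b) += v;
            Ke(3 * a + 1, 3 * b + 1) += v;
            Ke(3 * a + 2, 3 * b + 2) += v;
          }
      }
    }

    // scatter
    for (int a = 0; a < 8; ++a) {
      int na = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) fint(3 * na + i) += fe(3 * a + i);
    }
    if (want_tangent) {
      int base = e * 576, c = 0;
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          int row = 3 * (elems(e, a) - 1) + i + 1;
          for (int b = 0; b < 8; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki[base + c] = row;
              Kj[base + c] = 3 * (elems(e, b) - 1) + j + 1;
              Kv[base + c] = Ke(3 * a + i, 3 * b + j);
              ++c;
            }
        }
    }
  }

  List out = List::create(_["fint"] = fint);
  if (want_tangent) {
    out["Ki"] = Ki; out["Kj"] = Kj; out["Kv"] = Kv;
  }
  if (want_state) {
    out["Ftot"] = Ftot_out; out["sigma"] = sig_out; out["J"] = Jout;
  }
  return out;
}

// Follower pressure on bilinear quad facets.  Facet node order gives the
// solid-outward normal; the applied nodal force is -p * n * da (pressure
// compresses the solid).  Returns the force vector and, optionally, the
// load-stiffness triplets dfext/du.
// [[Rcpp::export(name = ".asm_pressure")]]
List asm_pressure(const arma::mat &nodes, const arma::mat &u,
                  const arma::imat &facets, double p, bool want_tangent) {
  const int Fn = facets.n_rows, N = nodes.n_rows;
  const double g = 1.0 / std::sqrt(3.0);
  static const double sx[4] = {-1, 1, 1, -1};
  static const double sy[4] = {-1, -1, 1, 1};
  vec fext(3 * N, arma::fill::zeros);
  IntegerVector Ki, Kj;
  NumericVector Kv;
  if (want_tangent) {
    Ki = IntegerVector(Fn * 144); Kj = IntegerVector(Fn * 144);
    Kv = NumericVector(Fn * 144);
  }
  mat xe(4, 3);
  mat Ke(12, 12);
  for (int f = 0; f < Fn; ++f) {
    for (int a = 0; a < 4; ++a) {
      int n = facets(f, a) - 1;
      xe.row(a) = nodes.row(n) + u.row(n);
    }
    vec fe(12, arma::fill::zeros);
    if (want_tangent) Ke.zeros();
    for (int q = 0; q < 4; ++q) {
      double xi = (q % 2) ? g : -g;
      double eta = (q / 2) ? g : -g;
      vec Nq(4), dXi(4), dEta(4);
      for (int a = 0; a < 4; ++a) {
        Nq(a) = (1 + xi * sx[a]) * (1 + eta * sy[a]) / 4.0;
        dXi(a) = sx[a] * (1 + eta * sy[a]) / 4.0;
        dEta(a) = sy[a] * (1 + xi * sx[a]) / 4.0;
      }
      arma::vec3 a1 = xe.t() * dXi, a2 = xe.t() * dEta;
      arma::vec3 cr = arma::cross(a1, a2);
      if (arma::norm(cr) < 1e-30)
        stop("degenerate (zero-area) deformed facet %d", f + 1);
      for (int a = 0; a < 4; ++a)
        fe.subvec(3 * a, 3 * a + 2) += -p * Nq(a) * cr;
      if (want_tangent) {
        arma::mat33 X1 = {{0, -a1(2), a1(1)}, {a1(2), 0, -a1(0)},
                          {-a1(1), a1(0), 0}};
        arma::mat33 X2 = {{0, -a2(2), a2(1)}, {a2(2), 0, -a2(0)},
                          {-a2(1), a2(0), 0}};
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            // d fe_a / d u_b = -p N_a (dEta_b [a1]x - dXi_b [a2]x)
            arma::mat33 blk = -p * Nq(a) * (dEta(b) * X1 - dXi(b) * X2);
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Ke(3 * a + i, 3 * b + j) += blk(i, j);
          }
      }
    }
    for (int a = 0; a < 4; ++a) {
      int na = facets(f, a) - 1;
      for (int i = 0; i < 3; ++i) fext(3 * na + i) += fe(3 * a + i);
    }
    if (want_tangent) {
      int base = f * 144, c = 0;
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki[base + c] = 3 * (facets(f, a) - 1) + i + 1;
              Kj[base + c] = 3 * (facets(f, b) - 1) + j + 1;
              Kv[base + c] = Ke(3 * a + i, 3 * b + j);
              ++c;
            }
    }
  }
  List out = List::create(_["fext"] = fext);
  if (want_tangent) {
    out["Ki"] = Ki; out["Kj"] = Kj; out["Kv"] = Kv;
  }
  return out;
}
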