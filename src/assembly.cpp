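// Finite-element assembly kernels: static finite-strain solid mechanics with
// a mixed displacement / nodal-pressure formulation (average nodal pressure
// tetrahedron, anti-locking for linear tets), equal-order stabilized
// incompressible flow, and scalar Laplace systems.
//
// All kernels take node coordinates in metres, 1-based tet connectivity, and
// return residuals / sparse triplets (1-based) for assembly with Matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ElemGeom {
  arma::mat G;      // 4 x 3 shape gradients
  double V0;        // reference volume
};

// Reference geometry of one tet; grads g_i with F = I + sum_i u_i g_i^T.
inline bool elem_geom(const arma::mat &X, const arma::Mat<int> &E, int e,
                      ElemGeom &out) {
  arma::mat33 Dm;
  const int n0 = E(e, 0), n1 = E(e, 1), n2 = E(e, 2), n3 = E(e, 3);
  for (int c = 0; c < 3; ++c) {
    Dm(c, 0) = X(n1, c) - X(n0, c);
    Dm(c, 1) = X(n2, c) - X(n0, c);
    Dm(c, 2) = X(n3, c) - X(n0, c);
  }
  const double det = arma::det(Dm);
  if (det <= 0.0) return false;
  out.V0 = det / 6.0;
  arma::mat33 Bm = arma::inv(Dm);
  out.G.set_size(4, 3);
  for (int j = 0; j < 3; ++j) {
    out.G(1, j) = Bm(0, j);
    out.G(2, j) = Bm(1, j);
    out.G(3, j) = Bm(2, j);
    out.G(0, j) = -(Bm(0, j) + Bm(1, j) + Bm(2, j));
  }
  return true;
}

inline arma::mat33 def_grad(const arma::mat &U, const arma::Mat<int> &E,
                            int e, const ElemGeom &g) {
  arma::mat33 F(arma::fill::eye);
  for (int i = 0; i < 4; ++i) {
    const int n = E(e, i);
    for (int k = 0; k < 3; ++k)
      for (int l = 0; l < 3; ++l)
        F(k, l) += U(n, k) * g.G(i, l);
  }
  return F;
}

}  // namespace

// Mixed residual/tangent for the tissue-artery solid.
//   u: nn x 3 displacements; pnod: nn nodal pressures (tissue nodes only)
//   c1, kappa: per-element C1 (Pa) and NODAL-part bulk modulus (Pa)
//   kloc: per-element local volumetric stiffness (Pa) applied in parallel
//         with the nodal term; stabilizes spurious nodal-pressure modes on
//         thin/constrained meshes (small relative to kappa, no locking)
//   nodal_vol: TRUE -> mixed nodal-pressure volumetric treatment (tissue);
//              FALSE -> local displacement-based volumetric term (wall)
// Dof numbering in the triplets: velocity-style u dofs 3*(node-1)+k,
// pressure dofs 3*nn + node (1-based).
// Pressure residual rows: r_p(a) = V0_a * (Jbar_a - 1 - p_a / kappa_a).
// [[Rcpp::export]]
List solid_system(const arma::mat &coords, const arma::Mat<int> &elems1,
                  const arma::mat &u, const arma::vec &pnod,
                  const arma::vec &c1, const arma::vec &kappa,
                  const arma::vec &kloc, const arma::uvec &nodal_vol,
                  bool want_tangent, bool want_fields) {
  const int nn = coords.n_rows, ne = elems1.n_rows;
  arma::Mat<int> E(elems1);
  E -= 1;

  std::vector<ElemGeom> geo(ne);
  arma::vec J(ne);
  arma::cube Fs(3, 3, ne);
  arma::vec nodeV(nn, arma::fill::zeros), nodeJV(nn, arma::fill::zeros);
  arma::vec nodeK(nn, arma::fill::zeros);

  for (int e = 0; e < ne; ++e) {
    if (!elem_geom(coords, E, e, geo[e]))
      return List::create(_["inverted"] = true, _["element"] = e + 1);
    arma::mat33 F = def_grad(u, E, e, geo[e]);
    const double Je = arma::det(F);
    if (Je <= 0.0)
      return List::create(_["inverted"] = true, _["element"] = e + 1);
    Fs.slice(e) = F;
    J(e) = Je;
    if (nodal_vol(e)) {
      const double w = geo[e].V0 / 4.0;
      for (int i = 0; i < 4; ++i) {
        nodeV(E(e, i)) += w;
        nodeJV(E(e, i)) += w * Je;
        nodeK(E(e, i)) += w * kappa(e);
      }
    }
  }

  arma::vec Jbar(nn, arma::fill::ones), kbar(nn, arma::fill::zeros);
  for (int a = 0; a < nn; ++a)
    if (nodeV(a) > 0) {
      Jbar(a) = nodeJV(a) / nodeV(a);
      kbar(a) = nodeK(a) / nodeV(a);
    }

  double energy = 0.0;   // physical strain energy (penalty form), diagnostics
  arma::mat grad(nn, 3, arma::fill::zeros);
  arma::vec rp(nn, arma::fill::zeros);
  for (int a = 0; a < nn; ++a)
    if (nodeV(a) > 0) {
      const double d = Jbar(a) - 1.0;
      energy += nodeV(a) * 0.5 * kbar(a) * d * d;
      rp(a) = nodeV(a) * (d - pnod(a) / kbar(a));
    }

  arma::vec vm, pout;
  if (want_fields) { vm.zeros(ne); pout.zeros(ne); }

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    const size_t cap = (size_t)ne * 240 + nn;
    ti.reserve(cap); tj.reserve(cap); tx.reserve(cap);
    for (int a = 0; a < nn; ++a)
      if (nodeV(a) > 0) {
        ti.push_back(3 * nn + a + 1);
        tj.push_back(3 * nn + a + 1);
        tx.push_back(-nodeV(a) / kbar(a));
      }
  }

  for (int e = 0; e < ne; ++e) {
    const ElemGeom &g = geo[e];
    const arma::mat33 F = Fs.slice(e);
    const double Je = J(e);
    const arma::mat33 a = arma::inv(F).t();   // F^{-T}
    const double I1 = arma::accu(F % F);
    const double Jm23 = std::pow(Je, -2.0 / 3.0);

    energy += g.V0 * c1(e) * (Jm23 * I1 - 3.0);
    arma::mat33 Pdev = 2.0 * c1(e) * Jm23 * (F - (I1 / 3.0) * a);

    // pressure entering the stress: nodal mean (tissue, plus the local
    // stabilization penalty) or purely local (wall)
    double pe, Upp_local;
    bool mixed = nodal_vol(e) != 0;
    const double d = Je - 1.0;
    if (mixed) {
      pe = kloc(e) * d;
      for (int i = 0; i < 4; ++i) pe += 0.25 * pnod(E(e, i));
      energy += g.V0 * 0.5 * kloc(e) * d * d;
      Upp_local = kloc(e);
    } else {
      energy += g.V0 * 0.5 * kappa(e) * d * d;
      pe = kappa(e) * d;
      Upp_local = kappa(e);
    }
    arma::mat33 P = Pdev + pe * Je * a;

    for (int i = 0; i < 4; ++i) {
      const int n = E(e, i);
      for (int k = 0; k < 3; ++k) {
        double s = 0.0;
        for (int l = 0; l < 3; ++l) s += P(k, l) * g.G(i, l);
        grad(n, k) += g.V0 * s;
      }
    }

    if (want_fields) {
      arma::mat33 sig = (P * F.t()) / Je;
      arma::mat33 dev = sig - (arma::trace(sig) / 3.0) * arma::mat33(arma::fill::eye);
      vm(e) = std::sqrt(1.5 * arma::accu(dev % dev));
      pout(e) = pe;
    }

    if (want_tangent) {
      arma::mat w(4, 3), s4(4, 3);   // w_i = F^{-T} g_i, s_i = F g_i
      for (int i = 0; i < 4; ++i)
        for (int k = 0; k < 3; ++k) {
          double sw = 0.0, ss = 0.0;
          for (int l = 0; l < 3; ++l) {
            sw += a(k, l) * g.G(i, l);
            ss += F(k, l) * g.G(i, l);
          }
          w(i, k) = sw; s4(i, k) = ss;
        }
      const double cdev = 2.0 * c1(e) * Jm23;
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          const double dij = arma::dot(g.G.row(i), g.G.row(j));
          for (int k = 0; k < 3; ++k)
            for (int m = 0; m < 3; ++m) {
              double v = cdev * ((k == m ? dij : 0.0)
                           - (2.0 / 3.0) * (w(j, m) * s4(i, k) + s4(j, m) * w(i, k))
                           + (2.0 * I1 / 9.0) * w(i, k) * w(j, m)
                           + (I1 / 3.0) * w(i, m) * w(j, k));
              // geometric stiffness of the pressure term (d2J)
              v += pe * Je * (w(i, k) * w(j, m) - w(j, k) * w(i, m));
              // local volumetric material stiffness
              v += Upp_local * Je * Je * w(i, k) * w(j, m);
              // push unconditionally: a value-independent sparsity pattern
              // lets the driver cache the CSC slot mapping across iterations
              ti.push_back(3 * E(e, i) + k + 1);
              tj.push_back(3 * E(e, j) + m + 1);
              tx.push_back(v * g.V0);
            }
        }
      if (mixed) {
        // coupling: dJ_e/du distributed with weight V0/4 to each node's
        // pressure row/column; h = J * F^{-T} g
        for (int i = 0; i < 4; ++i)
          for (int k = 0; k < 3; ++k) {
            const double h = g.V0 / 4.0 * Je * w(i, k);
            for (int j = 0; j < 4; ++j) {
              ti.push_back(3 * E(e, i) + k + 1);      // K_up
              tj.push_back(3 * nn + E(e, j) + 1);
              tx.push_back(h);
              ti.push_back(3 * nn + E(e, j) + 1);     // K_pu
              tj.push_back(3 * E(e, i) + k + 1);
              tx.push_back(h);
            }
          }
      }
    }
  }

  List out = List::create(_["inverted"] = false, _["energy"] = energy,
                          _["grad"] = grad, _["rp"] = rp,
                          _["J"] = J, _["Jbar"] = Jbar,
                          _["has_pressure"] = nodeV, _["kbar"] = kbar);
  if (want_fields) { out["von_mises"] = vm; out["pressure"] = pout; }
  if (want_tangent) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// Equal-order (P1/P1) stabilized incompressible flow system. Velocity dofs
// are 3*(node-1)+k (k=1..3), pressure dofs 3*nn + node. Convection is
// linearized about ustar (Picard); PSPG pressure stabilization throughout.
// [[Rcpp::export]]
List flow_system(const arma::mat &coords, const arma::Mat<int> &elems1,
                 const arma::mat &ustar, double mu, double rho,
                 bool convection) {
  const int nn = coords.n_rows, ne = elems1.n_rows;
  arma::Mat<int> E(elems1);
  E -= 1;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * 220); tj.reserve((size_t)ne * 220);
  tx.reserve((size_t)ne * 220);

  for (int e = 0; e < ne; ++e) {
    ElemGeom g;
    if (!elem_geom(coords, E, e, g))
      stop("flow assembly: element %d has non-positive volume", e + 1);
    const double V = g.V0;
    const double h = std::cbrt(6.0 * V);
    arma::vec3 ubar(arma::fill::zeros);
    if (convection)
      for (int i = 0; i < 4; ++i)
        for (int k = 0; k < 3; ++k) ubar(k) += 0.25 * ustar(E(e, i), k);
    const double unorm = arma::norm(ubar);
    const double inv_d = 12.0 * mu / (h * h);
    const double inv_c = convection ? 2.0 * rho * unorm / h : 0.0;
    const double tau = 1.0 / std::sqrt(inv_d * inv_d + inv_c * inv_c);

    arma::vec4 adv;
    for (int i = 0; i < 4; ++i)
      adv(i) = convection ? arma::dot(ubar, g.G.row(i).t()) : 0.0;

    for (int i = 0; i < 4; ++i) {
      const int ni = E(e, i);
      for (int j = 0; j < 4; ++j) {
        const int nj = E(e, j);
        const double dij = arma::dot(g.G.row(i), g.G.row(j));
        // momentum: viscous + convective Galerkin + SUPG streamline term
        const double mom = mu * V * dij + rho * V * adv(j) / 4.0
          + tau * rho * rho * V * adv(i) * adv(j);
        for (int k = 0; k < 3; ++k) {
          ti.push_back(3 * ni + k + 1);
          tj.push_back(3 * nj + k + 1);
          tx.push_back(mom);
        }
        for (int k = 0; k < 3; ++k) {
          // pressure gradient on momentum rows: -int p div v, plus SUPG
          ti.push_back(3 * ni + k + 1);
          tj.push_back(3 * nn + nj + 1);
          tx.push_back(-V * g.G(i, k) / 4.0
                       + tau * rho * V * adv(i) * g.G(j, k));
          // continuity rows: int q div u, plus PSPG convection
          ti.push_back(3 * nn + nj + 1);
          tj.push_back(3 * ni + k + 1);
          tx.push_back(V * g.G(i, k) / 4.0 + tau * rho * V * g.G(j, k) * adv(i));
        }
        // PSPG pressure-pressure block
        ti.push_back(3 * nn + ni + 1);
        tj.push_back(3 * nn + nj + 1);
        tx.push_back(tau * V * dij);
      }
    }
  }
  return List::create(_["ti"] = IntegerVector(ti.begin(), ti.end()),
                      _["tj"] = IntegerVector(tj.begin(), tj.end()),
                      _["tx"] = NumericVector(tx.begin(), tx.end()),
                      _["ndof"] = 4 * nn);
}

// Scalar Laplace stiffness (for harmonic mesh morphing).
// [[Rcpp::export]]
List laplace_system(const arma::mat &coords, const arma::Mat<int> &elems1) {
  const int ne = elems1.n_rows;
  arma::Mat<int> E(elems1);
  E -= 1;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * 16); tj.reserve((size_t)ne * 16);
  tx.reserve((size_t)ne * 16);
  for (int e = 0; e < ne; ++e) {
    ElemGeom g;
    if (!elem_geom(coords, E, e, g))
      stop("laplace assembly: element %d has non-positive volume", e + 1);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        ti.push_back(E(e, i) + 1);
        tj.push_back(E(e, j) + 1);
        tx.push_back(g.V0 * arma::dot(g.G.row(i), g.G.row(j)));
      }
  }
  return List::create(_["ti"] = IntegerVector(ti.begin(), ti.end()),
                      _["tj"] = IntegerVector(tj.begin(), tj.end()),
                      _["tx"] = NumericVector(tx.begin(), tx.end()));
}
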