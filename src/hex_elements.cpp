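// Trilinear (8-node) and serendipity quadratic (20-node) hexahedral
// elements for small-strain linear elasticity.  Voigt order throughout:
// (xx, yy, zz, yz, xz, xy) with engineering shear strains.  Node ordering
// follows the VTK hexahedron conventions (types 12 and 25).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double H8_XI[8]  = {-1,  1,  1, -1, -1,  1, 1, -1};
const double H8_ETA[8] = {-1, -1,  1,  1, -1, -1, 1,  1};
const double H8_ZE[8]  = {-1, -1, -1, -1,  1,  1, 1,  1};

// VTK-25 mid-edge natural coordinates (nodes 8..19)
const int H20_EDGE[12][2] = {
  {0, 1}, {1, 2}, {2, 3}, {3, 0},
  {4, 5}, {5, 6}, {6, 7}, {7, 4},
  {0, 4}, {1, 5}, {2, 6}, {3, 7}};

// Shape function derivatives (and values) at a natural point.
// dN is nn x 3, N length nn.
void shape_h8(double xi, double eta, double ze, arma::mat &dN, arma::vec &N) {
  for (int a = 0; a < 8; ++a) {
    const double sx = H8_XI[a], sy = H8_ETA[a], sz = H8_ZE[a];
    N(a)     = 0.125 * (1 + sx * xi) * (1 + sy * eta) * (1 + sz * ze);
    dN(a, 0) = 0.125 * sx * (1 + sy * eta) * (1 + sz * ze);
    dN(a, 1) = 0.125 * (1 + sx * xi) * sy * (1 + sz * ze);
    dN(a, 2) = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz;
  }
}

void shape_h20(double xi, double eta, double ze, arma::mat &dN, arma::vec &N) {
  // corners
  for (int a = 0; a < 8; ++a) {
    const double sx = H8_XI[a], sy = H8_ETA[a], sz = H8_ZE[a];
    const double px = 1 + sx * xi, py = 1 + sy * eta, pz = 1 + sz * ze;
    const double q = sx * xi + sy * eta + sz * ze - 2.0;
    N(a)     = 0.125 * px * py * pz * q;
    dN(a, 0) = 0.125 * sx * py * pz * (q + px);
    dN(a, 1) = 0.125 * px * sy * pz * (q + py);
    dN(a, 2) = 0.125 * px * py * sz * (q + pz);
  }
  // mid-edge nodes: natural coords are the mean of the edge's corners,
  // one of (xi, eta, ze) coordinates is zero there.
  for (int m = 0; m < 12; ++m) {
    const int a = H20_EDGE[m][0], b = H20_EDGE[m][1];
    const double cx = 0.5 * (H8_XI[a] + H8_XI[b]);
    const double cy = 0.5 * (H8_ETA[a] + H8_ETA[b]);
    const double cz = 0.5 * (H8_ZE[a] + H8_ZE[b]);
    const int k = 8 + m;
    if (cx == 0.0) {
      const double py = 1 + cy * eta, pz = 1 + cz * ze, s = 1 - xi * xi;
      N(k)     = 0.25 * s * py * pz;
      dN(k, 0) = -0.5 * xi * py * pz;
      dN(k, 1) = 0.25 * s * cy * pz;
      dN(k, 2) = 0.25 * s * py * cz;
    } else if (cy == 0.0) {
      const double px = 1 + cx * xi, pz = 1 + cz * ze, s = 1 - eta * eta;
      N(k)     = 0.25 * s * px * pz;
      dN(k, 0) = 0.25 * s * cx * pz;
      dN(k, 1) = -0.5 * eta * px * pz;
      dN(k, 2) = 0.25 * s * px * cz;
    } else {
      const double px = 1 + cx * xi, py = 1 + cy * eta, s = 1 - ze * ze;
      N(k)     = 0.25 * s * px * py;
      dN(k, 0) = 0.25 * s * cx * py;
      dN(k, 1) = 0.25 * s * px * cy;
      dN(k, 2) = -0.5 * ze * px * py;
    }
  }
}

void shape_at(int nn, double xi, double eta, double ze, arma::mat &dN,
              arma::vec &N) {
  if (nn == 8) shape_h8(xi, eta, ze, dN, N);
  else shape_h20(xi, eta, ze, dN, N);
}

struct GaussRule {
  std::vector<double> x, w;  // 1D points and weights
};

GaussRule gauss_rule(int nn) {
  GaussRule g;
  if (nn == 8) {
    const double p = 1.0 / std::sqrt(3.0);
    g.x = {-p, p};
    g.w = {1.0, 1.0};
  } else {
    const double p = std::sqrt(0.6);
    g.x = {-p, 0.0, p};
    g.w = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
  }
  return g;
}

// Strain-displacement matrix (6 x 3nn) from cartesian shape gradients.
void fill_B(const arma::mat &dNx, arma::mat &B) {
  const int nn = dNx.n_rows;
  B.zeros();
  for (int a = 0; a < nn; ++a) {
    const double bx = dNx(a, 0), by = dNx(a, 1), bz = dNx(a, 2);
    const int c = 3 * a;
    B(0, c)     = bx;
    B(1, c + 1) = by;
    B(2, c + 2) = bz;
    B(3, c + 1) = bz;  // gamma_yz
    B(3, c + 2) = by;
    B(4, c)     = bz;  // gamma_xz
    B(4, c + 2) = bx;
    B(5, c)     = by;  // gamma_xy
    B(5, c + 1) = bx;
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".hex_assemble")]]
List hex_assemble(const arma::mat &nodes, const arma::imat &conn,
                  const arma::mat &Cmats) {
  const int ne = conn.n_rows;
  const int nn = conn.n_cols;  // 8 or 20
  if (nn != 8 && nn != 20) stop("connectivity must have 8 or 20 nodes per element");
  if ((int)Cmats.n_rows != 36 || (int)Cmats.n_cols != ne)
    stop("Cmats must be 36 x n_elements");
  const int ndof = 3 * nn;
  const GaussRule g = gauss_rule(nn);
  const int ng1 = g.x.size();

  // precompute shape data at all gauss points
  std::vector<arma::mat> dN_all;
  std::vector<double> w_all;
  arma::vec N(nn);
  for (int i = 0; i < ng1; ++i)
    for (int j = 0; j < ng1; ++j)
      for (int k = 0; k < ng1; ++k) {
        arma::mat dN(nn, 3);
        shape_at(nn, g.x[i], g.x[j], g.x[k], dN, N);
        dN_all.push_back(dN);
        w_all.push_back(g.w[i] * g.w[j] * g.w[k]);
      }
  const int ngp = dN_all.size();

  const R_xlen_t ntrip = (R_xlen_t)ne * ndof * ndof;
  IntegerVector ii(ntrip), jj(ntrip);
  NumericVector xx(ntrip);
  NumericVector vol(ne);
  double min_detJ = R_PosInf;

  arma::mat X(nn, 3), Ke(ndof, ndof), B(6, ndof), dNx(nn, 3), C(6, 6);
  R_xlen_t pos = 0;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < nn; ++a) {
      const int nid = conn(e, a) - 1;
      X(a, 0) = nodes(nid, 0);
      X(a, 1) = nodes(nid, 1);
      X(a, 2) = nodes(nid, 2);
    }
    C = arma::reshape(Cmats.col(e), 6, 6);
    Ke.zeros();
    double ve = 0.0;
    for (int q = 0; q < ngp; ++q) {
      const arma::mat J = dN_all[q].t() * X;  // 3x3
      const double detJ = arma::det(J);
      if (detJ < min_detJ) min_detJ = detJ;
      if (detJ <= 0) continue;  // reported via min_detJ
      dNx = dN_all[q] * arma::inv(J).t();  // dN/dx = dN/dxi * J^{-T}... (nn x 3)
      fill_B(dNx, B);
      const double wdet = w_all[q] * detJ;
      Ke += wdet * (B.t() * C * B);
      ve += wdet;
    }
    vol[e] = ve;
    for (int a = 0; a < nn; ++a)
      for (int b = 0; b < nn; ++b) {
        const int ga = 3 * (conn(e, a) - 1), gb = 3 * (conn(e, b) - 1);
        for (int p = 0; p < 3; ++p)
          for (int r = 0; r < 3; ++r) {
            ii[pos] = ga + p + 1;
            jj[pos] = gb + r + 1;
            xx[pos] = Ke(3 * a + p, 3 * b + r);
            ++pos;
          }
      }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx,
                      _["volume"] = vol, _["min_detJ"] = min_detJ);
}

//' @noRd
// [[Rcpp::export(name = ".hex_fields")]]
List hex_fields(const arma::mat &nodes, const arma::imat &conn,
                const arma::mat &Cmats, const arma::mat &U) {
  const int ne = conn.n_rows;
  const int nn = conn.n_cols;
  if (nn != 8 && nn != 20) stop("connectivity must have 8 or 20 nodes per element");
  const int ndof = 3 * nn;
  const GaussRule g = gauss_rule(nn);
  const int ng1 = g.x.size();

  std::vector<arma::mat> dN_all;
  std::vector<double> w_all;
  arma::vec N(nn);
  for (int i = 0; i < ng1; ++i)
    for (int j = 0; j < ng1; ++j)
      for (int k = 0; k < ng1; ++k) {
        arma::mat dN(nn, 3);
        shape_at(nn, g.x[i], g.x[j], g.x[k], dN, N);
        dN_all.push_back(dN);
        w_all.push_back(g.w[i] * g.w[j] * g.w[k]);
      }
  const int ngp = dN_all.size();
  arma::mat dN0(nn, 3);
  shape_at(nn, 0.0, 0.0, 0.0, dN0, N);

  NumericMatrix eps_out(6, ne), sig_out(6, ne);
  NumericVector sed(ne), vol(ne);

  arma::mat X(nn, 3), B(6, ndof), dNx(nn, 3), C(6, 6);
  arma::vec ue(ndof), epsv(6), sigv(6);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < nn; ++a) {
      const int nid = conn(e, a) - 1;
      X(a, 0) = nodes(nid, 0);
      X(a, 1) = nodes(nid, 1);
      X(a, 2) = nodes(nid, 2);
      ue(3 * a)     = U(nid, 0);
      ue(3 * a + 1) = U(nid, 1);
      ue(3 * a + 2) = U(nid, 2);
    }
    C = arma::reshape(Cmats.col(e), 6, 6);
    // volume-averaged SED by full quadrature (exact energy bookkeeping)
    double ve = 0.0, we = 0.0;
    for (int q = 0; q < ngp; ++q) {
      const arma::mat J = dN_all[q].t() * X;
      const double detJ = arma::det(J);
      dNx = dN_all[q] * arma::inv(J).t();
      fill_B(dNx, B);
      epsv = B * ue;
      sigv = C * epsv;
      const double u_q = 0.5 * arma::dot(sigv, epsv);
      const double wdet = w_all[q] * detJ;
      ve += wdet;
      we += wdet * u_q;
    }
    vol[e] = ve;
    sed[e] = (ve > 0) ? we / ve : 0.0;
    // centroid strain/stress for reporting and gauges
    const arma::mat J0 = dN0.t() * X;
    dNx = dN0 * arma::inv(J0).t();
    fill_B(dNx, B);
    epsv = B * ue;
    sigv = C * epsv;
    for (int r = 0; r < 6; ++r) {
      eps_out(r, e) = epsv(r);
      sig_out(r, e) = sigv(r);
    }
  }
  return List::create(_["strain"] = eps_out, _["stress"] = sig_out,
                      _["sed"] = sed, _["volume"] = vol);
}

//' @noRd
// [[Rcpp::export(name = ".hex_nodal_eyy")]]
NumericMatrix hex_nodal_eyy(const arma::mat &nodes, const arma::imat &conn,
                            const arma::mat &U) {
  // axial (YY) strain evaluated at each element's own node positions
  const int ne = conn.n_rows;
  const int nn = conn.n_cols;
  // natural coordinates of the element nodes
  arma::mat nat(nn, 3);
  for (int a = 0; a < 8; ++a) {
    nat(a, 0) = H8_XI[a];
    nat(a, 1) = H8_ETA[a];
    nat(a, 2) = H8_ZE[a];
  }
  if (nn == 20)
    for (int m = 0; m < 12; ++m) {
      const int a = H20_EDGE[m][0], b = H20_EDGE[m][1];
      nat(8 + m, 0) = 0.5 * (H8_XI[a] + H8_XI[b]);
      nat(8 + m, 1) = 0.5 * (H8_ETA[a] + H8_ETA[b]);
      nat(8 + m, 2) = 0.5 * (H8_ZE[a] + H8_ZE[b]);
    }
  std::vector<arma::mat> dN_all(nn, arma::mat(nn, 3));
  arma::vec N(nn);
  for (int a = 0; a < nn; ++a)
    shape_at(nn, nat(a, 0), nat(a, 1), nat(a, 2), dN_all[a], N);

  NumericMatrix out(nn, ne);
  arma::mat X(nn, 3), dNx(nn, 3);
  arma::vec uy(nn);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < nn; ++a) {
      const int nid = conn(e, a) - 1;
      X(a, 0) = nodes(nid, 0);
      X(a, 1) = nodes(nid, 1);
      X(a, 2) = nodes(nid, 2);
      uy(a) = U(nid, 1);
    }
    for (int a = 0; a < nn; ++a) {
      const arma::mat J = dN_all[a].t() * X;
      dNx = dN_all[a] * arma::inv(J).t();
      out(a, e) = arma::dot(dNx.col(1), uy);  // d u_y / d y
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".hex_volumes")]]
List hex_volumes(const arma::mat &nodes, const arma::imat &conn) {
  const int ne = conn.n_rows;
  const int nn = conn.n_cols;
  const GaussRule g = gauss_rule(nn);
  const int ng1 = g.x.size();
  std::vector<arma::mat> dN_all;
  std::vector<double> w_all;
  arma::vec N(nn);
  for (int i = 0; i < ng1; ++i)
    for (int j = 0; j < ng1; ++j)
      for (int k = 0; k < ng1; ++k) {
        arma::mat dN(nn, 3);
        shape_at(nn, g.x[i], g.x[j], g.x[k], dN, N);
        dN_all.push_back(dN);
        w_all.push_back(g.w[i] * g.w[j] * g.w[k]);
      }
  NumericVector vol(ne);
  double min_detJ = R_PosInf;
  arma::mat X(nn, 3);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < nn; ++a) {
      const int nid = conn(e, a) - 1;
      X(a, 0) = nodes(nid, 0);
      X(a, 1) = nodes(nid, 1);
      X(a, 2) = nodes(nid, 2);
    }
    double ve = 0.0;
    for (size_t q = 0; q < dN_all.size(); ++q) {
      const arma::mat J = dN_all[q].t() * X;
      const double detJ = arma::det(J);
      if (detJ < min_detJ) min_detJ = detJ;
      ve += w_all[q] * detJ;
    }
    vol[e] = ve;
  }
  return List::create(_["volume"] = vol, _["min_detJ"] = min_detJ);
}
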