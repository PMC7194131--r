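// Boundary-element kernels: signed solid angles (van Oosterom & Strackee)
// and single-layer potential integrals over flat triangles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double tri_solid_angle(const vec& r1, const vec& r2,
                                     const vec& r3) {
  double a1 = norm(r1), a2 = norm(r2), a3 = norm(r3);
  const double eps = 1e-12;
  if (a1 < eps || a2 < eps || a3 < eps) return 0.0;  // observer at a vertex
  double num = dot(r1, cross(r2, r3));
  double den = a1 * a2 * a3 + dot(r1, r2) * a3 + dot(r1, r3) * a2 +
               dot(r2, r3) * a1;
  if (std::fabs(num) < eps * a1 * a2 * a3 && den > 0.0) return 0.0;
  return 2.0 * std::atan2(num, den);
}

// [[Rcpp::export(name = ".solid_angle_matrix_cpp")]]
arma::mat solid_angle_matrix_cpp(const arma::mat& vertices,
                                 const arma::imat& faces,
                                 const arma::mat& observers) {
  const uword nf = faces.n_rows, no = observers.n_rows;
  mat W(no, nf, fill::zeros);
  for (uword i = 0; i < no; ++i) {
    vec p = observers.row(i).t();
    for (uword f = 0; f < nf; ++f) {
      vec r1 = vertices.row(faces(f, 0) - 1).t() - p;
      vec r2 = vertices.row(faces(f, 1) - 1).t() - p;
      vec r3 = vertices.row(faces(f, 2) - 1).t() - p;
      W(i, f) = tri_solid_angle(r1, r2, r3);
    }
  }
  return W;
}

// Analytic integral of 1/r over triangle (P,Q,R) observed from vertex P.
// Polar integration about P in the triangle plane:
//   I = int_0^gamma d / cos(theta - phi0) dtheta
// with d the distance from P to line QR and phi0 the direction of the foot
// of the perpendicular.
static double single_layer_from_vertex(const vec& P, const vec& Q,
                                       const vec& R) {
  vec u = Q - P, v = R - P;
  double lu = norm(u), lv = norm(v);
  if (lu < 1e-12 || lv < 1e-12) return 0.0;
  // local in-plane orthonormal basis (e1 along u)
  vec e1 = u / lu;
  vec w = v - dot(v, e1) * e1;
  double lw = norm(w);
  if (lw < 1e-12) return 0.0;  // degenerate sliver
  vec e2 = w / lw;
  // 2-D coordinates
  double qx = lu, qy = 0.0;
  double rx = dot(v, e1), ry = dot(v, e2);
  double gamma = std::atan2(ry, rx);
  // line QR in 2-D; distance from origin and foot direction
  double tx = rx - qx, ty = ry - qy;
  double lt = std::sqrt(tx * tx + ty * ty);
  tx /= lt; ty /= lt;
  double proj = qx * tx + qy * ty;
  double fx = qx - proj * tx, fy = qy - proj * ty;
  double d = std::sqrt(fx * fx + fy * fy);
  if (d < 1e-12) return 0.0;
  double phi0 = std::atan2(fy, fx);
  auto F = [](double x) {  // antiderivative of sec
    return std::log(std::fabs(std::tan(x) + 1.0 / std::cos(x)));
  };
  return d * (F(gamma - phi0) - F(0.0 - phi0));
}

// 7-point degree-5 quadrature on a triangle
static const double QW[7] = {0.225,
                             0.1323941527, 0.1323941527, 0.1323941527,
                             0.1259391805, 0.1259391805, 0.1259391805};
static const double QA[7] = {1.0 / 3.0,
                             0.0597158717, 0.4701420641, 0.4701420641,
                             0.7974269853, 0.1012865073, 0.1012865073};
static const double QB[7] = {1.0 / 3.0,
                             0.4701420641, 0.0597158717, 0.4701420641,
                             0.1012865073, 0.7974269853, 0.1012865073};

static double quad_recip_r(const vec& p, const vec& A, const vec& B,
                           const vec& C, int depth) {
  vec cen = (A + B + C) / 3.0;
  double diam = std::max({norm(B - A), norm(C - B), norm(A - C)});
  double dist = norm(p - cen);
  if (depth > 0 && dist < 1.5 * diam) {
    vec ab = 0.5 * (A + B), bc = 0.5 * (B + C), ca = 0.5 * (C + A);
    return quad_recip_r(p, A, ab, ca, depth - 1) +
           quad_recip_r(p, ab, B, bc, depth - 1) +
           quad_recip_r(p, ca, bc, C, depth - 1) +
           quad_recip_r(p, ab, bc, ca, depth - 1);
  }
  double area = 0.5 * norm(cross(B - A, C - A));
  double s = 0.0;
  for (int k = 0; k < 7; ++k) {
    vec x = A + QA[k] * (B - A) + QB[k] * (C - A);
    s += QW[k] * area / std::max(norm(p - x), 1e-12);
  }
  return s;
}

// Single-layer matrix: entry (i, v) = sum over faces containing vertex v of
// (1/3) * int_face 1/r(observer_i, .) dS. `obs_vertex` gives, per observer,
// its 1-based index into `vertices` when the observer coincides with a mesh
// vertex (0 otherwise), so singular integrals use the analytic formula.
// [[Rcpp::export(name = ".single_layer_matrix_cpp")]]
arma::mat single_layer_matrix_cpp(const arma::mat& vertices,
                                  const arma::imat& faces,
                                  const arma::mat& observers,
                                  const arma::ivec& obs_vertex) {
  const uword nf = faces.n_rows, no = observers.n_rows,
              nv = vertices.n_rows;
  mat S(no, nv, fill::zeros);
  for (uword i = 0; i < no; ++i) {
    vec p = observers.row(i).t();
    int self = obs_vertex(i);  // 1-based or 0
    for (uword f = 0; f < nf; ++f) {
      int i1 = faces(f, 0), i2 = faces(f, 1), i3 = faces(f, 2);
      vec A = vertices.row(i1 - 1).t();
      vec B = vertices.row(i2 - 1).t();
      vec C = vertices.row(i3 - 1).t();
      double I;
      if (self == i1) I = single_layer_from_vertex(A, B, C);
      else if (self == i2) I = single_layer_from_vertex(B, C, A);
      else if (self == i3) I = single_layer_from_vertex(C, A, B);
      else I = quad_recip_r(p, A, B, C, 3);
      double third = I / 3.0;
      S(i, i1 - 1) += third;
      S(i, i2 - 1) += third;
      S(i, i3 - 1) += third;
    }
  }
  return S;
}
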