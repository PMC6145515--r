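// Discrete differential operators and the elastica/Weber flow.
//
// Grid conventions: row index i is the x direction, column index j the y
// direction, dx = dy = h.  Whole-pixel fields are M x N; x half-pixel
// (face) fields are (M+1) x N with face f sitting between whole rows f and
// f+1 (face 0 and face M lie on the domain boundary); y faces are
// M x (N+1).  Boundaries are Neumann: one mirrored ghost ring, rows first
// then columns (order-independent).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double minmod2(double m, double n) {
  double sm = (m > 0) - (m < 0), sn = (n > 0) - (n < 0);
  return 0.5 * (sm + sn) * std::min(std::fabs(m), std::fabs(n));
}

// one mirrored ghost ring
static arma::mat pad1(const arma::mat& A) {
  arma::uword M = A.n_rows, N = A.n_cols;
  arma::mat B(M + 2, N + 2);
  B.submat(1, 1, M, N) = A;
  B.row(0) = B.row(1);
  B.row(M + 1) = B.row(M);
  B.col(0) = B.col(1);
  B.col(N + 1) = B.col(N);
  return B;
}

// [[Rcpp::export]]
arma::mat cpp_neumann_pad(const arma::mat& A) { return pad1(A); }

// [[Rcpp::export]]
double cpp_minmod(double m, double n) { return minmod2(m, n); }

// central differences over 2h with mirrored ghosts; mag = sqrt(gx^2+gy^2+eps)
static void grad_core(const arma::mat& g, double h, double eps,
                      arma::mat& gx, arma::mat& gy, arma::mat& mag) {
  arma::uword M = g.n_rows, N = g.n_cols;
  arma::mat G = pad1(g);
  gx.set_size(M, N); gy.set_size(M, N); mag.set_size(M, N);
  for (arma::uword j = 0; j < N; ++j) {
    for (arma::uword i = 0; i < M; ++i) {
      double dx = (G(i + 2, j + 1) - G(i, j + 1)) / (2.0 * h);
      double dy = (G(i + 1, j + 2) - G(i + 1, j)) / (2.0 * h);
      gx(i, j) = dx;
      gy(i, j) = dy;
      mag(i, j) = std::sqrt(dx * dx + dy * dy + eps);
    }
  }
}

// [[Rcpp::export]]
List cpp_gradient(const arma::mat& g, double h, double eps) {
  arma::mat gx, gy, mag;
  grad_core(g, h, eps, gx, gy, mag);
  return List::create(_["gx"] = gx, _["gy"] = gy, _["mag"] = mag);
}

// level-set curvature: central divergence of the eps-regularized unit
// gradient, evaluated with the same stencil one ghost ring out
static arma::mat curv_core(const arma::mat& g, double h, double eps) {
  arma::uword M = g.n_rows, N = g.n_cols;
  arma::mat G2 = pad1(pad1(g));          // (M+4) x (N+4)
  arma::mat Nx(M + 2, N + 2), Ny(M + 2, N + 2);
  for (arma::uword j = 0; j < N + 2; ++j) {
    for (arma::uword i = 0; i < M + 2; ++i) {
      double dx = (G2(i + 2, j + 1) - G2(i, j + 1)) / (2.0 * h);
      double dy = (G2(i + 1, j + 2) - G2(i + 1, j)) / (2.0 * h);
      double m = std::sqrt(dx * dx + dy * dy + eps);
      Nx(i, j) = dx / m;
      Ny(i, j) = dy / m;
    }
  }
  arma::mat k(M, N);
  for (arma::uword j = 0; j < N; ++j) {
    for (arma::uword i = 0; i < M; ++i) {
      k(i, j) = (Nx(i + 2, j + 1) - Nx(i, j + 1)) / (2.0 * h) +
                (Ny(i + 1, j + 2) - Ny(i + 1, j)) / (2.0 * h);
    }
  }
  return k;
}

// [[Rcpp::export]]
arma::mat cpp_curvature(const arma::mat& g, double h, double eps) {
  return curv_core(g, h, eps);
}

struct HalfBundle {
  // x faces: (M+1) x N ; y faces: M x (N+1)
  arma::mat kx, dxg_x, dyg_x, dxP_x, dyP_x, mag_x;
  arma::mat ky, dyg_y, dxg_y, dyP_y, dxP_y, mag_y;
};

static void bundle_core(const arma::mat& g, double h, double eps,
                        HalfBundle& B) {
  arma::uword M = g.n_rows, N = g.n_cols;
  arma::mat kap = curv_core(g, h, eps);
  arma::mat gx, gy, mag;
  grad_core(g, h, eps, gx, gy, mag);
  arma::mat G = pad1(g);
  arma::mat K = pad1(kap);
  arma::mat P = pad1(kap % mag);         // kappa * |grad g|, then ghosts

  B.kx.set_size(M + 1, N);   B.dxg_x.set_size(M + 1, N);
  B.dyg_x.set_size(M + 1, N); B.dxP_x.set_size(M + 1, N);
  B.dyP_x.set_size(M + 1, N); B.mag_x.set_size(M + 1, N);
  for (arma::uword j = 0; j < N; ++j) {
    arma::uword jj = j + 1;
    for (arma::uword f = 0; f <= M; ++f) {
      arma::uword a = f, b = f + 1;      // padded rows below/above face
      double dxg = (G(b, jj) - G(a, jj)) / h;
      double dyg = minmod2((G(b, jj + 1) - G(b, jj - 1)) / (2.0 * h),
                           (G(a, jj + 1) - G(a, jj - 1)) / (2.0 * h));
      double dxP = (P(b, jj) - P(a, jj)) / h;
      double dyP = minmod2((P(b, jj + 1) - P(b, jj - 1)) / (2.0 * h),
                           (P(a, jj + 1) - P(a, jj - 1)) / (2.0 * h));
      B.kx(f, j) = minmod2(K(b, jj), K(a, jj));
      B.dxg_x(f, j) = dxg;
      B.dyg_x(f, j) = dyg;
      B.dxP_x(f, j) = dxP;
      B.dyP_x(f, j) = dyP;
      B.mag_x(f, j) = std::sqrt(dxg * dxg + dyg * dyg + eps);
    }
  }

  B.ky.set_size(M, N + 1);   B.dyg_y.set_size(M, N + 1);
  B.dxg_y.set_size(M, N + 1); B.dyP_y.set_size(M, N + 1);
  B.dxP_y.set_size(M, N + 1); B.mag_y.set_size(M, N + 1);
  for (arma::uword f = 0; f <= N; ++f) {
    arma::uword a = f, b = f + 1;        // padded cols left/right of face
    for (arma::uword i = 0; i < M; ++i) {
      arma::uword ii = i + 1;
      double dyg = (G(ii, b) - G(ii, a)) / h;
      double dxg = minmod2((G(ii + 1, b) - G(ii - 1, b)) / (2.0 * h),
                           (G(ii + 1, a) - G(ii - 1, a)) / (2.0 * h));
      double dyP = (P(ii, b) - P(ii, a)) / h;
      double dxP = minmod2((P(ii + 1, b) - P(ii - 1, b)) / (2.0 * h),
                           (P(ii + 1, a) - P(ii - 1, a)) / (2.0 * h));
      B.ky(i, f) = minmod2(K(ii, b), K(ii, a));
      B.dyg_y(i, f) = dyg;
      B.dxg_y(i, f) = dxg;
      B.dyP_y(i, f) = dyP;
      B.dxP_y(i, f) = dxP;
      B.mag_y(i, f) = std::sqrt(dxg * dxg + dyg * dyg + eps);
    }
  }
}

// [[Rcpp::export]]
List cpp_half_bundle(const arma::mat& g, double h, double eps) {
  HalfBundle B;
  bundle_core(g, h, eps, B);
  return List::create(
    _["kappa_x"] = B.kx, _["dxg_x"] = B.dxg_x, _["dyg_x"] = B.dyg_x,
    _["dxP_x"] = B.dxP_x, _["dyP_x"] = B.dyP_x, _["mag_x"] = B.mag_x,
    _["kappa_y"] = B.ky, _["dyg_y"] = B.dyg_y, _["dxg_y"] = B.dxg_y,
    _["dyP_y"] = B.dyP_y, _["dxP_y"] = B.dxP_y, _["mag_y"] = B.mag_y);
}

// elastica flux U = (a1 + a2 k^2) grad g / |grad g|
//                 - (2 a2 / |grad g|^3) (perp(g) . grad(k |grad g|)) perp(g)
// with perp(g) = (-gy, gx); assembled from the face bundle
static void flux_core(const HalfBundle& B, double a1, double a2,
                      arma::mat& U1, arma::mat& U2) {
  arma::uword Mx = B.kx.n_rows, Nx = B.kx.n_cols;
  U1.set_size(Mx, Nx);
  for (arma::uword j = 0; j < Nx; ++j) {
    for (arma::uword f = 0; f < Mx; ++f) {
      double k = B.kx(f, j), gxv = B.dxg_x(f, j), gyv = B.dyg_x(f, j);
      double m = B.mag_x(f, j);
      double dot = -gyv * B.dxP_x(f, j) + gxv * B.dyP_x(f, j);
      U1(f, j) = (a1 + a2 * k * k) * gxv / m
               - (2.0 * a2 / (m * m * m)) * dot * (-gyv);
    }
  }
  arma::uword My = B.ky.n_rows, Ny = B.ky.n_cols;
  U2.set_size(My, Ny);
  for (arma::uword f = 0; f < Ny; ++f) {
    for (arma::uword i = 0; i < My; ++i) {
      double k = B.ky(i, f), gxv = B.dxg_y(i, f), gyv = B.dyg_y(i, f);
      double m = B.mag_y(i, f);
      double dot = -gyv * B.dxP_y(i, f) + gxv * B.dyP_y(i, f);
      U2(i, f) = (a1 + a2 * k * k) * gyv / m
               - (2.0 * a2 / (m * m * m)) * dot * gxv;
    }
  }
}

// [[Rcpp::export]]
List cpp_elastica_flux(const arma::mat& g, double h, double eps,
                       double a1, double a2) {
  HalfBundle B;
  bundle_core(g, h, eps, B);
  arma::mat U1, U2;
  flux_core(B, a1, a2, U1, U2);
  return List::create(_["U1"] = U1, _["U2"] = U2);
}

// [[Rcpp::export]]
arma::mat cpp_flux_divergence(const arma::mat& U1, const arma::mat& U2,
                              double h) {
  arma::uword M = U2.n_rows, N = U1.n_cols;
  if (U1.n_rows != M + 1 || U2.n_cols != N + 1)
    stop("staggered flux shapes must be (M+1) x N and M x (N+1)");
  arma::mat d(M, N);
  for (arma::uword j = 0; j < N; ++j)
    for (arma::uword i = 0; i < M; ++i)
      d(i, j) = (U1(i + 1, j) - U1(i, j)) / h +
                (U2(i, j + 1) - U2(i, j)) / h;
  return d;
}

// discrete energy: h^2 * sum[(b1 + b2/g)(a1 + a2 k^2)|grad g| + log g + f/g]
// |grad g| enters either verbatim (intensity units, = h * consistent
// magnitude) or as the consistent gradient magnitude
static double energy_core(const arma::mat& g, const arma::mat& f, double h,
                          double eps, double b1, double b2, double a1,
                          double a2, bool literal) {
  arma::mat kap = curv_core(g, h, eps);
  arma::mat gx, gy, mag;
  grad_core(g, h, eps, gx, gy, mag);
  double s = 0.0;
  double magscale = literal ? h : 1.0;
  arma::uword M = g.n_rows, N = g.n_cols;
  for (arma::uword j = 0; j < N; ++j) {
    for (arma::uword i = 0; i < M; ++i) {
      double k = kap(i, j);
      s += (b1 + b2 / g(i, j)) * (a1 + a2 * k * k) * magscale * mag(i, j)
         + std::log(g(i, j)) + f(i, j) / g(i, j);
    }
  }
  return h * h * s;
}

// [[Rcpp::export]]
double cpp_m2_energy(const arma::mat& g, const arma::mat& f, double h,
                     double eps, double b1, double b2, double a1, double a2,
                     bool literal) {
  return energy_core(g, f, h, eps, b1, b2, a1, a2, literal);
}

static double psnr_core(const arma::mat& ref, const arma::mat& x) {
  double ss = arma::accu(arma::square(ref - x));
  if (ss <= 0) return R_PosInf;
  double mx = ref.max();
  return 10.0 * std::log10(ref.n_elem * mx * mx / ss);
}

// explicit time stepping of dg/dt = div U + fid_sign * lambda(g) (g - f),
// fid_sign = -1 descends the energy (default); +1 reproduces the verbatim
// printed update.  Clamps below pos_floor, counting clamp events.
// [[Rcpp::export]]
List cpp_m2_run(const arma::mat& f, const arma::mat& g0, double b1, double b2,
                double a1, double a2, double eps, double h, double dt,
                int max_iter, double rel_tol, double pos_floor,
                Nullable<NumericMatrix> reference, bool literal,
                double fid_sign, bool record_energy) {
  arma::mat g = g0;
  arma::uword M = g.n_rows, N = g.n_cols;
  bool has_ref = reference.isNotNull();
  arma::mat ref;
  if (has_ref) ref = as<arma::mat>(reference.get());

  std::vector<double> energies, rel_changes, psnrs;
  int clamps = 0, iters = 0;
  bool diverged = false;
  double e0 = record_energy ?
    energy_core(g, f, h, eps, b1, b2, a1, a2, literal) : NA_REAL;

  HalfBundle B;
  arma::mat U1, U2;
  for (int n = 0; n < max_iter; ++n) {
    bundle_core(g, h, eps, B);
    flux_core(B, a1, a2, U1, U2);
    double gnorm = 0.0, dnorm = 0.0;
    for (arma::uword j = 0; j < N; ++j) {
      for (arma::uword i = 0; i < M; ++i) {
        double divU = (U1(i + 1, j) - U1(i, j)) / h +
                      (U2(i, j + 1) - U2(i, j)) / h;
        double lam = b1 + b2 / g(i, j);
        double upd = dt * (divU + fid_sign * lam * (g(i, j) - f(i, j)));
        double gn = g(i, j) + upd;
        if (gn < pos_floor) { gn = pos_floor; ++clamps; }
        dnorm += (gn - g(i, j)) * (gn - g(i, j));
        gnorm += g(i, j) * g(i, j);
        g(i, j) = gn;
      }
    }
    ++iters;
    double rel = std::sqrt(dnorm) / std::max(std::sqrt(gnorm), 1e-300);
    rel_changes.push_back(rel);
    if (record_energy)
      energies.push_back(energy_core(g, f, h, eps, b1, b2, a1, a2, literal));
    if (has_ref) psnrs.push_back(psnr_core(ref, g));
    if (!g.is_finite()) { diverged = true; break; }
    if (rel < rel_tol) break;
  }

  return List::create(
    _["g"] = g, _["iterations"] = iters, _["diverged"] = diverged,
    _["clamp_count"] = clamps, _["energy0"] = e0,
    _["energies"] = energies, _["rel_changes"] = rel_changes,
    _["psnr"] = psnrs);
}
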