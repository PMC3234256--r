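#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-difference solve of div(eps grad phi) = -4 pi C rho on a cubic
// lattice, phi in kT/e, lengths in Angstrom, charges in e. Face dielectrics
// are harmonic means of the two adjacent node values. Dirichlet boundary
// values arrive preset in phi. Red-black successive over-relaxation.
//
// src holds 4 pi C q / h per node (q = trilinear charge fraction).
// Returns phi plus convergence diagnostics.
// [[Rcpp::export(name = ".sorSolve")]]
List sorSolve(NumericVector phi, NumericVector eps, NumericVector src,
              IntegerVector dims, double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::vector<double> p(phi.begin(), phi.end());
  const double *e = &eps[0];
  const double *b = &src[0];

  double bnorm = 0.0;
  for (R_xlen_t t = 0; t < src.size(); ++t) bnorm += b[t] * b[t];
  bnorm = std::sqrt(bnorm);
  if (bnorm <= 0.0) bnorm = 1.0;

  auto idx = [&](int i, int j, int k) { return i + (R_xlen_t)nx * j + nxy * k; };
  auto hmean = [](double a, double bb) { return 2.0 * a * bb / (a + bb); };

  double rel = R_PosInf;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + color) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            R_xlen_t c = idx(i, j, k);
            double e0 = e[c];
            double exm = hmean(e0, e[c - 1]), exp_ = hmean(e0, e[c + 1]);
            double eym = hmean(e0, e[c - nx]), eyp = hmean(e0, e[c + nx]);
            double ezm = hmean(e0, e[c - nxy]), ezp = hmean(e0, e[c + nxy]);
            double diag = exm + exp_ + eym + eyp + ezm + ezp;
            double rhs = exm * p[c - 1] + exp_ * p[c + 1] +
                         eym * p[c - nx] + eyp * p[c + nx] +
                         ezm * p[c - nxy] + ezp * p[c + nxy] + b[c];
            p[c] = (1.0 - omega) * p[c] + omega * rhs / diag;
          }
        }
      }
    }
    if (it % 10 == 0 || it == maxit) {
      double rnorm = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            R_xlen_t c = idx(i, j, k);
            double e0 = e[c];
            double exm = hmean(e0, e[c - 1]), exp_ = hmean(e0, e[c + 1]);
            double eym = hmean(e0, e[c - nx]), eyp = hmean(e0, e[c + nx]);
            double ezm = hmean(e0, e[c - nxy]), ezp = hmean(e0, e[c + nxy]);
            double r = exm * (p[c - 1] - p[c]) + exp_ * (p[c + 1] - p[c]) +
                       eym * (p[c - nx] - p[c]) + eyp * (p[c + nx] - p[c]) +
                       ezm * (p[c - nxy] - p[c]) + ezp * (p[c + nxy] - p[c]) +
                       b[c];
            rnorm += r * r;
          }
      rel = std::sqrt(rnorm) / bnorm;
      if (rel < tol) break;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector out(p.begin(), p.end());
  out.attr("dim") = dims;
  return List::create(_["phi"] = out, _["iterations"] = it,
                      _["residual"] = rel, _["converged"] = rel < tol);
}

// Paint node dielectric: soluteEps inside the union of atom spheres
// inflated by the probe radius, solventEps elsewhere.
// [[Rcpp::export(name = ".markDielectric")]]
NumericVector markDielectric(IntegerVector dims, NumericVector origin,
                             double h, NumericMatrix xyz,
                             NumericVector radius, double probe,
                             double soluteEps, double solventEps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector eps((R_xlen_t)nx * ny * nz, solventEps);
  for (int a = 0; a < xyz.nrow(); ++a) {
    double r = radius[a] + probe;
    double r2 = r * r;
    double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int i0 = std::max(0, (int)std::floor((ax - r - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::ceil((ax + r - origin[0]) / h));
    int j0 = std::max(0, (int)std::floor((ay - r - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::ceil((ay + r - origin[1]) / h));
    int k0 = std::max(0, (int)std::floor((az - r - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::ceil((az + r - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - az;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - ay;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - ax;
          if (dx * dx + dy * dy + dz * dz <= r2)
            eps[i + (R_xlen_t)nx * j + nxy * k] = soluteEps;
        }
      }
    }
  }
  eps.attr("dim") = dims;
  return eps;
}

// Coulomb superposition on the six boundary faces (solvent dielectric):
// phi = C/epsSolv * sum_a q_a / |r - r_a|, evaluated only at boundary nodes.
// [[Rcpp::export(name = ".coulombBoundary")]]
NumericVector coulombBoundary(IntegerVector dims, NumericVector origin,
                              double h, NumericMatrix xyz,
                              NumericVector q, double C, double epsSolv) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector phi((R_xlen_t)nx * ny * nz, 0.0);
  const double scale = C / epsSolv;
  for (int k = 0; k < nz; ++k) {
    bool zEdge = (k == 0 || k == nz - 1);
    double pz = origin[2] + k * h;
    for (int j = 0; j < ny; ++j) {
      bool yEdge = (j == 0 || j == ny - 1);
      double py = origin[1] + j * h;
      for (int i = 0; i < nx; ++i) {
        if (!zEdge && !yEdge && i != 0 && i != nx - 1) continue;
        double px = origin[0] + i * h;
        double v = 0.0;
        for (int a = 0; a < xyz.nrow(); ++a) {
          double dx = px - xyz(a, 0), dy = py - xyz(a, 1),
                 dz = pz - xyz(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          v += q[a] / r;
        }
        phi[i + (R_xlen_t)nx * j + nxy * k] = scale * v;
      }
    }
  }
  phi.attr("dim") = dims;
  return phi;
}
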