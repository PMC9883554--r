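// Matrix-free kernels for the 7-point finite-volume stencil.
//
// The system matrix is complex symmetric: A = D - B, where D is the
// diagonal and B holds the (positive) face conductances to the six
// neighbors. Storage: nbr (n x 6, 1-based neighbor row indices, 0 = none)
// and offd (n x 6, conductances). The solver is conjugate-orthogonal CG
// (COCG), the complex-symmetric analogue of CG, with a Jacobi or SSOR
// preconditioner.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline cplx toC(const Rcomplex& z) { return cplx(z.r, z.i); }

static void matvec(const IntegerMatrix& nbr, const std::vector<cplx>& offd,
                   const std::vector<cplx>& dia, const std::vector<cplx>& x,
                   std::vector<cplx>& y) {
  const int n = dia.size();
  for (int i = 0; i < n; ++i) {
    cplx acc = dia[i] * x[i];
    for (int c = 0; c < 6; ++c) {
      const int j = nbr(i, c);
      if (j > 0) acc -= offd[(size_t)c * n + i] * x[j - 1];
    }
    y[i] = acc;
  }
}

// [[Rcpp::export(name = ".fv_matvec")]]
ComplexVector fv_matvec_cpp(IntegerMatrix nbr, ComplexMatrix offd,
                            ComplexVector diag, ComplexVector x) {
  const int n = diag.size();
  std::vector<cplx> od((size_t)6 * n), d(n), xx(n), y(n);
  for (int c = 0; c < 6; ++c)
    for (int i = 0; i < n; ++i) od[(size_t)c * n + i] = toC(offd(i, c));
  for (int i = 0; i < n; ++i) { d[i] = toC(diag[i]); xx[i] = toC(x[i]); }
  matvec(nbr, od, d, xx, y);
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) { out[i].r = y[i].real(); out[i].i = y[i].imag(); }
  return out;
}

// SSOR preconditioner application: solve M z = r with
// M = (D + L) D^{-1} (D + U), L/U the strictly lower/upper parts of A.
static void ssor_apply(const IntegerMatrix& nbr, const std::vector<cplx>& offd,
                       const std::vector<cplx>& dia, const std::vector<cplx>& r,
                       std::vector<cplx>& z, std::vector<cplx>& tmp) {
  const int n = dia.size();
  // forward: (D + L) tmp = r, L entries are -B_ij for j < i
  for (int i = 0; i < n; ++i) {
    cplx acc = r[i];
    for (int c = 0; c < 6; ++c) {
      const int j = nbr(i, c);
      if (j > 0 && j - 1 < i) acc += offd[(size_t)c * n + i] * tmp[j - 1];
    }
    tmp[i] = acc / dia[i];
  }
  // backward: (D + U) z = D tmp
  for (int i = n - 1; i >= 0; --i) {
    cplx acc = dia[i] * tmp[i];
    for (int c = 0; c < 6; ++c) {
      const int j = nbr(i, c);
      if (j - 1 > i) acc += offd[(size_t)c * n + i] * z[j - 1];
    }
    z[i] = acc / dia[i];
  }
}

// [[Rcpp::export(name = ".fv_cocg")]]
List fv_cocg_cpp(IntegerMatrix nbr, ComplexMatrix offd, ComplexVector diag,
                 ComplexVector rhs, double tol, int maxit, int use_ssor) {
  const int n = diag.size();
  std::vector<cplx> od((size_t)6 * n), d(n), b(n);
  for (int c = 0; c < 6; ++c)
    for (int i = 0; i < n; ++i) od[(size_t)c * n + i] = toC(offd(i, c));
  for (int i = 0; i < n; ++i) { d[i] = toC(diag[i]); b[i] = toC(rhs[i]); }

  std::vector<cplx> x(n, cplx(0, 0)), r(b), z(n), p(n), q(n), tmp(n);
  double bnorm = 0;
  for (int i = 0; i < n; ++i) bnorm += std::norm(b[i]);
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0) {
    return List::create(_["x"] = ComplexVector(n), _["residual"] = 0.0,
                        _["iterations"] = 0, _["converged"] = true);
  }

  auto precond = [&](const std::vector<cplx>& rr, std::vector<cplx>& zz) {
    if (use_ssor) ssor_apply(nbr, od, d, rr, zz, tmp);
    else for (int i = 0; i < n; ++i) zz[i] = rr[i] / d[i];
  };

  precond(r, z);
  p = z;
  cplx rho(0, 0);
  for (int i = 0; i < n; ++i) rho += r[i] * z[i];   // unconjugated
  double resid = 1.0;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    matvec(nbr, od, d, p, q);
    cplx pq(0, 0);
    for (int i = 0; i < n; ++i) pq += p[i] * q[i];
    if (std::abs(pq) == 0.0 || std::abs(rho) == 0.0) break;  // breakdown
    cplx alpha = rho / pq;
    double rnorm = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rnorm += std::norm(r[i]);
    }
    resid = std::sqrt(rnorm) / bnorm;
    if (resid <= tol) { converged = true; break; }
    precond(r, z);
    cplx rho_new(0, 0);
    for (int i = 0; i < n; ++i) rho_new += r[i] * z[i];
    cplx beta = rho_new / rho;
    rho = rho_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  ComplexVector out(n);
  for (int i = 0; i < n; ++i) { out[i].r = x[i].real(); out[i].i = x[i].imag(); }
  return List::create(_["x"] = out, _["residual"] = resid,
                      _["iterations"] = it, _["converged"] = converged);
}
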