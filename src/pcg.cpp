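#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Jacobi-preconditioned conjugate gradients for a symmetric positive
// (semi-)definite sparse matrix in compressed sparse column form (the slots
// of a Matrix::dgCMatrix). For the pure-Neumann conductance system the
// matrix is singular with a constant null vector; the right-hand side is
// made consistent by the caller and the returned solution is re-referenced
// there. Convergence: ||r||_2 / ||b||_2 <= tol.
// [[Rcpp::export]]
List pcg_csc(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
             NumericVector b, double tol, int maxit) {
  const int n = b.size();
  std::vector<double> diag(n, 0.0);
  for (int col = 0; col < n; ++col)
    for (int k = Ap[col]; k < Ap[col + 1]; ++k)
      if (Ai[k] == col) diag[col] = Ax[k];
  for (int j = 0; j < n; ++j)
    if (!(diag[j] > 0.0)) stop("zero or negative diagonal at row %d", j + 1);

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), Apv(n);
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) { r[j] = b[j]; bnorm += b[j] * b[j]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }

  double rz = 0.0;
  for (int j = 0; j < n; ++j) { z[j] = r[j] / diag[j]; p[j] = z[j]; rz += r[j] * z[j]; }

  int it = 0;
  double relres = 1.0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    // Apv = A p (CSC of a symmetric matrix, scatter by column)
    std::fill(Apv.begin(), Apv.end(), 0.0);
    for (int col = 0; col < n; ++col) {
      const double pc = p[col];
      if (pc == 0.0) continue;
      for (int k = Ap[col]; k < Ap[col + 1]; ++k) Apv[Ai[k]] += Ax[k] * pc;
    }
    double pAp = 0.0;
    for (int j = 0; j < n; ++j) pAp += p[j] * Apv[j];
    if (pAp <= 0.0) break;  // null-space component or breakdown
    const double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p[j];
      r[j] -= alpha * Apv[j];
      rnorm += r[j] * r[j];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) { converged = true; break; }
    double rz_new = 0.0;
    for (int j = 0; j < n; ++j) { z[j] = r[j] / diag[j]; rz_new += r[j] * z[j]; }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
  }

  NumericVector xout(n);
  for (int j = 0; j < n; ++j) xout[j] = x[j];
  return List::create(_["x"] = xout, _["iterations"] = it,
                      _["relres"] = relres, _["converged"] = converged);
}

// Flood fill over the 6-connected neighborhood of a 3D logical mask,
// starting from linear index `start` (1-based). Returns the connected
// component as a logical vector of the same length.
// [[Rcpp::export]]
LogicalVector flood_component(LogicalVector mask, IntegerVector dm, int start) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dimensions");
  if (start < 1 || start > n) stop("start index out of range");
  LogicalVector comp(n, false);
  if (!mask[start - 1]) return comp;
  std::vector<int> stack;
  stack.push_back(start - 1);
  comp[start - 1] = true;
  const int sxy = nx * ny;
  while (!stack.empty()) {
    const int v = stack.back();
    stack.pop_back();
    const int k = v / sxy, rem = v % sxy, j = rem / nx, i = rem % nx;
    const int nb[6] = {
      i > 0 ? v - 1 : -1,       i < nx - 1 ? v + 1 : -1,
      j > 0 ? v - nx : -1,      j < ny - 1 ? v + nx : -1,
      k > 0 ? v - sxy : -1,     k < nz - 1 ? v + sxy : -1};
    for (int q = 0; q < 6; ++q) {
      const int w = nb[q];
      if (w >= 0 && mask[w] && !comp[w]) { comp[w] = true; stack.push_back(w); }
    }
  }
  return comp;
}
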