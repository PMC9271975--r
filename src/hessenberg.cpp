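#include <Rcpp.h>
using namespace Rcpp;

// LU factorization of an upper-Hessenberg matrix (single sub-diagonal),
// Gaussian elimination without pivoting in O(n^2). The shifted
// growth-division operator is an M-matrix for admissible shifts, so
// elimination without pivoting is stable (as for tridiagonal M-matrices).
// [[Rcpp::export]]
List hessenberg_lu(NumericMatrix A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  NumericMatrix U = clone(A);
  NumericVector m(n > 1 ? n - 1 : 0);
  double *u = REAL(U);
  for (int i = 0; i + 1 < n; ++i) {
    double piv = u[i + (R_xlen_t)i * n];
    if (piv == 0.0 || !R_finite(piv))
      stop("zero or non-finite pivot at row %d; shift too small?", i + 1);
    double mi = u[(i + 1) + (R_xlen_t)i * n] / piv;
    m[i] = mi;
    if (mi != 0.0) {
      // row i+1 -= mi * row i, columns i..n-1 (strided access)
      for (int j = i; j < n; ++j)
        u[(i + 1) + (R_xlen_t)j * n] -= mi * u[i + (R_xlen_t)j * n];
    }
  }
  return List::create(_["U"] = U, _["m"] = m);
}

// Solve LU x = b given the factors from hessenberg_lu.
// Forward pass applies the (bidiagonal) multipliers; back substitution is
// column-oriented so memory access is contiguous.
// [[Rcpp::export]]
NumericVector hessenberg_solve(NumericMatrix U, NumericVector m, NumericVector b) {
  int n = U.nrow();
  if (b.size() != n) stop("length(b) must match nrow(U)");
  NumericVector y = clone(b);
  double *u = REAL(U), *yy = REAL(y);
  for (int i = 0; i + 1 < n; ++i) yy[i + 1] -= m[i] * yy[i];
  NumericVector x(n);
  double *xx = REAL(x);
  for (int j = n - 1; j >= 0; --j) {
    double xj = yy[j] / u[j + (R_xlen_t)j * n];
    xx[j] = xj;
    if (xj != 0.0) {
      double *col = u + (R_xlen_t)j * n;
      for (int i = 0; i < j; ++i) yy[i] -= col[i] * xj;
    }
  }
  return x;
}

// Tridiagonal (Thomas) solve for the radial finite-volume systems.
// [[Rcpp::export]]
NumericVector thomas_solve(NumericVector lower, NumericVector diag,
                           NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  NumericVector d = clone(diag), b = clone(rhs);
  for (int i = 1; i < n; ++i) {
    double w = lower[i] / d[i - 1];
    d[i] -= w * upper[i - 1];
    b[i] -= w * b[i - 1];
  }
  NumericVector x(n);
  x[n - 1] = b[n - 1] / d[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (b[i] - upper[i] * x[i + 1]) / d[i];
  return x;
}
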