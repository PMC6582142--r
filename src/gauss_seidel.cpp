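#include <Rcpp.h>
using namespace Rcpp;

// Gauss-Seidel / SOR sweeps for the finite-volume perfusion system.
//
// p        : nx x ny initial guess, updated in place (a copy is made in R)
// source   : nx x ny, alpha * delta_p0
// diag     : nx x ny, alpha + omega + sum of face conductances
// gx       : (nx+1) x ny, x-face conductances; gx(0,j) and gx(nx,j) are the
//            boundary faces (0 under no-flux)
// gy       : nx x (ny+1), y-face conductances; under periodic_y the first
//            and last column both hold the wrap-face conductance
// Sweep order is fixed: ascending x within ascending y.
// Returns iterations used, the last max absolute update, and convergence.
// [[Rcpp::export]]
List gs_iterate(NumericMatrix p, NumericMatrix source, NumericMatrix diag,
                NumericMatrix gx, NumericMatrix gy, bool periodic_y,
                double tol, int max_iter, double relax) {
  const int nx = p.nrow(), ny = p.ncol();
  double max_update = R_PosInf;
  int it = 0;
  while (it < max_iter) {
    max_update = 0.0;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double nb = 0.0;
        if (i > 0)      nb += gx(i, j)     * p(i - 1, j);
        if (i < nx - 1) nb += gx(i + 1, j) * p(i + 1, j);
        if (j > 0)      nb += gy(i, j)     * p(i, j - 1);
        else if (periodic_y && ny > 1) nb += gy(i, 0) * p(i, ny - 1);
        if (j < ny - 1) nb += gy(i, j + 1) * p(i, j + 1);
        else if (periodic_y && ny > 1) nb += gy(i, ny) * p(i, 0);
        const double d = diag(i, j);
        if (d <= 0.0) continue; // isolated degenerate cell, keep value
        const double gs = (source(i, j) + nb) / d;
        const double pnew = (1.0 - relax) * p(i, j) + relax * gs;
        const double du = std::fabs(pnew - p(i, j));
        if (du > max_update) max_update = du;
        p(i, j) = pnew;
      }
    }
    ++it;
    if (max_update <= tol) break;
  }
  return List::create(_["iterations"] = it,
                      _["max_update"] = max_update,
                      _["converged"]  = (max_update <= tol));
}
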