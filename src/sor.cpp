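#include <Rcpp.h>
using namespace Rcpp;

// Successive over-relaxation for the 2-D Laplace equation on a square grid
// with curved Dirichlet boundaries (Shortley-Weller stencil).
//
// Nodes with fixed(i,j) == TRUE hold Dirichlet values throughout. Free
// nodes are swept in deterministic row-major Gauss-Seidel order with
// relaxation factor omega. aN/aS/aW/aE give, per node, the fractional arm
// length (in units of h) toward each neighbour; 1 for a regular arm, < 1
// where the arm is cut by a conductor circle, in which case the neighbour
// node is itself fixed at the conductor potential so u(neighbour) is the
// correct boundary value at the cut. The irregular-stencil mean value is
//   u_P = [ uE/(aE(aE+aW)) + uW/(aW(aE+aW)) + uN/(aN(aN+aS)) + uS/(aS(aN+aS)) ]
//         / [ 1/(aE aW) + 1/(aN aS) ].
// Convergence: max absolute update in a full sweep <= tol.
// [[Rcpp::export]]
List sor_laplace(NumericMatrix grid, LogicalMatrix fixed,
                 NumericMatrix aN, NumericMatrix aS,
                 NumericMatrix aW, NumericMatrix aE,
                 double omega, double tol, int max_iters) {
  int nr = grid.nrow(), nc = grid.ncol();
  if (fixed.nrow() != nr || fixed.ncol() != nc)
    stop("grid and fixed mask dimensions differ");
  NumericMatrix u = clone(grid);

  auto target = [&](int i, int j) {
    // rows index y (N = i+1), columns index x (E = j+1)
    double an = aN(i, j), as = aS(i, j), aw = aW(i, j), ae = aE(i, j);
    double num = u(i + 1, j) / (an * (an + as)) + u(i - 1, j) / (as * (an + as)) +
                 u(i, j + 1) / (ae * (ae + aw)) + u(i, j - 1) / (aw * (ae + aw));
    double den = 1.0 / (an * as) + 1.0 / (ae * aw);
    return num / den;
  };

  double delta = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iters && delta > tol; ++it) {
    delta = 0.0;
    for (int i = 1; i < nr - 1; ++i) {
      for (int j = 1; j < nc - 1; ++j) {
        if (fixed(i, j)) continue;
        double upd = omega * (target(i, j) - u(i, j));
        u(i, j) += upd;
        double a = std::fabs(upd);
        if (a > delta) delta = a;
      }
    }
  }
  // true residual: departure from the (possibly irregular) mean-value form
  double resid = 0.0;
  for (int i = 1; i < nr - 1; ++i)
    for (int j = 1; j < nc - 1; ++j) {
      if (fixed(i, j)) continue;
      double r = std::fabs(target(i, j) - u(i, j));
      if (r > resid) resid = r;
    }
  return List::create(_["potential"] = u, _["iterations"] = it,
                      _["max_update"] = delta, _["residual"] = resid,
                      _["converged"] = delta <= tol);
}
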