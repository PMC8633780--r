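#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential constraint projection (SHAKE-like Gauss-Seidel sweeps) over
// three constraint families on pairwise distances:
//   equality    |r_i - r_j| = t   (bond lengths, 1-3 and locked 1-4 distances)
//   upper bound |r_i - r_j| <= t  (polar / tether contacts may shorten only)
//   lower bound |r_i - r_j| >= t  (steric floors)
// Each projection moves both atoms equally and oppositely along the pair
// axis. Sweeps stop when the maximum violation is within tol.

static double maxViolation(const NumericMatrix &x,
                           const IntegerMatrix &eq, const NumericVector &eqT,
                           const IntegerMatrix &ub, const NumericVector &ubT,
                           const IntegerMatrix &lb, const NumericVector &lbT) {
  double worst = 0.0;
  for (int c = 0; c < eq.nrow(); ++c) {
    int i = eq(c, 0) - 1, j = eq(c, 1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double v = std::fabs(std::sqrt(dx*dx+dy*dy+dz*dz) - eqT[c]);
    if (v > worst) worst = v;
  }
  for (int c = 0; c < ub.nrow(); ++c) {
    int i = ub(c, 0) - 1, j = ub(c, 1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double v = std::sqrt(dx*dx+dy*dy+dz*dz) - ubT[c];
    if (v > worst) worst = v;
  }
  for (int c = 0; c < lb.nrow(); ++c) {
    int i = lb(c, 0) - 1, j = lb(c, 1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double v = lbT[c] - std::sqrt(dx*dx+dy*dy+dz*dz);
    if (v > worst) worst = v;
  }
  return worst;
}

static inline void project(NumericMatrix &x, int i, int j, double target) {
  double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
  double d = std::sqrt(dx*dx + dy*dy + dz*dz);
  if (d < 1e-12) return; // direction undefined; leave for a later sweep
  double s = 0.5 * (d - target) / d;
  x(i,0) -= s*dx; x(i,1) -= s*dy; x(i,2) -= s*dz;
  x(j,0) += s*dx; x(j,1) += s*dy; x(j,2) += s*dz;
}

// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix coords,
               IntegerMatrix eq, NumericVector eqT,
               IntegerMatrix ub, NumericVector ubT,
               IntegerMatrix lb, NumericVector lbT,
               double tol, int maxSweeps) {
  NumericMatrix x = clone(coords);
  double worst = maxViolation(x, eq, eqT, ub, ubT, lb, lbT);
  int sweeps = 0;
  while (worst > tol && sweeps < maxSweeps) {
    for (int c = 0; c < eq.nrow(); ++c)
      project(x, eq(c,0)-1, eq(c,1)-1, eqT[c]);
    for (int c = 0; c < ub.nrow(); ++c) {
      int i = ub(c,0)-1, j = ub(c,1)-1;
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      if (dx*dx+dy*dy+dz*dz > ubT[c]*ubT[c]) project(x, i, j, ubT[c]);
    }
    for (int c = 0; c < lb.nrow(); ++c) {
      int i = lb(c,0)-1, j = lb(c,1)-1;
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      if (dx*dx+dy*dy+dz*dz < lbT[c]*lbT[c]) project(x, i, j, lbT[c]);
    }
    ++sweeps;
    worst = maxViolation(x, eq, eqT, ub, ubT, lb, lbT);
  }
  return List::create(_["coords"] = x, _["sweeps"] = sweeps,
                      _["maxViolation"] = worst);
}
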