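// Dense two-phase primal simplex and the three LP formulations built on it
// (FBA, parsimonious FBA with reversible-reaction splitting, FVA).
//
// Models here are small (toy networks, tens of reactions), so a dense
// tableau with Bland's anti-cycling rule is robust and more than fast
// enough; upper bounds are handled through explicit slack rows.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double PIV_EPS = 1e-9;   // pivot / reduced-cost tolerance
static const double FEAS_EPS = 1e-7;  // phase-1 infeasibility threshold

enum LpStatus { LP_OPTIMAL = 0, LP_INFEASIBLE = 1, LP_UNBOUNDED = 2, LP_MAXITER = 3 };

struct LpResult {
  int status;
  double obj;
  std::vector<double> x;
};

// maximise c'x  s.t.  A x = b,  x >= 0   (A is m x n, row-major)
static LpResult simplex_core(const std::vector<double>& c,
                             const std::vector<double>& A,
                             const std::vector<double>& b,
                             int m, int n) {
  LpResult res;
  res.status = LP_MAXITER;
  res.obj = NA_REAL;

  const int ncol = n + m;              // structural + artificial
  std::vector<double> T((size_t)m * ncol, 0.0);
  std::vector<double> rhs(b);
  std::vector<int> basis(m);

  for (int i = 0; i < m; ++i) {
    double sgn = (rhs[i] < 0.0) ? -1.0 : 1.0;
    rhs[i] *= sgn;
    for (int j = 0; j < n; ++j) T[(size_t)i * ncol + j] = sgn * A[(size_t)i * n + j];
    T[(size_t)i * ncol + n + i] = 1.0;
    basis[i] = n + i;
  }

  std::vector<double> obj(ncol, 0.0);  // stores z_j - c_j for current phase
  double objval = 0.0;

  // phase 1: maximise -sum(artificials); initial reduced costs from basis
  for (int j = 0; j < ncol; ++j) {
    double colsum = 0.0;
    for (int i = 0; i < m; ++i) colsum += T[(size_t)i * ncol + j];
    obj[j] = -colsum - ((j >= n) ? -1.0 : 0.0);
  }
  objval = 0.0;
  for (int i = 0; i < m; ++i) objval -= rhs[i];

  const long maxit = 50000;
  long iter = 0;

  for (int phase = 1; phase <= 2; ++phase) {
    if (phase == 2) {
      if (objval < -FEAS_EPS) { res.status = LP_INFEASIBLE; return res; }
      // drive artificials (basic at zero) out of the basis where possible
      for (int i = 0; i < m; ++i) {
        if (basis[i] < n) continue;
        int pc = -1;
        for (int j = 0; j < n; ++j)
          if (std::fabs(T[(size_t)i * ncol + j]) > PIV_EPS) { pc = j; break; }
        if (pc < 0) continue;  // redundant row: harmless, stays zero
        double piv = T[(size_t)i * ncol + pc];
        for (int j = 0; j < ncol; ++j) T[(size_t)i * ncol + j] /= piv;
        rhs[i] /= piv;
        for (int r = 0; r < m; ++r) {
          if (r == i) continue;
          double f = T[(size_t)r * ncol + pc];
          if (std::fabs(f) < PIV_EPS) continue;
          for (int j = 0; j < ncol; ++j) T[(size_t)r * ncol + j] -= f * T[(size_t)i * ncol + j];
          rhs[r] -= f * rhs[i];
        }
        basis[i] = pc;
      }
      // reduced costs for the real objective
      objval = 0.0;
      for (int i = 0; i < m; ++i)
        if (basis[i] < n) objval += c[basis[i]] * rhs[i];
      for (int j = 0; j < ncol; ++j) {
        double z = 0.0;
        for (int i = 0; i < m; ++i)
          if (basis[i] < n) z += c[basis[i]] * T[(size_t)i * ncol + j];
        obj[j] = z - ((j < n) ? c[j] : 0.0);
      }
    }

    const int jmax = (phase == 1) ? ncol : n;  // artificials never re-enter in phase 2
    while (true) {
      if (++iter > maxit) { res.status = LP_MAXITER; return res; }
      int pc = -1;  // Bland: smallest-index improving column
      for (int j = 0; j < jmax; ++j)
        if (obj[j] < -PIV_EPS) { pc = j; break; }
      if (pc < 0) break;  // phase optimal

      int pr = -1;
      double best = std::numeric_limits<double>::infinity();
      for (int i = 0; i < m; ++i) {
        double a = T[(size_t)i * ncol + pc];
        if (a > PIV_EPS) {
          double ratio = rhs[i] / a;
          if (ratio < best - PIV_EPS ||
              (ratio < best + PIV_EPS && (pr < 0 || basis[i] < basis[pr]))) {
            best = ratio; pr = i;
          }
        }
      }
      if (pr < 0) {
        res.status = (phase == 1) ? LP_INFEASIBLE : LP_UNBOUNDED;
        return res;
      }

      double piv = T[(size_t)pr * ncol + pc];
      for (int j = 0; j < ncol; ++j) T[(size_t)pr * ncol + j] /= piv;
      rhs[pr] /= piv;
      for (int r = 0; r < m; ++r) {
        if (r == pr) continue;
        double f = T[(size_t)r * ncol + pc];
        if (std::fabs(f) < PIV_EPS) continue;
        for (int j = 0; j < ncol; ++j) T[(size_t)r * ncol + j] -= f * T[(size_t)pr * ncol + j];
        rhs[r] -= f * rhs[pr];
      }
      double fo = obj[pc];
      for (int j = 0; j < ncol; ++j) obj[j] -= fo * T[(size_t)pr * ncol + j];
      objval -= fo * rhs[pr];
      basis[pr] = pc;
    }
  }

  res.status = LP_OPTIMAL;
  res.x.assign(n, 0.0);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) res.x[basis[i]] = rhs[i];
  res.obj = 0.0;
  for (int j = 0; j < n; ++j) res.obj += c[j] * res.x[j];
  return res;
}

// maximise (or minimise) obj'v  s.t.  S v = rhs, lb <= v <= ub (all finite).
// Shifts to x = v - lb >= 0 and adds one slack row per upper bound.
static LpResult solve_box(const std::vector<double>& objv,
                          const std::vector<double>& S,  // m x n row-major
                          const std::vector<double>& rhs,
                          const std::vector<double>& lb,
                          const std::vector<double>& ub,
                          int m, int n, bool maximize) {
  const int M = m + n, N = 2 * n;
  std::vector<double> A((size_t)M * N, 0.0), b(M, 0.0), c(N, 0.0);
  for (int i = 0; i < m; ++i) {
    double shift = 0.0;
    for (int j = 0; j < n; ++j) {
      A[(size_t)i * N + j] = S[(size_t)i * n + j];
      shift += S[(size_t)i * n + j] * lb[j];
    }
    b[i] = rhs[i] - shift;
  }
  for (int j = 0; j < n; ++j) {
    A[(size_t)(m + j) * N + j] = 1.0;
    A[(size_t)(m + j) * N + n + j] = 1.0;
    b[m + j] = ub[j] - lb[j];
  }
  for (int j = 0; j < n; ++j) c[j] = maximize ? objv[j] : -objv[j];

  LpResult r = simplex_core(c, A, b, M, N);
  if (r.status == LP_OPTIMAL) {
    std::vector<double> v(n);
    double o = 0.0;
    for (int j = 0; j < n; ++j) { v[j] = r.x[j] + lb[j]; o += objv[j] * v[j]; }
    r.x = v;
    r.obj = o;
  }
  return r;
}

static std::vector<double> mat_to_vec(const NumericMatrix& S) {
  std::vector<double> out((size_t)S.nrow() * S.ncol());
  for (int i = 0; i < S.nrow(); ++i)
    for (int j = 0; j < S.ncol(); ++j)
      out[(size_t)i * S.ncol() + j] = S(i, j);
  return out;
}

// [[Rcpp::export]]
List lp_solve_box_cpp(NumericVector obj, NumericMatrix S, NumericVector rhs,
                      NumericVector lb, NumericVector ub, bool maximize) {
  int m = S.nrow(), n = S.ncol();
  LpResult r = solve_box(as<std::vector<double>>(obj), mat_to_vec(S),
                         as<std::vector<double>>(rhs),
                         as<std::vector<double>>(lb),
                         as<std::vector<double>>(ub), m, n, maximize);
  return List::create(_["status"] = r.status, _["objective"] = r.obj,
                      _["solution"] = r.status == LP_OPTIMAL ? wrap(r.x) : R_NilValue);
}

// Parsimonious FBA: maximise c'v, then minimise total flux sum_j |v_j| at
// that optimum, with every reaction split into non-negative forward and
// reverse components.  Returns the merged signed flux vector.
// [[Rcpp::export]]
List pfba_cpp(NumericMatrix Smat, NumericVector lbv, NumericVector ubv,
              NumericVector objv, bool parsimonious) {
  const int m = Smat.nrow(), n = Smat.ncol();
  std::vector<double> S = mat_to_vec(Smat);
  std::vector<double> lb = as<std::vector<double>>(lbv);
  std::vector<double> ub = as<std::vector<double>>(ubv);
  std::vector<double> cobj = as<std::vector<double>>(objv);
  std::vector<double> zero(m, 0.0);

  LpResult fba = solve_box(cobj, S, zero, lb, ub, m, n, true);
  if (fba.status != LP_OPTIMAL) {
    return List::create(_["status"] = fba.status, _["objective"] = NA_REAL,
                        _["flux"] = R_NilValue, _["total_flux"] = NA_REAL);
  }
  double vopt = fba.obj;

  if (!parsimonious) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += std::fabs(fba.x[j]);
    return List::create(_["status"] = 0, _["objective"] = vopt,
                        _["flux"] = wrap(fba.x), _["total_flux"] = tot);
  }

  // split variables: v_j = off_j + sgn_k x_k  (one or two components per rxn)
  std::vector<int> rxn, sgn;
  std::vector<double> cap, off(n, 0.0);
  for (int j = 0; j < n; ++j) {
    if (lb[j] >= 0.0) {                    // irreversibly forward
      off[j] = lb[j];
      rxn.push_back(j); sgn.push_back(1); cap.push_back(ub[j] - lb[j]);
    } else if (ub[j] <= 0.0) {             // irreversibly backward: v = ub - x
      off[j] = ub[j];
      rxn.push_back(j); sgn.push_back(-1); cap.push_back(ub[j] - lb[j]);
    } else {                               // reversible: forward + reverse part
      rxn.push_back(j); sgn.push_back(1); cap.push_back(ub[j]);
      rxn.push_back(j); sgn.push_back(-1); cap.push_back(-lb[j]);
    }
  }
  const int K = (int)rxn.size();
  const int M2 = m + 1;  // stoichiometry + biomass-pinning row
  std::vector<double> A((size_t)M2 * K, 0.0), b(M2, 0.0), cost(K, 1.0);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < m; ++i)
      A[(size_t)i * K + k] = sgn[k] * S[(size_t)i * n + rxn[k]];
  for (int i = 0; i < m; ++i) {
    double shift = 0.0;
    for (int j = 0; j < n; ++j) shift += S[(size_t)i * n + j] * off[j];
    b[i] = -shift;
  }
  // pin biomass within a hair of the FBA optimum (bounded slack keeps the
  // phase-1 problem feasible in floating point)
  double tol_eq = 1e-9 * std::max(1.0, std::fabs(vopt));
  for (int k = 0; k < K; ++k) A[(size_t)m * K + k] = sgn[k] * cobj[rxn[k]];
  double oshift = 0.0;
  for (int j = 0; j < n; ++j) oshift += cobj[j] * off[j];
  b[m] = vopt - tol_eq - oshift;
  rxn.push_back(-1); sgn.push_back(0);  // slack column on the biomass row
  std::vector<double> A2((size_t)M2 * (K + 1), 0.0);
  for (int i = 0; i < M2; ++i)
    for (int k = 0; k < K; ++k) A2[(size_t)i * (K + 1) + k] = A[(size_t)i * K + k];
  A2[(size_t)m * (K + 1) + K] = -1.0;
  std::vector<double> lo2(K + 1, 0.0), cap2(cap), cost2(cost);
  cap2.push_back(2.0 * tol_eq);
  cost2.push_back(0.0);

  LpResult ps = solve_box(cost2, A2, b, lo2, cap2, M2, K + 1, false);
  if (ps.status != LP_OPTIMAL) {
    // fall back to the FBA vertex (should not happen; keeps caller safe)
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += std::fabs(fba.x[j]);
    return List::create(_["status"] = 0, _["objective"] = vopt,
                        _["flux"] = wrap(fba.x), _["total_flux"] = tot);
  }
  std::vector<double> v(off);
  for (int k = 0; k < K; ++k) v[rxn[k]] += sgn[k] * ps.x[k];
  double tot = 0.0, realized = 0.0;
  for (int j = 0; j < n; ++j) { tot += std::fabs(v[j]); realized += cobj[j] * v[j]; }
  return List::create(_["status"] = 0, _["objective"] = realized,
                      _["flux"] = wrap(v), _["total_flux"] = tot);
}

// Flux variability analysis: per-reaction min/max flux subject to
// c'v >= fraction * vopt (implemented with a bounded slack column).
// [[Rcpp::export]]
NumericMatrix fva_cpp(NumericMatrix Smat, NumericVector lbv, NumericVector ubv,
                      NumericVector objv, double fraction, double vopt) {
  const int m = Smat.nrow(), n = Smat.ncol();
  std::vector<double> S = mat_to_vec(Smat);
  std::vector<double> lb = as<std::vector<double>>(lbv);
  std::vector<double> ub = as<std::vector<double>>(ubv);
  std::vector<double> cobj = as<std::vector<double>>(objv);

  const int M = m + 1, N = n + 1;
  std::vector<double> A((size_t)M * N, 0.0), b(M, 0.0);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) A[(size_t)i * N + j] = S[(size_t)i * n + j];
  for (int j = 0; j < n; ++j) A[(size_t)m * N + j] = cobj[j];
  A[(size_t)m * N + n] = -1.0;
  b[m] = fraction * vopt;

  std::vector<double> lo(lb), hi(ub);
  lo.push_back(0.0);
  // c'v cannot exceed vopt, so the slack needs at most (1 - fraction)*vopt
  hi.push_back(std::max(0.0, (1.0 - fraction) * std::fabs(vopt)) + 1e-6);

  NumericMatrix env(n, 2);
  std::vector<double> e(N, 0.0);
  for (int j = 0; j < n; ++j) {
    e.assign(N, 0.0);
    e[j] = 1.0;
    LpResult lomin = solve_box(e, A, b, lo, hi, M, N, false);
    LpResult lomax = solve_box(e, A, b, lo, hi, M, N, true);
    env(j, 0) = lomin.status == LP_OPTIMAL ? lomin.obj : NA_REAL;
    env(j, 1) = lomax.status == LP_OPTIMAL ? lomax.obj : NA_REAL;
  }
  return env;
}
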