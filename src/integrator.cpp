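// Stiff mass-action ODE integration for small kinetic schemes.
//
// The solver is a second-order L-stable Rosenbrock method with an embedded
// third-order error estimate (the classic ode23s pair of Shampine &
// Reichelt), using the analytic mass-action Jacobian.  Rate constants in
// the schemes handled here span ~0.007 to 1000 s^-1, which makes explicit
// methods useless; an L-stable linearly-implicit method takes steps sized
// by accuracy alone.  Systems are tiny (<= ~12 states) so dense LU solves
// via Armadillo are essentially free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct MassAction {
  mat S;            // n_state x n_reaction stoichiometry (may include flux rows)
  ivec r1, r2;      // 0-based reactant indices per reaction, -1 if absent
  vec k;            // rate constants
  int n;            // number of states

  vec rates(const vec& y) const {
    const int m = S.n_cols;
    vec v(m);
    for (int j = 0; j < m; ++j) {
      double r = k[j];
      if (r1[j] >= 0) r *= y[r1[j]];
      if (r2[j] >= 0) r *= y[r2[j]];
      v[j] = r;
    }
    return v;
  }

  vec f(const vec& y) const { return S * rates(y); }

  // d f / d y via d v_j / d y_i
  mat jac(const vec& y) const {
    const int m = S.n_cols;
    mat dv(m, n, fill::zeros);
    for (int j = 0; j < m; ++j) {
      const int a = r1[j], b = r2[j];
      if (a < 0) continue;
      if (b < 0) {
        dv(j, a) = k[j];
      } else if (a == b) {
        dv(j, a) = 2.0 * k[j] * y[a];
      } else {
        dv(j, a) = k[j] * y[b];
        dv(j, b) = k[j] * y[a];
      }
    }
    return S * dv;
  }
};

const double D_COEF = 1.0 / (2.0 + std::sqrt(2.0));
const double E32 = 6.0 + std::sqrt(2.0);

double err_norm(const vec& e, const vec& y0, const vec& y1,
                double rtol, double atol) {
  double m = 0.0;
  for (uword i = 0; i < e.n_elem; ++i) {
    double sc = atol + rtol * std::max(std::fabs(y0[i]), std::fabs(y1[i]));
    m = std::max(m, std::fabs(e[i]) / sc);
  }
  return m;
}

// One ode23s step of size h from y.  Returns accepted y and error norm.
// The three stage systems share the matrix W = I - h*d*J, factored once.
bool ros_step(const MassAction& sys, const vec& y, double h,
              double rtol, double atol, vec& ynew, double& enorm) {
  mat W = eye(sys.n, sys.n) - (h * D_COEF) * sys.jac(y);
  mat L, U, P;
  if (!lu(L, U, P, W)) return false;
  if (any(abs(U.diag()) < 1e-300)) return false;
  auto lusolve = [&](const vec& b) -> vec {
    return solve(trimatu(U), solve(trimatl(L), P * b));
  };
  vec F0 = sys.f(y);
  vec k1 = lusolve(F0);
  vec F1 = sys.f(y + 0.5 * h * k1);
  vec k2 = lusolve(F1 - k1) + k1;
  ynew = y + h * k2;
  vec F2 = sys.f(ynew);
  vec k3 = lusolve(F2 - E32 * (k2 - F1) - 2.0 * (k1 - F0));
  vec err = (h / 6.0) * (k1 - 2.0 * k2 + k3);
  enorm = err_norm(err, y, ynew, rtol, atol);
  return ynew.is_finite();
}

MassAction make_sys(const mat& S, const ivec& r1, const ivec& r2, const vec& k) {
  MassAction sys;
  sys.S = S; sys.r1 = r1; sys.r2 = r2; sys.k = k;
  sys.n = S.n_rows;
  return sys;
}

double initial_step(const MassAction& sys, const vec& y, double span,
                    double rtol, double atol) {
  vec f0 = sys.f(y);
  double d0 = norm(y, "inf"), d1 = norm(f0, "inf");
  double h = (d1 > 0) ? 0.01 * (atol + rtol * d0) / (atol + rtol * d1) : span * 1e-6;
  h = std::max(h, 1e-14);
  return std::min(h, span);
}

} // namespace

// Integrate from t=0 to each requested output time (strictly increasing,
// first may be 0).  Returns n_state x n_times matrix of states.
// [[Rcpp::export(name = ".ma_integrate_cpp")]]
Rcpp::NumericMatrix ma_integrate_cpp(Rcpp::NumericMatrix stoich,
                                     Rcpp::IntegerVector react1,
                                     Rcpp::IntegerVector react2,
                                     Rcpp::NumericVector rate_k,
                                     Rcpp::NumericVector y0,
                                     Rcpp::NumericVector times,
                                     double rtol, double atol) {
  MassAction sys = make_sys(Rcpp::as<mat>(stoich),
                            Rcpp::as<ivec>(react1), Rcpp::as<ivec>(react2),
                            Rcpp::as<vec>(rate_k));
  const int nt = times.size();
  mat out(sys.n, nt);
  vec y = Rcpp::as<vec>(y0);
  double t = 0.0;
  double tend = times[nt - 1];
  double h = initial_step(sys, y, std::max(tend, 1e-12), rtol, atol);
  int it = 0;
  while (it < nt && times[it] <= t + 1e-300) { out.col(it) = y; ++it; }
  long steps = 0;
  const long max_steps = 5000000;
  while (it < nt) {
    double tnext = times[it];
    if (t + h > tnext) h = tnext - t;
    vec ynew; double enorm;
    bool ok = ros_step(sys, y, h, rtol, atol, ynew, enorm);
    if (ok && enorm <= 1.0) {
      t += h;
      y = ynew;
      if (std::fabs(t - tnext) <= 1e-12 * std::max(1.0, std::fabs(tnext))) {
        out.col(it) = y;
        ++it;
      }
      double fac = (enorm > 0) ? 0.9 * std::pow(enorm, -1.0 / 3.0) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      double fac = ok ? std::max(0.1, 0.9 * std::pow(enorm, -1.0 / 3.0)) : 0.1;
      h *= fac;
      if (h < 1e-15 * std::max(1.0, t))
        Rcpp::stop("integrator step size underflow at t=%g", t);
    }
    if (++steps > max_steps)
      Rcpp::stop("integrator exceeded maximum step count at t=%g", t);
  }
  return Rcpp::wrap(out);
}

// Integrate until max |dy/dt| < ftol (relaxation to equilibrium), or until
// t exceeds tmax.  Returns final state; attribute 'converged' and 'time'.
// [[Rcpp::export(name = ".ma_equilibrate_cpp")]]
Rcpp::NumericVector ma_equilibrate_cpp(Rcpp::NumericMatrix stoich,
                                       Rcpp::IntegerVector react1,
                                       Rcpp::IntegerVector react2,
                                       Rcpp::NumericVector rate_k,
                                       Rcpp::NumericVector y0,
                                       double ftol, double tmax,
                                       double rtol, double atol) {
  MassAction sys = make_sys(Rcpp::as<mat>(stoich),
                            Rcpp::as<ivec>(react1), Rcpp::as<ivec>(react2),
                            Rcpp::as<vec>(rate_k));
  vec y = Rcpp::as<vec>(y0);
  double t = 0.0;
  double h = initial_step(sys, y, tmax, rtol, atol);
  bool converged = norm(sys.f(y), "inf") < ftol;
  long steps = 0;
  while (!converged && t < tmax) {
    if (t + h > tmax) h = tmax - t;
    vec ynew; double enorm;
    bool ok = ros_step(sys, y, h, rtol, atol, ynew, enorm);
    if (ok && enorm <= 1.0) {
      t += h;
      y = ynew;
      double fac = (enorm > 0) ? 0.9 * std::pow(enorm, -1.0 / 3.0) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
      converged = norm(sys.f(y), "inf") < ftol;
    } else {
      h *= ok ? std::max(0.1, 0.9 * std::pow(enorm, -1.0 / 3.0)) : 0.1;
      if (h < 1e-15 * std::max(1.0, t))
        Rcpp::stop("equilibration step size underflow at t=%g", t);
    }
    if (++steps > 5000000)
      Rcpp::stop("equilibration exceeded maximum step count");
  }
  Rcpp::NumericVector out = Rcpp::wrap(y);
  out.attr("converged") = converged;
  out.attr("time") = t;
  return out;
}
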