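// Compiled core for the KLK5-LEKTI-PAR2 network: right-hand side, analytic
// Jacobian, and damped-Newton steady-state enumeration. State ordering is
// fixed as (L, K, Kact, C, P, Pact); parameter ordering must match
// .param_order() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Parameter vector slots (see R/parameters.R .param_order())
enum par {
  KON, KOFF, KA, KP, DL, DK, DKACT, DC, DP, DPACT,
  RHOL, MK, MP, KI, BP, BL, BK, KAPPAK, KAPPAL, ALPHAK, ALPHAL, MU,
  NPAR
};

static inline double f_K(const vec& p, double Pact) {
  return p[BK] + p[KAPPAK] * p[MU] + p[ALPHAK] * Pact;
}

// Model 1: linear positive feedback; Model 2: saturating inhibition with
// strength alphaL and inhibition constant kI.
static inline double f_L(const vec& p, double Pact, int variant) {
  const double base = p[BL] + p[KAPPAL] * p[MU];
  if (variant == 1) return p[RHOL] * (base + p[ALPHAL] * Pact);
  return p[RHOL] * base * p[KI] / (p[KI] + p[ALPHAL] * Pact);
}

static vec rhs_(const vec& x, const vec& p, int variant) {
  const double L = x[0], K = x[1], Ka = x[2], C = x[3], P = x[4], Pa = x[5];
  const double act   = p[KA] * Ka * K / (p[MK] + K);
  const double assoc = p[KON] * L * Ka;
  const double dis   = p[KOFF] * C;
  const double pflux = p[KP] * Ka * P / (p[MP] + P);
  vec dx(6);
  dx[0] = f_L(p, Pa, variant) - assoc + dis - p[DL] * L;
  dx[1] = f_K(p, Pa) - act - p[DK] * K;
  dx[2] = act - assoc + dis - p[DKACT] * Ka;
  dx[3] = assoc - dis - p[DC] * C;
  dx[4] = p[BP] - pflux - p[DP] * P;
  dx[5] = pflux - p[DPACT] * Pa;
  return dx;
}

static mat jac_(const vec& x, const vec& p, int variant) {
  const double L = x[0], K = x[1], Ka = x[2], P = x[4], Pa = x[5];
  const double dact_dK  = p[KA] * Ka * p[MK] / std::pow(p[MK] + K, 2);
  const double dact_dKa = p[KA] * K / (p[MK] + K);
  const double dpf_dP   = p[KP] * Ka * p[MP] / std::pow(p[MP] + P, 2);
  const double dpf_dKa  = p[KP] * P / (p[MP] + P);
  double dfL_dPa;
  if (variant == 1) {
    dfL_dPa = p[RHOL] * p[ALPHAL];
  } else {
    const double den = p[KI] + p[ALPHAL] * Pa;
    dfL_dPa = -p[RHOL] * (p[BL] + p[KAPPAL] * p[MU]) * p[KI] * p[ALPHAL] /
              (den * den);
  }
  mat J(6, 6, fill::zeros);
  // dL/dt
  J(0, 0) = -p[KON] * Ka - p[DL];
  J(0, 2) = -p[KON] * L;
  J(0, 3) = p[KOFF];
  J(0, 5) = dfL_dPa;
  // dK/dt
  J(1, 1) = -dact_dK - p[DK];
  J(1, 2) = -dact_dKa;
  J(1, 5) = p[ALPHAK];
  // dKact/dt
  J(2, 0) = -p[KON] * Ka;
  J(2, 1) = dact_dK;
  J(2, 2) = dact_dKa - p[KON] * L - p[DKACT];
  J(2, 3) = p[KOFF];
  // dC/dt
  J(3, 0) = p[KON] * Ka;
  J(3, 2) = p[KON] * L;
  J(3, 3) = -p[KOFF] - p[DC];
  // dP/dt
  J(4, 2) = -dpf_dKa;
  J(4, 4) = -dpf_dP - p[DP];
  // dPact/dt
  J(5, 2) = dpf_dKa;
  J(5, 4) = dpf_dP;
  J(5, 5) = -p[DPACT];
  return J;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
arma::vec rhs_cpp(const arma::vec& state, const arma::vec& pars, int variant) {
  return rhs_(state, pars, variant);
}

// [[Rcpp::export(name = ".jac_cpp")]]
arma::mat jac_cpp(const arma::vec& state, const arma::vec& pars, int variant) {
  return jac_(state, pars, variant);
}

// Damped Newton iteration with projection onto the non-negative orthant.
// Returns the root (residual below tol) or a vector of NaN on failure.
static vec newton_(vec x, const vec& p, int variant, double tol, int maxit) {
  for (int it = 0; it < maxit; ++it) {
    vec f = rhs_(x, p, variant);
    double r0 = norm(f, "inf");
    if (r0 < tol) return x;
    mat J = jac_(x, p, variant);
    vec step;
    bool ok = solve(step, J, -f, solve_opts::no_approx);
    if (!ok || !step.is_finite()) break;
    double lambda = 1.0;
    bool accepted = false;
    for (int h = 0; h < 30; ++h) {
      vec xn = x + lambda * step;
      xn.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      vec fn = rhs_(xn, p, variant);
      if (fn.is_finite() && norm(fn, "inf") < r0) {
        x = xn;
        accepted = true;
        break;
      }
      lambda *= 0.5;
    }
    if (!accepted) break;
  }
  vec f = rhs_(x, p, variant);
  if (f.is_finite() && norm(f, "inf") < tol) return x;
  return vec(6, fill::value(datum::nan));
}

// [[Rcpp::export(name = ".newton_cpp")]]
arma::vec newton_cpp(const arma::vec& start, const arma::vec& pars,
                     int variant, double tol, int maxit) {
  return newton_(start, pars, variant, tol, maxit);
}

// Multi-start enumeration: run Newton from every row of `starts`, keep
// converged non-negative roots, merge duplicates within relative tolerance
// `dedup` (keeping the lower-residual representative).
// [[Rcpp::export(name = ".enumerate_cpp")]]
arma::mat enumerate_cpp(const arma::mat& starts, const arma::vec& pars,
                        int variant, double tol, double dedup, int maxit) {
  std::vector<vec> roots;
  std::vector<double> resid;
  for (uword i = 0; i < starts.n_rows; ++i) {
    vec x = newton_(starts.row(i).t(), pars, variant, tol, maxit);
    if (!x.is_finite()) continue;
    double r = norm(rhs_(x, pars, variant), "inf");
    bool dup = false;
    for (size_t j = 0; j < roots.size(); ++j) {
      double scale = std::max(1.0, std::max(norm(x, "inf"),
                                            norm(roots[j], "inf")));
      if (norm(x - roots[j], "inf") / scale < dedup) {
        dup = true;
        if (r < resid[j]) { roots[j] = x; resid[j] = r; }
        break;
      }
    }
    if (!dup) { roots.push_back(x); resid.push_back(r); }
  }
  mat out(roots.size(), 7);
  for (size_t j = 0; j < roots.size(); ++j) {
    out.submat(j, 0, j, 5) = roots[j].t();
    out(j, 6) = resid[j];
  }
  return out;
}
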