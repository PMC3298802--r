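// Compiled core: piecewise-exact solution of the linear compartmental system
// (eigendecomposition per parameter set, matrix-exponential fallback) and the
// Laplace-with-interaction marginal-likelihood objective with per-subject
// Newton search for the conditional random-effect modes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Canonical parameter order shared with R/model_spec.R (param_names()):
//  0 Cl   1 V1   2 V2   3 V3   4 V4   5 V5   6 Q2   7 Q3   8 Q4   9 Q5
// 10 k40 11 k50 12 Kin 13 k46 14 k58 15 k47 16 k59 17 k60 18 k80 19 k70 20 k90
enum ParIdx { iCl = 0, iV1, iV2, iV3, iV4, iV5, iQ2, iQ3, iQ4, iQ5,
              ik40, ik50, iKin, ik46, ik58, ik47, ik59, ik60, ik80, ik70, ik90 };

static inline cx_double phi1z(cx_double z) {
  if (std::abs(z) < 1e-5)
    return 1.0 + z / 2.0 + z * z / 6.0 + z * z * z / 24.0;
  return (std::exp(z) - 1.0) / z;
}
static inline cx_double phi2z(cx_double z) {
  if (std::abs(z) < 1e-4)
    return 0.5 + z / 6.0 + z * z / 24.0 + z * z * z / 120.0;
  return (std::exp(z) - 1.0 - z) / (z * z);
}

// Rate matrix and endogenous (zero-order) input over the active compartments.
// 'active' holds compartment numbers 1..9 (sorted); the state order follows it.
static void build_system(const vec& p, const ivec& active, mat& A, vec& b) {
  const int n = active.n_elem;
  ivec pos(10);
  pos.fill(-1);
  for (int s = 0; s < n; ++s) pos[active[s]] = s;
  A.zeros(n, n);
  b.zeros(n);
  const int c1 = pos[1];
  if (c1 < 0) Rcpp::stop("central plasma compartment (1) must be active");
  double loss1 = p[iCl] / p[iV1];
  // peripheral / brain exchange pairs: (comp, Q, V)
  const int cmp[4] = {2, 3, 4, 5};
  const int qi[4] = {iQ2, iQ3, iQ4, iQ5};
  const int vi[4] = {iV2, iV3, iV4, iV5};
  for (int k = 0; k < 4; ++k) {
    int s = pos[cmp[k]];
    if (s < 0) continue;
    double Q = p[qi[k]], V = p[vi[k]];
    loss1 += Q / p[iV1];
    A(c1, s) += Q / V;
    A(s, c1) += Q / p[iV1];
    A(s, s) -= Q / V;
  }
  A(c1, c1) -= loss1;
  if (pos[4] >= 0) { A(pos[4], pos[4]) -= p[ik40]; b[pos[4]] = p[iKin]; }
  if (pos[5] >= 0) { A(pos[5], pos[5]) -= p[ik50]; b[pos[5]] = p[iKin]; }
  // metabolite compartments live on the concentration scale: formation is
  // k * (parent ECF concentration), first-order loss
  struct Met { int comp, parent, kf, ke, vpar; };
  const Met mets[4] = { {6, 4, ik46, ik60, iV4}, {7, 4, ik47, ik70, iV4},
                        {8, 5, ik58, ik80, iV5}, {9, 5, ik59, ik90, iV5} };
  for (int k = 0; k < 4; ++k) {
    int s = pos[mets[k].comp];
    if (s < 0) continue;
    int sp = pos[mets[k].parent];
    if (sp < 0) Rcpp::stop("metabolite compartment requires its parent ECF compartment");
    A(s, sp) += p[mets[k].kf] / p[mets[k].vpar];
    A(s, s) -= p[mets[k].ke];
  }
}

// [[Rcpp::export]]
Rcpp::List build_system_cpp(const arma::vec& p, const arma::ivec& active) {
  mat A; vec b;
  build_system(p, active, A, b);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("b") = b);
}

// Piecewise solver state: eigendecomposition of A with matrix-exponential
// fallback when A is (numerically) defective.
struct LinSolver {
  int n;
  mat A;
  bool use_eig;
  cx_mat E, Einv;
  cx_vec lam;

  void init(const mat& A_) {
    A = A_;
    n = A.n_rows;
    use_eig = false;
    cx_vec lv; cx_mat Ev;
    if (eig_gen(lv, Ev, A)) {
      cx_mat Einv_;
      if (inv(Einv_, Ev)) {
        // accept the decomposition only if it reconstructs A accurately
        double rel = norm(real(Ev * diagmat(lv) * Einv_) - A, "fro") /
                     (norm(A, "fro") + 1e-300);
        if (rel < 1e-9) {
          E = Ev; Einv = Einv_; lam = lv; use_eig = true;
        }
      }
    }
  }

  // advance over [0, dt] with constant input u; returns x(dt), accumulates
  // the integral of x over the segment into iseg
  void step(const vec& x0, const vec& u, double dt, vec& x1, vec& iseg) const {
    if (use_eig) {
      cx_vec w0 = Einv * cx_vec(x0, vec(n, fill::zeros));
      cx_vec wu = Einv * cx_vec(u, vec(n, fill::zeros));
      cx_vec ex(n), p1(n), p2(n);
      for (int i = 0; i < n; ++i) {
        cx_double z = lam[i] * dt;
        ex[i] = std::exp(z);
        p1[i] = phi1z(z) * dt;
        p2[i] = phi2z(z) * dt * dt;
      }
      x1 = real(E * (ex % w0 + p1 % wu));
      iseg = real(E * (p1 % w0 + p2 % wu));
    } else {
      // augmented exponential: z = (x, s, Ix) with the input column scaled to
      // unit norm for conditioning
      int m = 2 * n + 1;
      double unorm = norm(u, 2);
      vec uh = (unorm > 0) ? vec(u / unorm) : u;
      mat M(m, m, fill::zeros);
      M.submat(0, 0, n - 1, n - 1) = A;
      M.submat(0, n, n - 1, n) = uh;
      M.submat(n + 1, 0, m - 1, n - 1) = eye(n, n);
      mat eM;
      bool ok = true;
      try {
        ok = expmat(eM, M * dt);
      } catch (...) {
        ok = false;
      }
      if (!ok) {
        x1.set_size(n); x1.fill(datum::nan);
        iseg = x1;
        return;
      }
      vec z0(m, fill::zeros);
      z0.subvec(0, n - 1) = x0;
      z0[n] = (unorm > 0) ? unorm : 1.0;
      vec z1 = eM * z0;
      x1 = z1.subvec(0, n - 1);
      iseg = z1.subvec(n + 1, m - 1);
    }
  }
};

// Walk the time axis from t0, breaking at infusion on/off switches and at all
// requested output times; returns states at 'times' and cumulative integrals
// at every breakpoint so window integrals can be assembled by differencing.
static void walk(const LinSolver& S, const vec& b_endo, const vec& x0, double t0,
                 const mat& infusions, int dose_state, const vec& bp,
                 mat& x_at_bp, mat& cumint_at_bp) {
  const int n = S.n, nb = bp.n_elem;
  x_at_bp.set_size(nb, n);
  cumint_at_bp.set_size(nb, n);
  vec x = x0, cum(n, fill::zeros);
  double tcur = t0;
  int k0 = 0;
  // bp must start at t0
  x_at_bp.row(0) = x.t();
  cumint_at_bp.row(0) = cum.t();
  for (int k = 1; k < nb; ++k) {
    double t1 = bp[k];
    double dt = t1 - tcur;
    if (dt > 0) {
      vec u = b_endo;
      double tm = 0.5 * (tcur + t1);
      for (uword j = 0; j < infusions.n_rows; ++j) {
        if (infusions(j, 0) < tm && tm < infusions(j, 1))
          u[dose_state] += infusions(j, 2);
      }
      vec x1, iseg;
      S.step(x, u, dt, x1, iseg);
      x = x1;
      cum += iseg;
      tcur = t1;
    }
    x_at_bp.row(k) = x.t();
    cumint_at_bp.row(k) = cum.t();
    (void)k0;
  }
}

static vec make_breakpoints(double t0, const mat& infusions, const vec& times,
                            const mat& windows, double t_end_extra) {
  std::vector<double> v;
  v.push_back(t0);
  for (uword j = 0; j < infusions.n_rows; ++j) {
    v.push_back(infusions(j, 0));
    v.push_back(infusions(j, 1));
  }
  for (uword j = 0; j < times.n_elem; ++j) v.push_back(times[j]);
  for (uword j = 0; j < windows.n_rows; ++j) {
    v.push_back(windows(j, 0));
    v.push_back(windows(j, 1));
  }
  if (R_finite(t_end_extra)) v.push_back(t_end_extra);
  std::sort(v.begin(), v.end());
  std::vector<double> u;
  for (double t : v) {
    if (t < t0 - 1e-12) continue;
    if (u.empty() || t - u.back() > 1e-10) u.push_back(t);
  }
  return vec(u);
}

static int find_bp(const vec& bp, double t) {
  // bp sorted; exact-ish match
  uword lo = 0, hi = bp.n_elem;
  while (lo < hi) {
    uword mid = (lo + hi) / 2;
    if (bp[mid] < t - 1e-9) lo = mid + 1; else hi = mid;
  }
  return (int)lo;
}

// [[Rcpp::export]]
Rcpp::List traj_solve_cpp(const arma::mat& A, const arma::vec& b_endo,
                          const arma::vec& x0, double t0,
                          const arma::mat& infusions, int dose_state,
                          const arma::vec& times, const arma::mat& windows) {
  LinSolver S;
  S.init(A);
  vec bp = make_breakpoints(t0, infusions, times, windows, NA_REAL);
  mat xb, cb;
  walk(S, b_endo, x0, t0, infusions, dose_state, bp, xb, cb);
  const int n = S.n;
  mat xt(times.n_elem, n), wint(windows.n_rows, n), wavg(windows.n_rows, n);
  for (uword j = 0; j < times.n_elem; ++j) xt.row(j) = xb.row(find_bp(bp, times[j]));
  for (uword j = 0; j < windows.n_rows; ++j) {
    rowvec d = cb.row(find_bp(bp, windows(j, 1))) - cb.row(find_bp(bp, windows(j, 0)));
    wint.row(j) = d;
    wavg.row(j) = d / (windows(j, 1) - windows(j, 0));
  }
  return Rcpp::List::create(Rcpp::Named("state") = xt,
                            Rcpp::Named("wint") = wint,
                            Rcpp::Named("wavg") = wavg,
                            Rcpp::Named("eig") = S.use_eig);
}

// ---------------------------------------------------------------------------
// Laplace objective
// ---------------------------------------------------------------------------

struct SubjData {
  double t0;
  mat infusions;        // start, end, rate (ng/min into central)
  vec pt_time;          // point observations
  ivec pt_state;
  ivec pt_vol;          // param index for volume scaling, -1 = none
  mat win;              // window observations
  ivec win_state;
  ivec win_vol;
  vec y;                // values, points first then windows
  ivec err_id;          // index into sigma
  ivec err_prop;        // 1 = proportional, 0 = additive
  vec bp;               // precomputed breakpoints
  vec base;             // length-21 subject base parameters
};

static SubjData unpack_subject(const Rcpp::List& s) {
  SubjData d;
  d.t0 = Rcpp::as<double>(s["t0"]);
  d.infusions = Rcpp::as<mat>(s["infusions"]);
  d.pt_time = Rcpp::as<vec>(s["pt_time"]);
  d.pt_state = Rcpp::as<ivec>(s["pt_state"]);
  d.pt_vol = Rcpp::as<ivec>(s["pt_vol"]);
  d.win = Rcpp::as<mat>(s["win"]);
  d.win_state = Rcpp::as<ivec>(s["win_state"]);
  d.win_vol = Rcpp::as<ivec>(s["win_vol"]);
  d.y = Rcpp::as<vec>(s["y"]);
  d.err_id = Rcpp::as<ivec>(s["err_id"]);
  d.err_prop = Rcpp::as<ivec>(s["err_prop"]);
  d.base = Rcpp::as<vec>(s["base"]);
  d.bp = make_breakpoints(d.t0, d.infusions, d.pt_time, d.win, NA_REAL);
  return d;
}

// individual parameter assembly; iiv_apply[j] >= 0 gives the eta index
// multiplying parameter j (hemisphere-shared random effects map both V4 and
// V5 to the same eta, etc.)
static vec assemble_p(const SubjData& d, const vec& theta, const ivec& use_theta,
                      const ivec& cons_src, const ivec& iiv_apply, const vec& eta) {
  vec p = d.base;
  for (int j = 0; j < 21; ++j) if (use_theta[j]) p[j] = theta[j];
  for (int j = 0; j < 21; ++j)
    if (iiv_apply[j] >= 0) p[j] *= std::exp(eta[iiv_apply[j]]);
  for (int j = 0; j < 21; ++j) if (cons_src[j] >= 0) p[j] = p[cons_src[j]];
  return p;
}

// model predictions (concentration scale) for all observations of a subject
static bool predict_subject(const SubjData& d, const vec& p, const ivec& active,
                            vec& f) {
  mat A; vec b;
  build_system(p, active, A, b);
  LinSolver S;
  S.init(A);
  vec x0;
  if (norm(b, "inf") > 0) {
    bool ok = true;
    try {
      ok = solve(x0, A, -b, solve_opts::no_approx);
    } catch (...) {
      ok = false;
    }
    if (!ok) return false;
  } else {
    x0 = vec(S.n, fill::zeros);
  }
  mat xb, cb;
  walk(S, b, x0, d.t0, d.infusions, 0, d.bp, xb, cb);
  const int np = d.pt_time.n_elem, nw = d.win.n_rows;
  f.set_size(np + nw);
  for (int j = 0; j < np; ++j) {
    double val = xb(find_bp(d.bp, d.pt_time[j]), d.pt_state[j]);
    if (d.pt_vol[j] >= 0) val /= p[d.pt_vol[j]];
    f[j] = val;
  }
  for (int j = 0; j < nw; ++j) {
    int s0 = find_bp(d.bp, d.win(j, 0)), s1 = find_bp(d.bp, d.win(j, 1));
    double val = (cb(s1, d.win_state[j]) - cb(s0, d.win_state[j])) /
                 (d.win(j, 1) - d.win(j, 0));
    if (d.win_vol[j] >= 0) val /= p[d.win_vol[j]];
    f[np + j] = val;
  }
  return f.is_finite();
}

static const double VAR_FLOOR = 1e-24;

// -2 log joint density (up to the constant that cancels in the Laplace
// approximation): residual part + eta penalty + normalising terms
static double minus2lj(const SubjData& d, const vec& f, const vec& sigma,
                       const vec& eta, const vec& omega2) {
  double l = 0;
  for (uword j = 0; j < d.y.n_elem; ++j) {
    double s = sigma[d.err_id[j]];
    double v = d.err_prop[j] ? s * s * f[j] * f[j] : s * s;
    if (v < VAR_FLOOR) v = VAR_FLOOR;
    double r = d.y[j] - f[j];
    l += std::log(2.0 * M_PI * v) + r * r / v;
  }
  for (uword k = 0; k < eta.n_elem; ++k)
    l += std::log(omega2[k]) + eta[k] * eta[k] / omega2[k];
  return l;
}

// Inner Newton search for the conditional eta mode, starting from the given
// eta (updated in place); Gauss-Newton curvature, finite-difference
// sensitivities, damped steps. Returns the final -2 log joint value; Hhalf
// receives the curvature (J'WJ + Omega^-1) at the mode.
static double inner_newton(const SubjData& d, const vec& theta, const ivec& use_theta,
                           const ivec& cons_src, const ivec& iiv_apply, const vec& omega2,
                           const vec& sigma, const ivec& active, vec& eta,
                           double tol, int maxit, mat& Hhalf, bool& ok) {
  const int q = omega2.n_elem;
  const int nobs = d.y.n_elem;
  ok = true;
  vec f0;
  mat J(nobs, q);
  vec p = assemble_p(d, theta, use_theta, cons_src, iiv_apply, eta);
  if (!predict_subject(d, p, active, f0)) { ok = false; return 1e10; }
  double l0 = minus2lj(d, f0, sigma, eta, omega2);
  bool have_H = false;
  for (int it = 0; it < maxit; ++it) {
    // finite-difference sensitivities of predictions wrt eta
    for (int k = 0; k < q; ++k) {
      double h = 1e-5;
      vec e2 = eta; e2[k] += h;
      vec fk;
      vec pk = assemble_p(d, theta, use_theta, cons_src, iiv_apply, e2);
      if (!predict_subject(d, pk, active, fk)) { ok = false; return 1e10; }
      J.col(k) = (fk - f0) / h;
    }
    vec g(q, fill::zeros);
    Hhalf.zeros();
    for (int j = 0; j < nobs; ++j) {
      double s = sigma[d.err_id[j]];
      double v = d.err_prop[j] ? s * s * f0[j] * f0[j] : s * s;
      if (v < VAR_FLOOR) v = VAR_FLOOR;
      double r = d.y[j] - f0[j];
      double w = 1.0 / v;
      double dvdf = d.err_prop[j] ? 2.0 * s * s * f0[j] : 0.0;
      for (int k = 0; k < q; ++k) {
        g[k] += (-2.0 * r * w + (w - r * r * w * w) * dvdf) * J(j, k);
        for (int k2 = k; k2 < q; ++k2)
          Hhalf(k, k2) += w * J(j, k) * J(j, k2);
      }
    }
    Hhalf = symmatu(Hhalf);
    for (int k = 0; k < q; ++k) {
      g[k] += 2.0 * eta[k] / omega2[k];
      Hhalf(k, k) += 1.0 / omega2[k];
    }
    have_H = true;
    vec step;
    if (!solve(step, Hhalf, -0.5 * g)) { ok = false; break; }
    // damped update
    double lam = 1.0;
    vec eta_new = eta + step;
    vec f1;
    double l1 = datum::inf;
    for (int ls = 0; ls < 25; ++ls) {
      eta_new = eta + lam * step;
      vec p1 = assemble_p(d, theta, use_theta, cons_src, iiv_apply, eta_new);
      if (predict_subject(d, p1, active, f1)) {
        l1 = minus2lj(d, f1, sigma, eta_new, omega2);
        if (l1 <= l0 + 1e-10) break;
      }
      lam *= 0.5;
    }
    if (!std::isfinite(l1) || l1 > l0 + 1e-8) break;  // no further progress
    double delta = norm(lam * step, "inf");
    eta = clamp(eta_new, -20.0, 20.0);
    f0 = f1;
    l0 = l1;
    if (delta < tol) break;
    if (it == maxit - 1) ok = false;
  }
  if (!have_H || !std::isfinite(l0)) { ok = false; return 1e10; }
  return l0;
}

// Laplace contribution of one subject; eta is updated in place. The warm
// start is validated against a cold start at eta = 0 so the objective does
// not depend on the optimisation history.
static double subject_obj(const SubjData& d, const vec& theta, const ivec& use_theta,
                          const ivec& cons_src, const ivec& iiv_apply, const vec& omega2,
                          const vec& sigma, const ivec& active, vec& eta,
                          double tol, int maxit, bool& ok) {
  const int q = omega2.n_elem;
  ok = true;
  if (q == 0) {
    vec f0;
    vec p = assemble_p(d, theta, use_theta, cons_src, iiv_apply, vec());
    if (!predict_subject(d, p, active, f0)) { ok = false; return 1e10; }
    double l = minus2lj(d, f0, sigma, vec(), vec());
    if (!std::isfinite(l)) { ok = false; return 1e10; }
    return l;
  }
  mat Hw(q, q), Hz(q, q);
  bool ok_w = true, ok_z = true;
  double lw = datum::inf;
  bool warm = norm(eta, "inf") > 0;
  vec eta_w = eta;
  if (warm)
    lw = inner_newton(d, theta, use_theta, cons_src, iiv_apply, omega2, sigma,
                      active, eta_w, tol, maxit, Hw, ok_w);
  double lz = datum::inf;
  vec eta_z(q, fill::zeros);
  if (!warm || !ok_w || !std::isfinite(lw))
    lz = inner_newton(d, theta, use_theta, cons_src, iiv_apply, omega2, sigma,
                      active, eta_z, tol, maxit, Hz, ok_z);
  double l0;
  mat Hhalf;
  if (lw <= lz) {
    l0 = lw; Hhalf = Hw; eta = eta_w; ok = ok_w;
  } else {
    l0 = lz; Hhalf = Hz; eta = eta_z; ok = ok_z;
  }
  if (!std::isfinite(l0)) { ok = false; return 1e10; }
  double ld, sign;
  if (!log_det(ld, sign, Hhalf) || sign <= 0 || !std::isfinite(ld)) {
    ok = false;
    return 1e10;
  }
  return l0 + ld;
}

// [[Rcpp::export]]
Rcpp::NumericVector predict_subject_cpp(const Rcpp::List& subject,
                                        const arma::vec& theta,
                                        const arma::ivec& use_theta,
                                        const arma::ivec& cons_src,
                                        const arma::ivec& iiv_apply,
                                        const arma::vec& eta,
                                        const arma::ivec& active) {
  SubjData d = unpack_subject(subject);
  vec p = assemble_p(d, theta, use_theta, cons_src, iiv_apply, eta);
  vec f;
  if (!predict_subject(d, p, active, f))
    Rcpp::stop("prediction failed (singular or non-finite system)");
  return Rcpp::wrap(f);
}

// [[Rcpp::export]]
Rcpp::List laplace_obj_cpp(const Rcpp::List& subjects, const arma::vec& theta,
                           const arma::ivec& use_theta, const arma::ivec& cons_src,
                           const arma::ivec& iiv_apply, const arma::vec& omega2,
                           const arma::vec& sigma, const arma::ivec& active,
                           arma::mat eta_init, double inner_tol, int inner_maxit) {
  const int S = subjects.size();
  const int q = omega2.n_elem;
  double total = 0;
  ivec conv(S, fill::ones);
  if ((int)eta_init.n_rows != q || (int)eta_init.n_cols != S)
    eta_init = mat(q, S, fill::zeros);
  for (int i = 0; i < S; ++i) {
    SubjData d = unpack_subject(subjects[i]);
    vec eta = (q > 0) ? vec(eta_init.col(i)) : vec();
    bool ok = true;
    double li = subject_obj(d, theta, use_theta, cons_src, iiv_apply, omega2, sigma,
                            active, eta, inner_tol, inner_maxit, ok);
    if (q > 0) eta_init.col(i) = eta;
    if (!ok) conv[i] = 0;
    total += li;
  }
  return Rcpp::List::create(Rcpp::Named("value") = total,
                            Rcpp::Named("eta") = eta_init,
                            Rcpp::Named("conv") = conv);
}
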