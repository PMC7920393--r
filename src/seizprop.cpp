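#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear-then-exponential excitation rate.
//
// fhat(c, y) is the bilinear interpolant through the four anchors
// (c_a=-1, y_a=0) -> qaa, (c_a, y_b=1) -> qab, (c_b=1, y_a) -> qba,
// (c_b, y_b) -> qbb, extended by the same algebraic form outside the
// anchor square.  The rate is exp(fhat), strictly positive.
static inline double fhat_eval(const double* q4, double c, double y,
                               double* dc, double* dq) {
  const double wa = 0.5 * (1.0 - c);
  const double wb = 0.5 * (1.0 + c);
  const double f = (q4[0] * wa + q4[2] * wb) * (1.0 - y)
                 + (q4[1] * wa + q4[3] * wb) * y;
  if (dc) *dc = 0.5 * ((q4[2] - q4[0]) * (1.0 - y) + (q4[3] - q4[1]) * y);
  if (dq) {
    dq[0] = wa * (1.0 - y);
    dq[1] = wa * y;
    dq[2] = wb * (1.0 - y);
    dq[3] = wb * y;
  }
  return f;
}

// [[Rcpp::export]]
NumericVector excitation_rate_cpp(NumericVector q4, NumericVector c,
                                  NumericVector y) {
  const R_xlen_t n = std::max(c.size(), y.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double ci = c[i % c.size()], yi = y[i % y.size()];
    out[i] = std::exp(fhat_eval(&q4[0], ci, yi, nullptr, nullptr));
  }
  return out;
}

// Event-driven solution of z_i' = f_q(c_i, sum_j w_ij H(z_j - 1)),
// z_i(0) = 0, onset t_i = min{t : z_i >= 1}.  Between threshold
// crossings each z_i grows linearly, so the trajectory is solved
// exactly event by event.  Optionally propagates forward sensitivities
// of the onset times w.r.t. c (n columns) and the full q4 (4 columns).
//
// Regions that have not crossed the threshold by t_max keep t = +Inf
// (their sensitivity rows stay zero).
struct SimResult {
  std::vector<double> t;
  std::vector<double> dt;   // n x (n + 4), row-major, only if grad
  bool grad;
};

static SimResult simulate_core(const NumericMatrix& W, const double* q4,
                               const NumericVector& c, double t_max,
                               bool grad) {
  const int n = W.nrow();
  const int np = n + 4;  // parameters: c_1..c_n, qaa, qab, qba, qbb
  SimResult res;
  res.grad = grad;
  res.t.assign(n, R_PosInf);
  if (grad) res.dt.assign((size_t)n * np, 0.0);

  // scratch buffers reused across calls (single-threaded R)
  static std::vector<char> seized;
  static std::vector<double> z, y, slope, dsl_c, dsl_q, dz, dtau;
  seized.assign(n, 0);
  z.assign(n, 0.0); y.assign(n, 0.0); slope.assign(n, 0.0);
  dsl_c.assign(n, 0.0);
  dsl_q.assign(4 * (size_t)n, 0.0);
  // dz: gradient of z_i at current event time tau; tau gradient dtau.
  if (grad) {
    dz.assign((size_t)n * np, 0.0);
    dtau.assign(np, 0.0);
  }

  auto recompute_slope = [&](int i) {
    double dc, dq[4];
    const double f = fhat_eval(q4, c[i], y[i], grad ? &dc : nullptr,
                               grad ? dq : nullptr);
    const double s = std::exp(f);
    slope[i] = s;
    if (grad) {
      dsl_c[i] = s * dc;
      for (int k = 0; k < 4; ++k) dsl_q[4 * (size_t)i + k] = s * dq[k];
    }
  };

  for (int i = 0; i < n; ++i) recompute_slope(i);

  double tau = 0.0;
  int n_seized = 0;
  static std::vector<int> batch;
  static std::vector<double> Tcand, dstep;
  Tcand.assign(n, 0.0);
  if (grad) dstep.assign(np, 0.0);

  while (n_seized < n) {
    // next event: earliest threshold crossing among active regions
    double Tmin = R_PosInf;
    for (int i = 0; i < n; ++i) {
      if (seized[i]) continue;
      Tcand[i] = tau + (1.0 - z[i]) / slope[i];
      if (Tcand[i] < Tmin) Tmin = Tcand[i];
    }
    if (!(Tmin <= t_max)) break;  // nothing more within the horizon

    // batch simultaneous crossings (ties are a measure-zero event for
    // continuous c; batching matches the continuous-time semantics)
    const double tol = 1e-12 * (1.0 + std::fabs(Tmin));
    batch.clear();
    for (int i = 0; i < n; ++i)
      if (!seized[i] && Tcand[i] <= Tmin + tol) batch.push_back(i);

    const double dt_step = Tmin - tau;
    if (grad) {
      // change of the event-time gradient, from the first batch member
      // (ties share it up to the tolerance):
      //   dT* - dtau = (-dz_w * s - rem * dsl_w) / s^2
      const int w0 = batch[0];
      const double s = slope[w0], rem = 1.0 - z[w0];
      const double* dzw = &dz[(size_t)w0 * np];
      for (int p = 0; p < np; ++p) dstep[p] = -dzw[p] / s;
      dstep[w0] -= rem * dsl_c[w0] / (s * s);
      for (int k = 0; k < 4; ++k)
        dstep[n + k] -= rem * dsl_q[4 * (size_t)w0 + k] / (s * s);
      // advance survivor gradients, then the time gradient
      for (int j = 0; j < n; ++j) {
        if (seized[j]) continue;
        double* dzj = &dz[(size_t)j * np];
        const double sj = slope[j];
        for (int p = 0; p < np; ++p) dzj[p] += sj * dstep[p];
        dzj[j] += dsl_c[j] * dt_step;
        for (int k = 0; k < 4; ++k)
          dzj[n + k] += dsl_q[4 * (size_t)j + k] * dt_step;
      }
      for (int p = 0; p < np; ++p) dtau[p] += dstep[p];
    }
    // advance survivors to the event time
    for (int j = 0; j < n; ++j)
      if (!seized[j]) z[j] += slope[j] * dt_step;
    tau = Tmin;

    // record the batch and switch it on; the onset-time gradient of a
    // batch member is dtau
    for (int b : batch) {
      res.t[b] = tau;
      seized[b] = 1;
      z[b] = 1.0;
      ++n_seized;
      if (grad)
        std::copy(dtau.begin(), dtau.end(), res.dt.begin() + (size_t)b * np);
    }
    // update inputs and slopes of the survivors
    for (int j = 0; j < n; ++j) {
      if (seized[j]) continue;
      for (int b : batch) y[j] += W(j, b);
      if (y[j] > 1.0 + 1e-9)
        stop("weighted seizing input exceeds 1; connectome not normalized");
      if (y[j] > 1.0) y[j] = 1.0;
      recompute_slope(j);
    }
  }
  return res;
}

static void validate_sim_inputs(const NumericMatrix& W,
                                const NumericVector& q4,
                                const NumericVector& c) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("connectome matrix must be square");
  if ((int)c.size() != n) stop("length(c) must match nrow(W)");
  if (q4.size() != 4) stop("q4 must have 4 elements (qaa, qab, qba, qbb)");
  for (int i = 0; i < n; ++i) {
    if (!R_finite(c[i])) stop("non-finite excitability");
    double rs = 0.0;
    for (int j = 0; j < n; ++j) {
      if (W(i, j) < 0) stop("negative connectome weight");
      rs += W(i, j);
    }
    if (rs > 1.0 + 1e-8)
      stop("max ingoing weight sum exceeds 1; normalize the connectome");
  }
}

// [[Rcpp::export]]
List sim_onsets_cpp(NumericMatrix W, NumericVector q4, NumericVector c,
                    double t_max, bool want_grad) {
  validate_sim_inputs(W, q4, c);
  SimResult r = simulate_core(W, &q4[0], c, t_max, want_grad);
  const int n = W.nrow(), np = n + 4;
  NumericVector t(n);
  for (int i = 0; i < n; ++i) t[i] = r.t[i];
  if (!want_grad) return List::create(_["t"] = t);
  NumericMatrix dt_dc(n, n), dt_dq(n, 4);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) dt_dc(i, j) = r.dt[(size_t)i * np + j];
    for (int k = 0; k < 4; ++k) dt_dq(i, k) = r.dt[(size_t)i * np + n + k];
  }
  return List::create(_["t"] = t, _["dt_dc"] = dt_dc, _["dt_dq"] = dt_dq);
}

// Simulate onset times for many excitability draws (no gradients).
// cdraws: draws x n matrix.  Returns draws x n matrix of onset times.
// [[Rcpp::export]]
NumericMatrix sim_onsets_many_cpp(NumericMatrix W, NumericVector q4,
                                  NumericMatrix cdraws, double t_max) {
  const int n = W.nrow(), S = cdraws.nrow();
  if (cdraws.ncol() != n) stop("cdraws must have n columns");
  NumericMatrix out(S, n);
  NumericVector c(n);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) c[i] = cdraws(s, i);
    if (s == 0) validate_sim_inputs(W, q4, c);
    SimResult r = simulate_core(W, &q4[0], c, t_max, false);
    for (int i = 0; i < n; ++i) out(s, i) = r.t[i];
  }
  return out;
}

static const double LOG_2PI = 1.8378770664093454836;

// Single-seizure log posterior over c with fixed q (Box-2 form):
//   log N(c | 0, I)
//   + sum_{i seizing}     log N(tobs_i | min(t_i, t_lim), sigma_t)
//   + sum_{i non-seizing} log N(t_lim  | min(t_i, t_lim), sigma_t)
// status: 0 hidden, 1 seizing, 2 non-seizing.  Simulation is run to
// t_lim only: any later onset enters the density as t_lim exactly and
// contributes zero gradient.
struct LpResult {
  double lp;
  std::vector<double> gc;  // d lp / d c
  std::vector<double> gq;  // d lp / d q4 (data terms only)
};

static LpResult lp_single_core(const NumericMatrix& W, const double* q4,
                               const NumericVector& c,
                               const IntegerVector& status,
                               const NumericVector& tobs, double sigma_t,
                               double t_lim, bool grad, bool with_prior_c) {
  const int n = W.nrow(), np = n + 4;
  SimResult sim = simulate_core(W, q4, c, t_lim, grad);
  LpResult r;
  r.lp = 0.0;
  r.gc.assign(n, 0.0);
  r.gq.assign(4, 0.0);
  if (with_prior_c) {
    for (int i = 0; i < n; ++i) {
      r.lp += -0.5 * c[i] * c[i] - 0.5 * LOG_2PI;
      if (grad) r.gc[i] = -c[i];
    }
  }
  const double s2 = sigma_t * sigma_t;
  for (int i = 0; i < n; ++i) {
    if (status[i] == 0) continue;  // hidden: no likelihood term
    const double target = (status[i] == 1) ? tobs[i] : t_lim;
    const bool capped = !(sim.t[i] < t_lim);
    const double m = capped ? t_lim : sim.t[i];
    const double resid = target - m;
    r.lp += -0.5 * resid * resid / s2 - std::log(sigma_t) - 0.5 * LOG_2PI;
    if (grad && !capped) {
      const double coef = resid / s2;  // d lp / d m
      for (int j = 0; j < n; ++j)
        r.gc[j] += coef * sim.dt[(size_t)i * np + j];
      for (int k = 0; k < 4; ++k)
        r.gq[k] += coef * sim.dt[(size_t)i * np + n + k];
    }
  }
  return r;
}

// [[Rcpp::export]]
List lp_single_cpp(NumericMatrix W, NumericVector q4, NumericVector c,
                   IntegerVector status, NumericVector tobs, double sigma_t,
                   double t_lim, bool want_grad) {
  validate_sim_inputs(W, q4, c);
  LpResult r = lp_single_core(W, &q4[0], c, status, tobs, sigma_t, t_lim,
                              want_grad, true);
  if (!want_grad) return List::create(_["lp"] = r.lp);
  return List::create(_["lp"] = r.lp,
                      _["grad_c"] = NumericVector(r.gc.begin(), r.gc.end()),
                      _["grad_q"] = NumericVector(r.gq.begin(), r.gq.end()));
}

// Hierarchical multi-seizure log posterior on the unconstrained scale.
// theta = (qaa, qab, u_ba, u_bb, c_1, ..., c_K stacked), with
// qba = qaa + exp(u_ba), qbb = qab + exp(u_bb).  Priors (Box-1 form):
//   qaa, qab ~ Normal(0, sigma_q); qba*, qbb* ~ HalfNormal(sigma_q)
// with the log-Jacobian of the log transform added.
// data: list of lists with elements W, status, tobs.
// [[Rcpp::export]]
List lp_multi_cpp(NumericVector theta, List data, double sigma_t,
                  double t_lim, double sigma_q, bool want_grad) {
  const int K = data.size();
  const double qaa = theta[0], qab = theta[1];
  const double u1 = theta[2], u2 = theta[3];
  const double e1 = std::exp(u1), e2 = std::exp(u2);
  double q4[4] = {qaa, qab, qaa + e1, qab + e2};

  const double sq2 = sigma_q * sigma_q;
  double lp = 0.0;
  // Normal(0, sigma_q) on qaa, qab
  lp += -0.5 * qaa * qaa / sq2 - std::log(sigma_q) - 0.5 * LOG_2PI;
  lp += -0.5 * qab * qab / sq2 - std::log(sigma_q) - 0.5 * LOG_2PI;
  // HalfNormal(sigma_q) on exp(u), plus log-Jacobian u
  lp += 0.5 * std::log(2.0 / M_PI) - std::log(sigma_q)
        - 0.5 * e1 * e1 / sq2 + u1;
  lp += 0.5 * std::log(2.0 / M_PI) - std::log(sigma_q)
        - 0.5 * e2 * e2 / sq2 + u2;

  NumericVector grad;
  if (want_grad) {
    grad = NumericVector(theta.size());
    grad[0] = -qaa / sq2;
    grad[1] = -qab / sq2;
    grad[2] = -e1 * e1 / sq2 + 1.0;
    grad[3] = -e2 * e2 / sq2 + 1.0;
  }

  int off = 4;
  double gq_tot[4] = {0, 0, 0, 0};
  for (int k = 0; k < K; ++k) {
    List dk = data[k];
    NumericMatrix W = dk["W"];
    IntegerVector status = dk["status"];
    NumericVector tobs = dk["tobs"];
    const int n = W.nrow();
    NumericVector ck(n);
    for (int i = 0; i < n; ++i) ck[i] = theta[off + i];
    validate_sim_inputs(W, NumericVector::create(q4[0], q4[1], q4[2], q4[3]),
                        ck);
    LpResult r = lp_single_core(W, q4, ck, status, tobs, sigma_t, t_lim,
                                want_grad, true);
    lp += r.lp;
    if (want_grad) {
      for (int i = 0; i < n; ++i) grad[off + i] = r.gc[i];
      for (int j = 0; j < 4; ++j) gq_tot[j] += r.gq[j];
    }
    off += n;
  }
  if (want_grad) {
    // chain rule: qba = qaa + exp(u1), qbb = qab + exp(u2)
    grad[0] += gq_tot[0] + gq_tot[2];
    grad[1] += gq_tot[1] + gq_tot[3];
    grad[2] += gq_tot[2] * e1;
    grad[3] += gq_tot[3] * e2;
  }
  if (!want_grad) return List::create(_["lp"] = lp);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}
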