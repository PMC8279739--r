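#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Canonical parameter layout (see R/params.R):
//  0 c_mf | 1 f_mf | 2..7 c_mb (S1,S2,PI1,PI2,RI1,RI2) | 8 f_mb | 9 pr
// 10 f_p | 11 c_cross_12 (reward 1 -> outcome 2) | 12 c_cross_21
// The retrospective-inference update always uses the cross form; with both
// cross gains at 0 it reduces to the plain per-outcome update, so the same
// code serves the full model and the cross-credit extension.

namespace {

constexpr int NP = 13;
constexpr int I_CMF = 0, I_FMF = 1, I_MB0 = 2, I_FMB = 8, I_PR = 9,
              I_FP = 10, I_CR12 = 11, I_CR21 = 12;

struct State {
  double qmf[4], qmb[4], pers[4];
  double dqmf[4][NP], dqmb[4][NP], dpers[4][NP];

  void reset(bool grad) {
    for (int p = 0; p < 4; ++p) qmf[p] = qmb[p] = pers[p] = 0.0;
    if (grad)
      for (int p = 0; p < 4; ++p)
        for (int k = 0; k < NP; ++k)
          dqmf[p][k] = dqmb[p][k] = dpers[p][k] = 0.0;
  }
};

// One learning update. chosen, o1, o2 are 0-based; o1/o2 in temporal order;
// r1/r2 signed (+1 reward, -1 non-reward); fmt 0=S, 1=PI, 2=RI.
inline void update(State& s, const double* th, int chosen, int fmt,
                   int o1, int o2, double r1, double r2, bool grad) {
  const double fmf = th[I_FMF], fmb = th[I_FMB], fp = th[I_FP];
  const double rt = r1 + r2;

  for (int p = 0; p < 4; ++p) {
    const double old = s.qmf[p];
    if (grad) {
      for (int k = 0; k < NP; ++k) s.dqmf[p][k] *= (1.0 - fmf);
      s.dqmf[p][I_FMF] -= old;
    }
    s.qmf[p] = (1.0 - fmf) * old;
  }
  s.qmf[chosen] += th[I_CMF] * rt;
  if (grad) s.dqmf[chosen][I_CMF] += rt;

  for (int o = 0; o < 4; ++o) {
    const double old = s.qmb[o];
    if (grad) {
      for (int k = 0; k < NP; ++k) s.dqmb[o][k] *= (1.0 - fmb);
      s.dqmb[o][I_FMB] -= old;
    }
    s.qmb[o] = (1.0 - fmb) * old;
  }
  if (fmt == 2) {
    s.qmb[o1] += th[I_MB0 + 4] * r1 + th[I_CR21] * r2;
    s.qmb[o2] += th[I_MB0 + 5] * r2 + th[I_CR12] * r1;
    if (grad) {
      s.dqmb[o1][I_MB0 + 4] += r1;
      s.dqmb[o1][I_CR21] += r2;
      s.dqmb[o2][I_MB0 + 5] += r2;
      s.dqmb[o2][I_CR12] += r1;
    }
  } else {
    const int g1 = I_MB0 + 2 * fmt, g2 = g1 + 1;
    s.qmb[o1] += th[g1] * r1;
    s.qmb[o2] += th[g2] * r2;
    if (grad) {
      s.dqmb[o1][g1] += r1;
      s.dqmb[o2][g2] += r2;
    }
  }

  for (int p = 0; p < 4; ++p) {
    const double old = s.pers[p];
    if (grad) {
      for (int k = 0; k < NP; ++k) s.dpers[p][k] *= (1.0 - fp);
      s.dpers[p][I_FP] -= old;
    }
    s.pers[p] = (1.0 - fp) * old;
  }
  s.pers[chosen] += th[I_PR];
  if (grad) s.dpers[chosen][I_PR] += 1.0;
}

inline double qnet(const State& s, const int* pref0, int p) {
  return s.qmf[p] + s.qmb[pref0[p]] + s.qmb[pref0[p + 4]] + s.pers[p];
}

inline void dqnet(const State& s, const int* pref0, int p, double* out) {
  const int oa = pref0[p], ov = pref0[p + 4];
  for (int k = 0; k < NP; ++k)
    out[k] = s.dqmf[p][k] + s.dqmb[oa][k] + s.dqmb[ov][k] + s.dpers[p][k];
}

inline void to_pref0(const IntegerMatrix& pref, int* pref0) {
  for (int p = 0; p < 4; ++p) {
    pref0[p] = pref(p, 0) - 1;
    pref0[p + 4] = pref(p, 1) - 1;
  }
}

struct TrialData {
  const int *block, *left, *right, *chosen, *fmt, *o1, *o2;
  const double *r1, *r2;
  int n;
  int pref0[8];
};

// session log-likelihood on raw arrays; writes the 13-gradient to gout
double ll_core(const double* th, const TrialData& d, bool grad,
               double* gout) {
  State s;
  double ll = 0.0;
  double dl[NP], dr[NP];
  if (grad) for (int k = 0; k < NP; ++k) gout[k] = 0.0;
  int last_block = -1;

  for (int t = 0; t < d.n; ++t) {
    if (d.block[t] != last_block) {
      s.reset(grad);
      last_block = d.block[t];
    }
    const int c1 = d.chosen[t];
    if (c1 == 0) continue;
    const int l = d.left[t] - 1, r = d.right[t] - 1, c = c1 - 1;
    const double ql = qnet(s, d.pref0, l), qr = qnet(s, d.pref0, r);
    const double m = ql > qr ? ql : qr;
    const double el = std::exp(ql - m), er = std::exp(qr - m);
    const double pl = el / (el + er), pr = er / (el + er);
    ll += (c == l ? ql : qr) - (m + std::log(el + er));
    if (grad) {
      dqnet(s, d.pref0, l, dl);
      dqnet(s, d.pref0, r, dr);
      const double* dc = (c == l) ? dl : dr;
      for (int k = 0; k < NP; ++k)
        gout[k] += dc[k] - (pl * dl[k] + pr * dr[k]);
    }
    update(s, th, c, d.fmt[t] - 1, d.o1[t] - 1, d.o2[t] - 1, d.r1[t],
           d.r2[t], grad);
  }
  return ll;
}

}  // namespace

// Session log-likelihood under the hybrid model, with optional analytic
// gradient. Ids are 1-based; chosen == 0 marks a missing response (the trial
// contributes no likelihood and triggers no update). r1/r2 are signed.
// [[Rcpp::export]]
List cm_loglik_cpp(NumericVector theta, IntegerVector block, IntegerVector left,
                   IntegerVector right, IntegerVector chosen, IntegerVector fmt,
                   IntegerVector o1, IntegerVector o2, NumericVector r1,
                   NumericVector r2, IntegerMatrix pref, bool grad) {
  if (theta.size() != NP) stop("theta must have length %d", NP);
  TrialData d{block.begin(), left.begin(),   right.begin(),
              chosen.begin(), fmt.begin(),   o1.begin(),
              o2.begin(),     r1.begin(),    r2.begin(),
              (int)block.size()};
  to_pref0(pref, d.pref0);
  NumericVector g(NP);
  const double ll = ll_core(theta.begin(), d, grad, g.begin());
  return List::create(_["loglik"] = ll, _["gradient"] = g);
}

namespace {

// objective environment for the box-constrained quasi-Newton fits: free
// parameters map linearly onto the 13 canonical ones (theta = J x), so the
// free-parameter gradient is J^T g. fn caches the gradient for gr.
struct FitEnv {
  TrialData d;
  const double* jac;  // NP x k, column-major
  int k;
  std::vector<double> theta, g13, gfree, last_x;
  bool have_grad = false;

  void expand(const double* x) {
    for (int i = 0; i < NP; ++i) theta[i] = 0.0;
    for (int j = 0; j < k; ++j) {
      const double xj = x[j];
      const double* col = jac + (size_t)NP * j;
      for (int i = 0; i < NP; ++i) theta[i] += col[i] * xj;
    }
  }
};

double fit_fn(int n, double* x, void* ex) {
  FitEnv* e = static_cast<FitEnv*>(ex);
  e->expand(x);
  const double ll = ll_core(e->theta.data(), e->d, true, e->g13.data());
  for (int j = 0; j < n; ++j) {
    const double* col = e->jac + (size_t)NP * j;
    double s = 0.0;
    for (int i = 0; i < NP; ++i) s += col[i] * e->g13[i];
    e->gfree[j] = -s;
  }
  std::memcpy(e->last_x.data(), x, n * sizeof(double));
  e->have_grad = true;
  return -ll;
}

void fit_gr(int n, double* x, double* g, void* ex) {
  FitEnv* e = static_cast<FitEnv*>(ex);
  if (!e->have_grad ||
      std::memcmp(e->last_x.data(), x, n * sizeof(double)) != 0)
    (void)fit_fn(n, x, ex);
  std::memcpy(g, e->gfree.data(), n * sizeof(double));
}

}  // namespace

// Multi-start bounded maximum-likelihood fit. starts is n_starts x k (free
// parameters); jac is the constant NP x k Jacobian of the model
// specification's free-to-full expansion.
// Returns the best free vector (first-found ties within reltol), per-start
// log-likelihoods, and convergence codes (0 ok, 1 maxit, 51/52 warnings).
// [[Rcpp::export]]
List cm_fit_cpp(NumericMatrix starts, NumericVector lower,
                NumericVector upper, NumericMatrix jac, IntegerVector block,
                IntegerVector left, IntegerVector right,
                IntegerVector chosen, IntegerVector fmt, IntegerVector o1,
                IntegerVector o2, NumericVector r1, NumericVector r2,
                IntegerMatrix pref, int maxit, double factr, double reltol) {
  const int k = starts.ncol(), ns = starts.nrow();
  if (jac.nrow() != NP || jac.ncol() != k)
    stop("jac must be %d x k", NP);
  FitEnv env;
  env.d = TrialData{block.begin(), left.begin(), right.begin(),
                    chosen.begin(), fmt.begin(), o1.begin(), o2.begin(),
                    r1.begin(),     r2.begin(),  (int)block.size()};
  to_pref0(pref, env.d.pref0);
  env.jac = jac.begin();
  env.k = k;
  env.theta.resize(NP);
  env.g13.resize(NP);
  env.gfree.resize(k);
  env.last_x.resize(k);

  std::vector<double> x(k), best_x(k);
  std::vector<int> nbd(k, 2);  // both bounds active everywhere
  NumericVector lls(ns);
  IntegerVector convs(ns);
  double best_ll = R_NegInf;
  char msg[256];

  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < k; ++j) x[j] = starts(s, j);
    double fmin = 0.0;
    int fail = 0, fncount = 0, grcount = 0;
    env.have_grad = false;
    lbfgsb(k, 5, x.data(), const_cast<double*>(lower.begin()),
           const_cast<double*>(upper.begin()), nbd.data(), &fmin, fit_fn,
           fit_gr, &fail, &env, factr, 0.0, &fncount, &grcount, maxit, msg,
           0, 10);
    lls[s] = -fmin;
    convs[s] = fail;
    if (lls[s] > best_ll + reltol) {
      best_ll = lls[s];
      best_x = x;
    }
  }
  return List::create(_["free"] = NumericVector(best_x.begin(), best_x.end()),
                      _["loglik"] = best_ll, _["start_logliks"] = lls,
                      _["convergence"] = convs);
}

// Forward-simulate choices and rewards on a session plan. animal_first gives
// the planned temporal outcome order; rewp is the blocks x 4 outcome
// reward-probability matrix. Uses R's RNG (choice, reward 1, reward 2 per
// trial, in that order).
// [[Rcpp::export]]
List cm_simulate_cpp(NumericVector theta, IntegerVector block,
                     IntegerVector left, IntegerVector right, IntegerVector fmt,
                     LogicalVector animal_first, IntegerMatrix pref,
                     NumericMatrix rewp) {
  if (theta.size() != NP) stop("theta must have length %d", NP);
  const int n = block.size();
  const double* th = theta.begin();
  int pref0[8];
  to_pref0(pref, pref0);

  IntegerVector chosen(n), out1(n), out2(n), rew1(n), rew2(n);
  State s;
  int last_block = -1;

  for (int t = 0; t < n; ++t) {
    if (block[t] != last_block) {
      s.reset(false);
      last_block = block[t];
    }
    const int l = left[t] - 1, r = right[t] - 1;
    const double ql = qnet(s, pref0, l), qr = qnet(s, pref0, r);
    const double pl = 1.0 / (1.0 + std::exp(qr - ql));
    const int c = (unif_rand() < pl) ? l : r;
    const int oa = pref0[c], ov = pref0[c + 4];
    const int a = animal_first[t] ? oa : ov, b = animal_first[t] ? ov : oa;
    const int w1 = (unif_rand() < rewp(block[t] - 1, a)) ? 1 : 0;
    const int w2 = (unif_rand() < rewp(block[t] - 1, b)) ? 1 : 0;
    chosen[t] = c + 1;
    out1[t] = a + 1;
    out2[t] = b + 1;
    rew1[t] = w1;
    rew2[t] = w2;
    update(s, th, c, fmt[t] - 1, a, b, 2.0 * w1 - 1.0, 2.0 * w2 - 1.0, false);
  }
  return List::create(_["chosen"] = chosen, _["outcome1"] = out1,
                      _["outcome2"] = out2, _["reward1"] = rew1,
                      _["reward2"] = rew2);
}
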