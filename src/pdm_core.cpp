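#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Model codes shared with the R side (see model_code() in R/agents.R):
// 1 = base, 2 = fixed, 3 = value, 4 = world, 5 = hybrid.

struct Pars {
  double mu0, sm, ss, s0, smp, sdiff, alpha, beta, vinit;
};

static Pars parse_pars(int model, const NumericVector &par) {
  Pars p = {0, 1, 1, 1, 0, 0, 0, 0, 1};
  switch (model) {
  case 1: // base: sigma_m
    p.sm = par[0];
    break;
  case 2: // fixed: mu0, sigma_m
    p.mu0 = par[0]; p.sm = par[1];
    break;
  case 3: // value: mu0, sigma_m, alpha, beta, v_init
    p.mu0 = par[0]; p.sm = par[1]; p.alpha = par[2]; p.beta = par[3];
    p.vinit = par[4];
    break;
  case 4: // world: mu0, sigma_m, sigma_s, sigma_0, sigma_mprime, sigma_diffusion
    p.mu0 = par[0]; p.sm = par[1]; p.ss = par[2]; p.s0 = par[3];
    p.smp = par[4]; p.sdiff = par[5];
    break;
  case 5: // hybrid: world parameters then alpha, beta, v_init
    p.mu0 = par[0]; p.sm = par[1]; p.ss = par[2]; p.s0 = par[3];
    p.smp = par[4]; p.sdiff = par[5]; p.alpha = par[6]; p.beta = par[7];
    p.vinit = par[8];
    break;
  default:
    stop("unknown model code");
  }
  return p;
}

// Posterior over the class boundary after one episode, summarized by its
// grid mean and variance.  The posterior is
//   p(b | m', CL) ~ N(b; pm, pv) * N(m'; b, sM2 + sS2) * Phi(+/- kappa (b - m'))
// with kappa = sqrt(sS2 / (sM2 * (sM2 + sS2))); the CDF factor carries the
// feedback-informed class state (small: +, large: -).  The two Gaussian
// factors are combined analytically and the grid spans their product
// +/- gridw posterior SDs, which contains all posterior mass because the CDF
// factor is bounded by 1.
static bool bmbu_posterior(double pm, double pv, double mprime, int cl_large,
                           double sM2, double sS2, int ngrid, double gridw,
                           double &postm, double &postv) {
  if (pv <= 0) { postm = pm; postv = 0.0; return true; }
  double s2 = sM2 + sS2;
  double C = 1.0 / (1.0 / pv + 1.0 / s2);
  double c = C * (pm / pv + mprime / s2);
  double kappa = std::sqrt(sS2 / (sM2 * s2));
  double sgn = cl_large ? -1.0 : 1.0;
  double sd = std::sqrt(C);
  double lo = c - gridw * sd;
  double h = (2.0 * gridw * sd) / (ngrid - 1);
  // single pass accumulating moments of (b - c); the offset keeps the
  // second moment numerically clean
  double s0w = 0, s1w = 0, s2w = 0;
  for (int i = 0; i < ngrid; ++i) {
    double bc = lo + h * i - c;
    double z = bc / sd;
    double d = 0.5 * std::erfc(-(sgn * kappa * (bc + c - mprime)) * M_SQRT1_2) *
               std::exp(-0.5 * z * z);
    double w = (i == 0 || i == ngrid - 1) ? 0.5 : 1.0;
    s0w += w * d;
    s1w += w * d * bc;
    s2w += w * d * bc * bc;
  }
  if (!(s0w > 0) || !std::isfinite(s0w)) {
    // extreme truncation (very large kappa): redo in log space
    std::vector<double> ld(ngrid);
    double mx = -INFINITY;
    for (int i = 0; i < ngrid; ++i) {
      double bc = lo + h * i - c;
      double z = bc / sd;
      ld[i] = R::pnorm(sgn * kappa * (bc + c - mprime), 0.0, 1.0, 1, 1) -
              0.5 * z * z;
      if (ld[i] > mx) mx = ld[i];
    }
    if (!std::isfinite(mx)) return false;
    s0w = s1w = s2w = 0;
    for (int i = 0; i < ngrid; ++i) {
      double bc = lo + h * i - c;
      double d = std::exp(ld[i] - mx);
      double w = (i == 0 || i == ngrid - 1) ? 0.5 : 1.0;
      s0w += w * d;
      s1w += w * d * bc;
      s2w += w * d * bc * bc;
    }
    if (!(s0w > 0)) return false;
  }
  double m1 = s1w / s0w;
  postm = c + m1;
  postv = s2w / s0w - m1 * m1;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_bmbu_posterior(double prior_mean, double prior_var,
                                 double m_prime, int cl_large, double sigma_M2,
                                 double sigma_S2, int ngrid, double gridw) {
  double pm = NA_REAL, pv = NA_REAL;
  bool ok = bmbu_posterior(prior_mean, prior_var, m_prime, cl_large, sigma_M2,
                           sigma_S2, ngrid, gridw, pm, pv);
  if (!ok) stop("boundary posterior has numerically zero mass on the grid");
  return NumericVector::create(pm, pv);
}

static inline double plogis_safe(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// One agent state, reset at each run start.
struct AgentState {
  double vS, vL, bm, bv;
  void reset(const Pars &p, int model) {
    vS = vL = p.vinit;
    bm = p.mu0;
    bv = p.s0 * p.s0;
    if (model <= 3) { bm = (model == 1) ? 0.0 : p.mu0; bv = 0.0; }
  }
};

static inline double decision_boundary(int model, const Pars &p,
                                       const AgentState &st) {
  if (model == 1) return 0.0;
  if (model == 4 || model == 5) return st.bm;
  return p.mu0;
}

// Probability of choosing "large" given measurement m (before lapse).
static inline double p_large_given_m(int model, const Pars &p,
                                     const AgentState &st, double m,
                                     double &pl_out) {
  double b = decision_boundary(model, p, st);
  double pl = R::pnorm((m - b) / p.sm, 0.0, 1.0, 1, 0);
  pl_out = pl;
  if (model == 3 || model == 5) {
    double qL = pl * st.vL, qS = (1.0 - pl) * st.vS;
    return plogis_safe(p.beta * (qL - qS));
  }
  if (pl > 0.5) return 1.0;
  if (pl < 0.5) return 0.0;
  return 0.5;
}

// Latent updates driven by the episode (m_acc, choice, feedback).  Draws the
// mnemonic measurement internally for the boundary-updating models.
static inline void update_state(int model, const Pars &p, AgentState &st,
                                double m_acc, int choice, int feedback,
                                int ngrid, double gridw, double &mprime_out) {
  mprime_out = NA_REAL;
  if (model == 3 || model == 5) {
    double b = (model == 5) ? st.bm : p.mu0;
    double pl = R::pnorm((m_acc - b) / p.sm, 0.0, 1.0, 1, 0);
    double pC = choice ? pl : (1.0 - pl);
    double r = feedback ? 1.0 : 0.0;
    if (choice) st.vL += p.alpha * (r - pC * st.vL);
    else        st.vS += p.alpha * (r - pC * st.vS);
  }
  if (model == 4 || model == 5) {
    double mprime = (p.smp > 0) ? R::rnorm(m_acc, p.smp) : m_acc;
    mprime_out = mprime;
    int cl_large = (choice == feedback) ? 1 : 0;
    double sM2 = p.smp * p.smp + p.sm * p.sm;
    double sS2 = p.ss * p.ss;
    double postm, postv;
    if (!bmbu_posterior(st.bm, st.bv, mprime, cl_large, sM2, sS2, ngrid,
                        gridw, postm, postv))
      stop("boundary posterior lost all mass during simulation");
    double s02 = p.s0 * p.s0;
    double lambda = s02 / (s02 + postv);
    st.bm = lambda * postm + (1.0 - lambda) * p.mu0;
    st.bv = lambda * postv + p.sdiff * p.sdiff;
  }
}

// Forward simulation of one agent across runs.  `criterion` holds the
// pre-drawn virtual criterion for each trial; feedback is correct iff the
// choice matches the true class sign(stimulus - criterion).
// [[Rcpp::export]]
List cpp_simulate(int model, NumericVector par, IntegerVector stim,
                  IntegerVector run, NumericVector criterion,
                  double lapse_rate, int ngrid, double gridw) {
  int n = stim.size();
  Pars p = parse_pars(model, par);
  AgentState st;
  IntegerVector choice(n), feedback(n), lapse(n);
  NumericVector m(n), pl(n), mprime(n), bmean(n), bvar(n), vS(n), vL(n);
  int cur_run = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || run[t] != cur_run) { st.reset(p, model); cur_run = run[t]; }
    bmean[t] = (model >= 4) ? st.bm : NA_REAL;
    bvar[t] = (model >= 4) ? st.bv : NA_REAL;
    vS[t] = (model == 3 || model == 5) ? st.vS : NA_REAL;
    vL[t] = (model == 3 || model == 5) ? st.vL : NA_REAL;
    double mt = R::rnorm((double)stim[t], p.sm);
    m[t] = mt;
    double plt;
    double pLarge = p_large_given_m(model, p, st, mt, plt);
    pl[t] = plt;
    int ch = (unif_rand() < pLarge) ? 1 : 0;
    int lp = 0;
    if (lapse_rate > 0 && unif_rand() < lapse_rate) {
      lp = 1;
      ch = (unif_rand() < 0.5) ? 1 : 0;
    }
    int truth = ((double)stim[t] > criterion[t]) ? 1 : 0;
    int fb = (ch == truth) ? 1 : 0;
    choice[t] = ch; feedback[t] = fb; lapse[t] = lp;
    double mp;
    update_state(model, p, st, mt, ch, fb, ngrid, gridw, mp);
    mprime[t] = mp;
  }
  return List::create(_["choice"] = choice, _["feedback"] = feedback,
                      _["lapse"] = lapse, _["m"] = m, _["p_l"] = pl,
                      _["m_prime"] = mprime, _["b_mean"] = bmean,
                      _["b_var"] = bvar, _["v_small"] = vS, _["v_large"] = vL);
}

// Inverse binomial sampling estimate of the log likelihood of observed
// choices.  Latent state trajectories are conditioned on the observed
// choices and feedback; the accepted (matching) draw's measurement feeds the
// mnemonic/update step.  Trials flagged as lapse trials emit a fair coin.
// [[Rcpp::export]]
List cpp_ibs(int model, NumericVector par, IntegerVector stim,
             IntegerVector choice, IntegerVector feedback, IntegerVector run,
             LogicalVector lapse, int max_draws, int ngrid, double gridw) {
  int n = stim.size();
  Pars p = parse_pars(model, par);
  AgentState st;
  double ll = 0.0;
  int n_capped = 0;
  int cur_run = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || run[t] != cur_run) { st.reset(p, model); cur_run = run[t]; }
    int K = 0;
    double m_acc = NA_REAL;
    bool matched = false;
    while (K < max_draws) {
      ++K;
      double mt = R::rnorm((double)stim[t], p.sm);
      int ch;
      if (lapse[t]) {
        ch = (unif_rand() < 0.5) ? 1 : 0;
      } else {
        double plt;
        double pLarge = p_large_given_m(model, p, st, mt, plt);
        if (pLarge >= 1.0) ch = 1;
        else if (pLarge <= 0.0) ch = 0;
        else ch = (unif_rand() < pLarge) ? 1 : 0;
      }
      m_acc = mt;
      if (ch == choice[t]) { matched = true; break; }
    }
    for (int j = 1; j <= K - 1; ++j) ll -= 1.0 / j;
    if (!matched) ++n_capped;
    double mp;
    update_state(model, p, st, m_acc, choice[t], feedback[t], ngrid, gridw, mp);
  }
  return List::create(_["ll"] = ll, _["n_capped"] = n_capped);
}
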