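// Dynamic-programming solvers on count lattices.
//
// States are success/failure counts (sufficient statistics), so a depth-H
// lookahead visits C(H+4,4) count states instead of 4^H reward histories.
// Backward induction keeps only two adjacent lattice levels in memory.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// number of states (i1,j1,i2,j3) >= 0 with i1+j1+i2+j3 == n
static inline size_t level_size(int n) {
  return (size_t)(n + 1) * (n + 2) * (n + 3) / 6;
}

// Cached lgamma tables for integer offsets from the prior hyperparameters.
struct BetaTables {
  std::vector<double> A1, B1, AB1, A2, B2, AB2, A0, B0, AB0;
  double lb11, lb22, lb00; // lbeta at zero counts
  double ga0b0, ga1b1, ga2b2, a1, a2, a0, b0, b1, b2;

  void init(double a1_, double b1_, double a2_, double b2_,
            double a0_, double b0_, int K) {
    a1 = a1_; b1 = b1_; a2 = a2_; b2 = b2_; a0 = a0_; b0 = b0_;
    A1.resize(K + 1); B1.resize(K + 1); AB1.resize(2 * K + 1);
    A2.resize(K + 1); B2.resize(K + 1); AB2.resize(2 * K + 1);
    A0.resize(K + 1); B0.resize(K + 1); AB0.resize(2 * K + 1);
    for (int x = 0; x <= K; ++x) {
      A1[x] = R::lgammafn(a1 + x); B1[x] = R::lgammafn(b1 + x);
      A2[x] = R::lgammafn(a2 + x); B2[x] = R::lgammafn(b2 + x);
      A0[x] = R::lgammafn(a0 + x); B0[x] = R::lgammafn(b0 + x);
    }
    for (int x = 0; x <= 2 * K; ++x) {
      AB1[x] = R::lgammafn(a1 + b1 + x);
      AB2[x] = R::lgammafn(a2 + b2 + x);
      AB0[x] = R::lgammafn(a0 + b0 + x);
    }
    lb11 = A1[0] + B1[0] - AB1[0];
    lb22 = A2[0] + B2[0] - AB2[0];
    lb00 = A0[0] + B0[0] - AB0[0];
    ga0b0 = a0 + b0; ga1b1 = a1 + b1; ga2b2 = a2 + b2;
  }

  // posterior log odds of coupling at absolute counts, given prior log odds
  inline double coupling_logit(int s1, int f1, int s2, int f2,
                               double lko) const {
    int n = s1 + f1 + s2 + f2;
    return lko
      + (A0[s1 + f2] + B0[f1 + s2] - AB0[n]) - lb00
      - ((A1[s1] + B1[f1] - AB1[s1 + f1]) - lb11)
      - ((A2[s2] + B2[f2] - AB2[s2 + f2]) - lb22);
  }

  // predictive reward probabilities for both options
  inline void predictive(int s1, int f1, int s2, int f2, double lko,
                         double &p1, double &p2) const {
    int n = s1 + f1 + s2 + f2;
    double pc;
    if (lko == R_PosInf) pc = 1.0;
    else if (lko == R_NegInf) pc = 0.0;
    else {
      double z = coupling_logit(s1, f1, s2, f2, lko);
      pc = 1.0 / (1.0 + std::exp(-z));
    }
    double mc1 = (a0 + s1 + f2) / (ga0b0 + n);
    double mi1 = (a1 + s1) / (ga1b1 + s1 + f1);
    double mc2 = (b0 + f1 + s2) / (ga0b0 + n);
    double mi2 = (a2 + s2) / (ga2b2 + s2 + f2);
    p1 = pc * mc1 + (1.0 - pc) * mi1;
    p2 = pc * mc2 + (1.0 - pc) * mi2;
  }
};

// Backward induction over the count lattice rooted at (rs1,rf1,rs2,rf2),
// depth H. Bellman: V = max_a p_a (1 + g V_succ) + (1-p_a) g V_fail.
// If record >= 0, Q-values for all lattice states with increment level
// <= record are appended to rec (columns s1,f1,s2,f2,q1,q2).
static void struct_dp(const BetaTables &bt, int rs1, int rf1, int rs2, int rf2,
                      double lko, double gamma, int H,
                      double &q1_root, double &q2_root,
                      int record, std::vector<double> *rec) {
  std::vector<double> Vnext(level_size(H), 0.0), Vcur;
  std::vector<size_t> cum1;
  for (int n = H - 1; n >= 0; --n) {
    Vcur.assign(level_size(n), 0.0);
    int n1 = n + 1; // child level
    cum1.assign(n1 + 2, 0);
    for (int x = 0; x <= n1; ++x) {
      int m = n1 - x; // remaining budget for (j1,i2)
      cum1[x + 1] = cum1[x] + (size_t)(m + 1) * (m + 2) / 2;
    }
    size_t r = 0;
    for (int i1 = 0; i1 <= n; ++i1) {
      for (int j1 = 0; j1 <= n - i1; ++j1) {
        for (int i2 = 0; i2 <= n - i1 - j1; ++i2, ++r) {
          int j3 = n - i1 - j1 - i2;
          double p1, p2;
          bt.predictive(rs1 + i1, rf1 + j1, rs2 + i2, rf2 + j3, lko, p1, p2);
          // child ranks at level n+1
          // rank(x,y,z) = cum1[x] + y*(n1-x+1) - y*(y-1)/2 + z
          size_t cs1 = cum1[i1 + 1] + (size_t)j1 * (n1 - i1) -
                       (size_t)j1 * (j1 - 1) / 2 + i2;
          size_t base = cum1[i1] + (size_t)j1 * (n1 - i1 + 1) -
                        (size_t)j1 * (j1 - 1) / 2;
          size_t cf1 = cum1[i1] + (size_t)(j1 + 1) * (n1 - i1 + 1) -
                       (size_t)(j1 + 1) * j1 / 2 + i2;
          size_t cs2 = base + i2 + 1;
          size_t cf2 = base + i2; // j3 increment leaves (i1,j1,i2) fixed
          double q1 = p1 * (1.0 + gamma * Vnext[cs1]) +
                      (1.0 - p1) * gamma * Vnext[cf1];
          double q2 = p2 * (1.0 + gamma * Vnext[cs2]) +
                      (1.0 - p2) * gamma * Vnext[cf2];
          Vcur[r] = q1 > q2 ? q1 : q2;
          if (n == 0) { q1_root = q1; q2_root = q2; }
          if (rec && n <= record) {
            rec->push_back(rs1 + i1); rec->push_back(rf1 + j1);
            rec->push_back(rs2 + i2); rec->push_back(rf2 + j3);
            rec->push_back(q1); rec->push_back(q2);
          }
        }
      }
    }
    std::swap(Vnext, Vcur);
  }
}

static double kappa_to_logit(double kappa) {
  if (kappa <= 0.0) return R_NegInf;
  if (kappa >= 1.0) return R_PosInf;
  return std::log(kappa) - std::log1p(-kappa);
}

static void check_capacity(int H, double max_states) {
  double need = (double)(H + 1) * (H + 2) * (H + 3) / 6.0;
  if (need > max_states) {
    stop("horizon %d needs a lattice level of %.3g states, over the "
         "configured budget of %.3g states", H, need, max_states);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_struct_q_batch(IntegerMatrix roots, NumericVector kappa,
                                 double a1, double b1, double a2, double b2,
                                 double a0, double b0, double gamma,
                                 int horizon, double max_states) {
  int n = roots.nrow();
  if (kappa.size() != n && kappa.size() != 1)
    stop("kappa must have length 1 or nrow(roots)");
  check_capacity(horizon, max_states);
  int maxtot = 0;
  for (int i = 0; i < n; ++i) {
    int tot = roots(i, 0) + roots(i, 1) + roots(i, 2) + roots(i, 3);
    if (tot > maxtot) maxtot = tot;
  }
  BetaTables bt;
  bt.init(a1, b1, a2, b2, a0, b0, maxtot + horizon + 2);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double lko = kappa_to_logit(kappa.size() == 1 ? kappa[0] : kappa[i]);
    double q1 = 0, q2 = 0;
    struct_dp(bt, roots(i, 0), roots(i, 1), roots(i, 2), roots(i, 3),
              lko, gamma, horizon, q1, q2, -1, nullptr);
    out(i, 0) = q1; out(i, 1) = q2;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_struct_q_lattice(int rs1, int rf1, int rs2, int rf2,
                                   double kappa, double a1, double b1,
                                   double a2, double b2, double a0, double b0,
                                   double gamma, int total_depth,
                                   int record_depth, double max_states) {
  check_capacity(total_depth, max_states);
  BetaTables bt;
  bt.init(a1, b1, a2, b2, a0, b0, rs1 + rf1 + rs2 + rf2 + total_depth + 2);
  std::vector<double> rec;
  double q1 = 0, q2 = 0;
  struct_dp(bt, rs1, rf1, rs2, rf2, kappa_to_logit(kappa), gamma,
            total_depth, q1, q2, record_depth, &rec);
  size_t nrow = rec.size() / 6;
  NumericMatrix out(nrow, 6);
  for (size_t i = 0; i < nrow; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = rec[6 * i + j];
  colnames(out) = CharacterVector::create("s1", "f1", "s2", "f2", "q1", "q2");
  return out;
}

// value difference (continue - retire) of a single Beta(a,b) arm against a
// deterministic option paying lambda per step, finite horizon H
static double arm_margin(double a, double b, double lambda, double gamma,
                         int H) {
  std::vector<double> Vnext(H + 1, 0.0), Vcur;
  double root_margin = 0.0;
  for (int n = H - 1; n >= 0; --n) {
    int remaining = H - n;
    double retire = lambda * (1.0 - std::pow(gamma, remaining)) / (1.0 - gamma);
    Vcur.assign(n + 1, 0.0);
    for (int i = 0; i <= n; ++i) {
      double p = (a + i) / (a + b + n);
      double cont = p * (1.0 + gamma * Vnext[i + 1]) +
                    (1.0 - p) * gamma * Vnext[i];
      Vcur[i] = cont > retire ? cont : retire;
      if (n == 0) root_margin = cont - retire;
    }
    std::swap(Vnext, Vcur);
  }
  return root_margin;
}

// [[Rcpp::export]]
NumericVector cpp_gittins(NumericVector a, NumericVector b, double gamma,
                          int horizon, double tol) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (a[i] <= 0 || b[i] <= 0) stop("pseudo-counts must be positive");
    double mean = a[i] / (a[i] + b[i]);
    if (gamma == 0.0) { out[i] = mean; continue; }
    double lo = mean, hi = 1.0;
    while (hi - lo > tol) {
      double mid = 0.5 * (lo + hi);
      if (arm_margin(a[i], b[i], mid, gamma, horizon) > 0) lo = mid;
      else hi = mid;
    }
    out[i] = 0.5 * (lo + hi);
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Prediction rate of soft-max Q-learning on a fixed trial log, one rate per
// parameter row (columns q1_init, q2_init, alpha, beta, gamma_q). The modal
// action is scored; exact value ties score 0.5. Q resets at task boundaries.
// [[Rcpp::export]]
NumericVector cpp_q_rates(IntegerVector action, NumericVector reward,
                          IntegerVector task, NumericMatrix params) {
  int nt = action.size(), np = params.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double q1i = params(p, 0), q2i = params(p, 1), alpha = params(p, 2),
           beta = params(p, 3), gq = params(p, 4);
    double q1 = q1i, q2 = q2i, score = 0.0;
    for (int t = 0; t < nt; ++t) {
      if (t == 0 || task[t] != task[t - 1]) { q1 = q1i; q2 = q2i; }
      double d = beta * (q1 - q2);
      if (std::fabs(d) <= 1e-12) score += 0.5;
      else if ((d > 0 && action[t] == 1) || (d < 0 && action[t] == 2))
        score += 1.0;
      double qmax = q1 > q2 ? q1 : q2;
      if (action[t] == 1) q1 += alpha * (reward[t] + gq * qmax - q1);
      else q2 += alpha * (reward[t] + gq * qmax - q2);
    }
    out[p] = score / nt;
  }
  return out;
}
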