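#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

// Exact two-sided Fisher test on a 2xK table, conditioning on both margins.
// All tables with the observed margins are enumerated; a table contributes to
// the p-value when its point probability is <= the observed one (up to a tie
// tolerance on the log scale). Accumulation is in natural-log space via a
// streaming log-sum-exp so that p-values far below double underflow of the
// individual terms remain well defined on the log scale.
//
// Groups of equal size are collapsed into classes: a table's probability
// depends only on the multiset of per-group positive counts within each
// class, so one "configuration" (a count multiset per class) stands for
// multinomial-many raw tables of identical probability. This keeps cut
// levels with many singleton clusters enumerable.

namespace {

struct Entry {
  int t;           // positives allocated to this size class
  double lognum;   // sum over the class's groups of log C(n, k)
  double logmult;  // log number of raw tables sharing this multiset
};

// Enumerate all multisets of per-group counts for one class of m groups of
// size n, recording total positives, log numerator and log multiplicity.
void gen_entries(int n, int m, int j, int rem, int t_acc, double ln_acc,
                 double lm_acc, const std::vector<double> &lch,
                 std::vector<Entry> &out, int t_cap, double max_entries) {
  if (j == n) {
    int t = t_acc + rem * n;
    if (t <= t_cap) {
      out.push_back({t, ln_acc + rem * lch[n],
                     lm_acc - std::lgamma(rem + 1.0)});
      if ((double)out.size() > max_entries)
        stop("enumeration guard exceeded: table has too many configurations "
             "for exact enumeration");
    }
    return;
  }
  for (int c = 0; c <= rem; ++c) {
    int t2 = t_acc + c * j;
    if (t2 > t_cap) break;
    gen_entries(n, m, j + 1, rem - c, t2, ln_acc + c * lch[j],
                lm_acc - std::lgamma(c + 1.0), lch, out, t_cap, max_entries);
  }
}

struct Walker {
  std::vector<std::vector<Entry> > classes;
  std::vector<int> suffix_max;  // max positives placeable in classes ci..end
  double obs_lognum, log_tol, max_configs;
  double n_configs;
  double tailM, tailS;  // log-sum-exp of qualifying (as-or-more-extreme) mass
  double totM, totS;    // log-sum-exp of all mass (normalisation check)

  Walker() : n_configs(0.0), tailM(R_NegInf), tailS(0.0),
             totM(R_NegInf), totS(0.0) {}

  static void lse_add(double &M, double &S, double x) {
    if (x == R_NegInf) return;
    if (x <= M) {
      S += std::exp(x - M);
    } else {
      S = S * std::exp(M - x) + 1.0;
      M = x;
    }
  }

  void dfs(size_t ci, int rem, double lognum, double logmult) {
    if (ci == classes.size()) {
      if (rem != 0) return;
      n_configs += 1.0;
      if (n_configs > max_configs)
        stop("enumeration guard exceeded: more than %g configurations; "
             "table too large for exact enumeration", max_configs);
      lse_add(totM, totS, logmult + lognum);
      if (lognum <= obs_lognum + log_tol)
        lse_add(tailM, tailS, logmult + lognum);
      return;
    }
    int smax = suffix_max[ci + 1];
    const std::vector<Entry> &es = classes[ci];
    for (size_t i = 0; i < es.size(); ++i) {
      int r2 = rem - es[i].t;
      if (r2 < 0 || r2 > smax) continue;
      dfs(ci + 1, r2, lognum + es[i].lognum, logmult + es[i].logmult);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List fisher2xk_enum(IntegerVector group_sizes, IntegerVector positives,
                    double log_tol, double max_configs) {
  int K = group_sizes.size();
  if (K < 1 || positives.size() != K)
    stop("group_sizes and positives must have equal positive length");
  long long N = 0, T = 0;
  double obs_lognum = 0.0;
  std::map<int, int> mult;  // class size -> number of groups
  for (int i = 0; i < K; ++i) {
    int n = group_sizes[i], k = positives[i];
    if (n < 1) stop("group sizes must be >= 1");
    if (k < 0 || k > n) stop("positives must satisfy 0 <= k <= group size");
    N += n;
    T += k;
    obs_lognum += Rf_lchoose((double)n, (double)k);
    mult[n] += 1;
  }

  Walker w;
  w.obs_lognum = obs_lognum;
  w.log_tol = log_tol;
  w.max_configs = max_configs;

  for (std::map<int, int>::const_iterator it = mult.begin(); it != mult.end();
       ++it) {
    int n = it->first, m = it->second;
    std::vector<double> lch(n + 1);
    for (int j = 0; j <= n; ++j)
      lch[j] = Rf_lchoose((double)n, (double)j);
    std::vector<Entry> es;
    int t_cap = (int)std::min((long long)n * m, T);
    gen_entries(n, m, 0, m, 0, 0.0, std::lgamma(m + 1.0), lch, es, t_cap,
                max_configs);
    w.classes.push_back(es);
  }

  size_t C = w.classes.size();
  w.suffix_max.assign(C + 1, 0);
  std::vector<int> caps;
  for (std::map<int, int>::const_iterator it = mult.begin(); it != mult.end();
       ++it)
    caps.push_back(it->first * it->second);
  for (int ci = (int)C - 1; ci >= 0; --ci)
    w.suffix_max[ci] = w.suffix_max[ci + 1] + caps[ci];

  w.dfs(0, (int)T, 0.0, 0.0);

  double log_denom = Rf_lchoose((double)N, (double)T);
  double log_tail = (w.tailS > 0.0) ? w.tailM + std::log(w.tailS) : R_NegInf;
  double log_tot = (w.totS > 0.0) ? w.totM + std::log(w.totS) : R_NegInf;

  return List::create(_["log_num_tail"] = log_tail,
                      _["log_num_total"] = log_tot,
                      _["log_denom"] = log_denom,
                      _["n_configs"] = w.n_configs);
}
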