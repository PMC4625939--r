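// Exact event-by-event simulation of a context-dependent nucleotide
// substitution process along one branch.  CpG context (C->T with next G,
// G->A with previous C) multiplies the affected transition rate, which
// makes the process non-reversible and site-dependent, so substitutions
// are drawn one at a time (Gillespie) with local rate updates after each
// event.  Base codes: 0=A, 1=C, 2=G, 3=T.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline bool is_stop(int b1, int b2, int b3) {
  // TAA, TAG, TGA
  if (b1 != 3) return false;
  if (b2 == 0 && (b3 == 0 || b3 == 2)) return true;
  if (b2 == 2 && b3 == 0) return true;
  return false;
}

// Fenwick tree over per-site total rates: O(log n) sampling and update.
struct Fenwick {
  int n, logn;
  std::vector<double> t;
  void init(int n_) {
    n = n_;
    t.assign(n + 1, 0.0);
    logn = 0;
    while ((1 << (logn + 1)) <= n) ++logn;
  }
  void add(int i, double d) {
    for (++i; i <= n; i += i & -i) t[i] += d;
  }
  double total() const {
    double s = 0;
    for (int i = n; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // largest prefix with cumulative sum <= u; returns 0-based site index
  int search(double u) const {
    int pos = 0;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] <= u) {
        pos += pw;
        u -= t[pos];
      }
    }
    return pos;  // first index whose inclusion exceeds u
  }
};

// per-target rates for one site under the current sequence state
static void site_rates(const std::vector<int>& s, int i,
                       const NumericMatrix& Q, double cpg,
                       const IntegerVector& cpos, bool forbidStop,
                       double out[4]) {
  const int n = (int)s.size();
  const int b = s[i];
  const int cp = cpos[i];
  out[0] = out[1] = out[2] = out[3] = 0.0;
  if (cp == 1 || cp == 2) return;  // frozen codon positions
  for (int to = 0; to < 4; ++to) {
    if (to == b) continue;
    double r = Q(b, to);
    if (r <= 0) continue;
    if (b == 1 && to == 3 && i + 1 < n && s[i + 1] == 2) r *= cpg;  // CpG C->T
    if (b == 2 && to == 0 && i > 0 && s[i - 1] == 1) r *= cpg;      // CpG G->A
    if (forbidStop && cp == 3 && i >= 2 && is_stop(s[i - 2], s[i - 1], to))
      r = 0.0;
    out[to] = r;
  }
}

// [[Rcpp::export]]
List cpp_evolve_branch(IntegerVector seq0, double len, NumericMatrix rates,
                       double cpgMultiplier, IntegerVector codonPos,
                       bool forbidStop) {
  const int n = seq0.size();
  if (n == 0) stop("parameter error: zero-length sequence");
  if (len < 0) stop("parameter error: negative branch length");
  std::vector<int> s(seq0.begin(), seq0.end());
  std::vector<double> tot(n, 0.0);
  Fenwick fw;
  fw.init(n);
  double r4[4];
  for (int i = 0; i < n; ++i) {
    site_rates(s, i, rates, cpgMultiplier, codonPos, forbidStop, r4);
    tot[i] = r4[0] + r4[1] + r4[2] + r4[3];
    fw.add(i, tot[i]);
  }
  std::vector<int> evPos, evFrom, evTo;
  std::vector<int> evCpg;
  double t = 0.0;
  double T = fw.total();
  while (T > 0) {
    t += R::exp_rand() / T;
    if (t > len) break;
    double u = unif_rand() * T;
    int i = fw.search(u);
    if (i >= n) i = n - 1;
    // skip numerical zero-rate hits at the boundary
    site_rates(s, i, rates, cpgMultiplier, codonPos, forbidStop, r4);
    double ti = r4[0] + r4[1] + r4[2] + r4[3];
    if (ti <= 0) { T = fw.total(); continue; }
    double v = unif_rand() * ti;
    int to = 0;
    double c = 0.0;
    for (to = 0; to < 4; ++to) {
      c += r4[to];
      if (v < c) break;
    }
    if (to > 3) to = 3;
    const int from = s[i];
    const bool cpgctx = (from == 1 && i + 1 < n && s[i + 1] == 2) ||
                        (from == 2 && i > 0 && s[i - 1] == 1);
    evPos.push_back(i + 1);
    evFrom.push_back(from);
    evTo.push_back(to);
    evCpg.push_back(cpgctx ? 1 : 0);
    s[i] = to;
    const int lo = i > 0 ? i - 1 : 0;
    const int hi = i + 1 < n ? i + 1 : n - 1;
    for (int j = lo; j <= hi; ++j) {
      site_rates(s, j, rates, cpgMultiplier, codonPos, forbidStop, r4);
      const double nt = r4[0] + r4[1] + r4[2] + r4[3];
      fw.add(j, nt - tot[j]);
      tot[j] = nt;
    }
    T = fw.total();
  }
  return List::create(
      _["seq"] = IntegerVector(s.begin(), s.end()),
      _["pos"] = IntegerVector(evPos.begin(), evPos.end()),
      _["from"] = IntegerVector(evFrom.begin(), evFrom.end()),
      _["to"] = IntegerVector(evTo.begin(), evTo.end()),
      _["cpg"] = LogicalVector(evCpg.begin(), evCpg.end()));
}
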