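#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// Depth-first enumeration of small pedigrees with latent individuals,
// pruned by pairwise-degree evidence between sampled individuals.
//
// Node indices are 0-based; parents 0 = none (stored as -1 internally).
// Degree codes: 0 identical, 1..3 degrees, 4 unrelated, 5 undetermined.

namespace {

struct SearchState {
  int ns;                    // sampled count
  int maxNodes, maxLatent;
  double gapLo, gapHi;
  long cap, visits;
  bool complete, noInbreed;
  std::vector<int> evdeg;    // ns x ns degree codes
  std::vector<double> maxphi;
  std::vector<double> lo0, hi0;
  std::vector<std::array<int, 3 * 14> > results; // sex, mo, fa per node
  std::vector<int> resultN;
  size_t maxResults;
};

inline int ev(const SearchState &S, int a, int b) {
  return S.evdeg[a * S.ns + b];
}

// kinship matrix for current pedigree
void kinship(const std::vector<int> &mo, const std::vector<int> &fa,
             double phi[14][14]) {
  int n = (int)mo.size();
  // topological order by depth sweeps
  int depth[14] = {0};
  for (int pass = 0; pass <= n; ++pass) {
    bool ch = false;
    for (int i = 0; i < n; ++i) {
      int d = 0;
      if (mo[i] >= 0) d = std::max(d, depth[mo[i]] + 1);
      if (fa[i] >= 0) d = std::max(d, depth[fa[i]] + 1);
      if (d != depth[i]) { depth[i] = d; ch = true; }
    }
    if (!ch) break;
  }
  int ord[14];
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord, ord + n, [&](int a, int b) { return depth[a] < depth[b]; });
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) phi[a][b] = 0.0;
  for (int k = 0; k < n; ++k) {
    int i = ord[k];
    int m = mo[i], f = fa[i];
    for (int l = 0; l < k; ++l) {
      int j = ord[l];
      double v = 0.5 * ((m >= 0 ? phi[m][j] : 0.0) +
                        (f >= 0 ? phi[f][j] : 0.0));
      phi[i][j] = phi[j][i] = v;
    }
    phi[i][i] = 0.5 * (1.0 + (m >= 0 && f >= 0 ? phi[m][f] : 0.0));
  }
}

int degree_code(double p) {
  if (p <= 0) return 4;
  if (p >= 0.4) return 0;
  int d = (int)std::lround(-std::log2(4.0 * p)) + 1;
  if (d < 1) d = 1;
  return d > 3 ? 4 : d;
}

bool anc_of(const std::vector<int> &mo, const std::vector<int> &fa,
            int node, int anc) {
  // is `anc` an ancestor of (or equal to) node
  if (node == anc) return true;
  if (mo[node] >= 0 && anc_of(mo, fa, mo[node], anc)) return true;
  if (fa[node] >= 0 && anc_of(mo, fa, fa[node], anc)) return true;
  return false;
}

bool intervals_ok(const std::vector<int> &mo, const std::vector<int> &fa,
                  std::vector<double> lo, std::vector<double> hi,
                  double gapLo, double gapHi) {
  int n = (int)mo.size();
  for (int pass = 0; pass < 16; ++pass) {
    bool ch = false;
    for (int k = 0; k < n; ++k) {
      int ps[2] = {mo[k], fa[k]};
      for (int t = 0; t < 2; ++t) {
        int p = ps[t];
        if (p < 0) continue;
        double nlo = std::max(lo[k], lo[p] + gapLo);
        double nhi = std::min(hi[k], hi[p] + gapHi);
        double plo = std::max(lo[p], lo[k] - gapHi);
        double phi_ = std::min(hi[p], hi[k] - gapLo);
        if (nlo > nhi || plo > phi_) return false;
        if (nlo > lo[k] || nhi < hi[k] || plo > lo[p] || phi_ < hi[p])
          ch = true;
        lo[k] = nlo; hi[k] = nhi; lo[p] = plo; hi[p] = phi_;
      }
    }
    if (!ch) break;
  }
  return true;
}

// prune: kinship bounds, no-inbreeding, and exactness for closed pairs
bool prune_ok(SearchState &S, const std::vector<int> &mo,
              const std::vector<int> &fa, const std::vector<bool> &sexF,
              const std::vector<int> &pending) {
  int n = (int)mo.size();
  double phi[14][14];
  kinship(mo, fa, phi);
  for (int a = 0; a < S.ns; ++a)
    for (int b = a + 1; b < S.ns; ++b)
      if (phi[a][b] > S.maxphi[a * S.ns + b] + 1e-9) return false;
  if (S.noInbreed) {
    for (int k = 0; k < n; ++k)
      if (mo[k] >= 0 && fa[k] >= 0 && phi[mo[k]][fa[k]] > 1e-9) return false;
  }
  // openness: a node's kinship can still change iff it or an ancestor is
  // pending (new edges only attach parents to pending nodes)
  bool open[14] = {false};
  for (size_t q = 0; q < pending.size(); ++q) open[pending[q]] = true;
  for (int pass = 0; pass <= n; ++pass) {
    bool ch = false;
    for (int i = 0; i < n; ++i) {
      bool o = open[i] || (mo[i] >= 0 && open[mo[i]]) ||
               (fa[i] >= 0 && open[fa[i]]);
      if (o != open[i]) { open[i] = o; ch = true; }
    }
    if (!ch) break;
  }
  for (int a = 0; a < S.ns; ++a)
    for (int b = a + 1; b < S.ns; ++b) {
      int e = ev(S, a, b);
      if (e == 5) continue;
      if (!open[a] && !open[b] && degree_code(phi[a][b]) != e) return false;
    }
  return true;
}

void recurse(SearchState &S, std::vector<bool> sexF, std::vector<int> mo,
             std::vector<int> fa, std::vector<double> lo,
             std::vector<double> hi, std::vector<int> queue) {
  if (++S.visits > S.cap) { S.complete = false; return; }
  if (queue.empty()) {
    // closed-pair pruning already enforced degree exactness; check ages
    if (!intervals_ok(mo, fa, lo, hi, S.gapLo, S.gapHi)) return;
    if (S.results.size() >= S.maxResults) { S.complete = false; return; }
    std::array<int, 3 * 14> rec;
    rec.fill(-9);
    int n = (int)mo.size();
    for (int i = 0; i < n; ++i) {
      rec[i] = sexF[i] ? 1 : 0;
      rec[14 + i] = mo[i];
      rec[28 + i] = fa[i];
    }
    S.results.push_back(rec);
    S.resultN.push_back(n);
    return;
  }
  int child = queue.front();
  std::vector<int> rest(queue.begin() + 1, queue.end());
  bool sampledChild = child < S.ns;
  int n = (int)mo.size();
  int nLat = n - S.ns;

  std::vector<int> mothers, fathers;
  mothers.push_back(-1);
  fathers.push_back(-1);
  for (int p = 0; p < n; ++p) {
    if (p == child) continue;
    if (anc_of(mo, fa, p, child)) continue;  // would create a cycle
    if (sampledChild && p < S.ns) {
      int e = ev(S, child, p);
      if (e != 1 && e != 5) continue;  // sampled parent must be 1st/unknown
    }
    // local age screen
    if (lo[child] > hi[p] + S.gapHi || hi[child] < lo[p] + S.gapLo) continue;
    if (sexF[p]) mothers.push_back(p); else fathers.push_back(p);
  }
  if (sampledChild) { mothers.push_back(-2); fathers.push_back(-2); } // NEW

  for (size_t im = 0; im < mothers.size(); ++im)
    for (size_t io = 0; io < fathers.size(); ++io) {
      int mom = mothers[im], fat = fathers[io];
      int nNew = (mom == -2 ? 1 : 0) + (fat == -2 ? 1 : 0);
      if (nLat + nNew > S.maxLatent) continue;
      if (n + nNew > S.maxNodes) continue;
      std::vector<bool> sexF2 = sexF;
      std::vector<int> mo2 = mo, fa2 = fa;
      std::vector<double> lo2 = lo, hi2 = hi;
      std::vector<int> newq;
      int momId = mom, fatId = fat;
      if (mom == -2) {
        sexF2.push_back(true); mo2.push_back(-1); fa2.push_back(-1);
        lo2.push_back(-1e6); hi2.push_back(1e6);
        momId = (int)sexF2.size() - 1;
        newq.push_back(momId);
      }
      if (fat == -2) {
        sexF2.push_back(false); mo2.push_back(-1); fa2.push_back(-1);
        lo2.push_back(-1e6); hi2.push_back(1e6);
        fatId = (int)sexF2.size() - 1;
        newq.push_back(fatId);
      }
      mo2[child] = momId;
      fa2[child] = fatId;
      std::vector<int> pend = rest;
      pend.insert(pend.end(), newq.begin(), newq.end());
      if (!prune_ok(S, mo2, fa2, sexF2, pend)) continue;
      recurse(S, sexF2, mo2, fa2, lo2, hi2, pend);
      if (!S.complete && S.visits > S.cap) return;
    }
}

}  // namespace

// [[Rcpp::export]]
List ped_search_cpp(int ns, LogicalVector sexF, IntegerVector evdeg,
                    NumericVector maxphi, NumericVector lo0,
                    NumericVector hi0, int maxLatent, int maxNodes,
                    double gapLo, double gapHi, double cap,
                    bool noInbreed, int maxResults) {
  SearchState S;
  S.ns = ns;
  S.maxNodes = std::min(maxNodes, 14);
  S.maxLatent = maxLatent;
  S.gapLo = gapLo; S.gapHi = gapHi;
  S.cap = (long)cap; S.visits = 0;
  S.complete = true;
  S.noInbreed = noInbreed;
  S.evdeg = as<std::vector<int> >(evdeg);
  S.maxphi = as<std::vector<double> >(maxphi);
  S.maxResults = (size_t)maxResults;
  std::vector<bool> sx(ns);
  for (int i = 0; i < ns; ++i) sx[i] = sexF[i];
  std::vector<int> mo(ns, -1), fa(ns, -1), queue(ns);
  for (int i = 0; i < ns; ++i) queue[i] = i;
  std::vector<double> lo = as<std::vector<double> >(lo0);
  std::vector<double> hi = as<std::vector<double> >(hi0);
  recurse(S, sx, mo, fa, lo, hi, queue);

  int nr = (int)S.results.size();
  List out(nr);
  for (int r = 0; r < nr; ++r) {
    int n = S.resultN[r];
    IntegerVector sexv(n), mov(n), fav(n);
    for (int i = 0; i < n; ++i) {
      sexv[i] = S.results[r][i];
      mov[i] = S.results[r][14 + i] + 1;  // back to 1-based, 0 = none
      fav[i] = S.results[r][28 + i] + 1;
    }
    out[r] = List::create(Named("sex") = sexv, Named("mother") = mov,
                          Named("father") = fav);
  }
  return List::create(Named("candidates") = out,
                      Named("complete") = S.complete,
                      Named("n_visited") = (double)S.visits);
}
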