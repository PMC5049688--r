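// Core backward-in-time machinery: interval algebra on genome coordinates,
// closed-form effective recombination rates with analytical (rejection-free)
// event sampling, the coalescent-with-gene-conversion event loop, and
// Jukes-Cantor sequence propagation down the resulting graph.
//
// All randomness draws from R's RNG stream, so set.seed() on the R side
// makes every run byte-reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef std::pair<int, int> PI;
typedef std::vector<PI> ISet;   // sorted, disjoint, non-adjacent [start,end)

// ---------------------------------------------------------------- intervals

static ISet iset_from_matrix(const IntegerMatrix& m) {
  ISet s;
  s.reserve(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) s.push_back(PI(m(i, 0), m(i, 1)));
  return s;
}

static IntegerMatrix iset_to_matrix(const ISet& s) {
  IntegerMatrix m((int)s.size(), 2);
  for (size_t i = 0; i < s.size(); ++i) {
    m((int)i, 0) = s[i].first;
    m((int)i, 1) = s[i].second;
  }
  return m;
}

static long long iset_total(const ISet& s) {
  long long t = 0;
  for (const PI& p : s) t += p.second - p.first;
  return t;
}

// canonicalize a list of possibly overlapping/abutting intervals
static ISet iset_canon(ISet v) {
  if (v.empty()) return v;
  std::sort(v.begin(), v.end());
  ISet out;
  int cs = v[0].first, ce = v[0].second;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i].first <= ce) ce = std::max(ce, v[i].second);
    else { out.push_back(PI(cs, ce)); cs = v[i].first; ce = v[i].second; }
  }
  out.push_back(PI(cs, ce));
  return out;
}

static ISet iset_union(const ISet& a, const ISet& b) {
  ISet v(a);
  v.insert(v.end(), b.begin(), b.end());
  return iset_canon(v);
}

static ISet iset_intersect(const ISet& a, const ISet& b) {
  ISet out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    int s = std::max(a[i].first, b[j].first);
    int e = std::min(a[i].second, b[j].second);
    if (s < e) out.push_back(PI(s, e));
    if (a[i].second < b[j].second) ++i; else ++j;
  }
  return out;
}

static ISet iset_diff(const ISet& a, const ISet& b) {
  ISet out;
  size_t j = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int s = a[i].first, e = a[i].second;
    while (j < b.size() && b[j].second <= s) ++j;
    size_t jj = j;
    while (jj < b.size() && b[jj].first < e) {
      if (b[jj].first > s) out.push_back(PI(s, b[jj].first));
      s = std::max(s, b[jj].second);
      ++jj;
    }
    if (s < e) out.push_back(PI(s, e));
  }
  return out;
}

// footprint of a conversion tract: wraps on circular, truncates on linear
static ISet wrap_tract(int s, long long len, int G, bool circular) {
  ISet out;
  if (!circular) {
    long long e = std::min((long long)G, (long long)s + len);
    out.push_back(PI(s, (int)e));
    return out;
  }
  if (len >= G) { out.push_back(PI(0, G)); return out; }
  int e = (int)(((long long)s + len) % G);
  if (e > s) out.push_back(PI(s, e));
  else if (e == 0) out.push_back(PI(s, G));
  else { out.push_back(PI(0, e)); out.push_back(PI(s, G)); }
  return out;
}

// ------------------------------------------------- geometric tract lengths
//
// Tract lengths are geometric with mean delta: P(l) = (1/delta) q^(l-1),
// l >= 1, q = 1 - 1/delta.  All tail quantities are computed through
// log1p/expm1 so that very large delta stays accurate.

struct Geom {
  double delta;
  double lq;     // log q
  bool q0;       // delta == 1 (q == 0)
  explicit Geom(double d) : delta(d) {
    q0 = (d <= 1.0);
    lq = q0 ? R_NegInf : std::log1p(-1.0 / d);
  }
  double pow_q(long long k) const {          // q^k
    if (k <= 0) return 1.0;
    if (q0) return 0.0;
    return std::exp((double)k * lq);
  }
  double om_pow(long long k) const {         // 1 - q^k
    if (k <= 0) return 0.0;
    if (q0) return 1.0;
    return -std::expm1((double)k * lq);
  }
  double geo_sum(long long g) const {        // sum_{d=1..g} q^d
    if (g <= 0 || q0) return 0.0;
    return std::exp(lq) * om_pow(g) * delta; // q (1-q^g) / (1-q), 1-q = 1/delta
  }
};

// truncated geometric: P(l) proportional to q^(l-1) on [a, b]
static long long rtgeom(const Geom& g, long long a, long long b) {
  if (g.q0 || a >= b) return a;
  double u = R::unif_rand();
  double T = 1.0 - u * g.om_pow(b - a + 1);
  long long j = (long long)std::ceil(std::log(T) / g.lq);
  if (j < 1) j = 1;
  if (j > b - a + 1) j = b - a + 1;
  return a - 1 + j;
}

// unconditioned geometric shifted to l >= a
static long long rgeom_ge(const Geom& g, long long a) {
  if (g.q0) return a;
  double u = R::unif_rand();
  long long j = (long long)std::floor(std::log(u) / g.lq);
  if (j < 0) j = 0;
  return a + j;
}

// --------------------------------------- effective within-species sampling
//
// A within-species event starting at s with tract length l is effective iff
// the tract both touches the lineage's ancestral material and leaves some of
// it untouched.  For every start s the effective lengths form a contiguous
// range [a(s), L(s)], so P(effective | s) = q^(a(s)-1) - q^(L(s)) and the
// start sites group into O(k) categories (material interior, interval start
// sites, gap runs) with closed-form total weights.  The same decomposition
// drives both the rate and the exact sampler, so they agree by construction.

struct Cat {
  double w;        // total weight of the category
  int type;
  long long a, b;  // type-specific parameters
};

// circular types: 0 material-interior site; 1 interval start (a=s, b=Lmax);
//                 2 gap run (a=next interval start, b=gap length)
// linear types:   0 material site other than the first; 1 first material
//                 site (a=s, b=span last-first); 3 leading gap (a=first,
//                 b=span); 4 interior gap (a=next interval start, b=gap)
static double within_cats(const ISet& mat, int G, bool circular,
                          const Geom& g, std::vector<Cat>& cats) {
  cats.clear();
  int k = (int)mat.size();
  long long m = iset_total(mat);
  double tot = 0.0;
  if (circular) {
    std::vector<long long> gap(k);
    for (int i = 0; i < k; ++i) {
      if (i == k - 1) gap[i] = (long long)mat[0].first + G - mat[k - 1].second;
      else gap[i] = (long long)mat[i + 1].first - mat[i].second;
    }
    if (m - k > 0) {
      double w = (double)(m - k) * g.om_pow(G - 1);
      if (w > 0) { cats.push_back({w, 0, 0, 0}); tot += w; }
    }
    for (int i = 0; i < k; ++i) {
      long long gprev = gap[(i - 1 + k) % k];
      long long L = (long long)G - gprev - 1;
      if (L >= 1) {
        double w = g.om_pow(L);
        if (w > 0) { cats.push_back({w, 1, (long long)mat[i].first, L}); tot += w; }
      }
    }
    for (int i = 0; i < k; ++i) {
      if (gap[i] > 0) {
        double w = g.om_pow((long long)G - gap[i] - 1) * g.geo_sum(gap[i]);
        if (w > 0) {
          cats.push_back({w, 2, (long long)mat[(i + 1) % k].first, gap[i]});
          tot += w;
        }
      }
    }
  } else {
    long long first = mat[0].first, last = mat[k - 1].second - 1;
    long long D = last - first;
    if (m - 1 > 0) { cats.push_back({(double)(m - 1), 0, 0, 0}); tot += m - 1; }
    if (D >= 1) {
      double w = g.om_pow(D);
      if (w > 0) { cats.push_back({w, 1, first, D}); tot += w; }
      if (first > 0) {
        double wl = g.om_pow(D) * g.geo_sum(first);
        if (wl > 0) { cats.push_back({wl, 3, first, D}); tot += wl; }
      }
    }
    for (int i = 0; i + 1 < k; ++i) {
      long long gp = (long long)mat[i + 1].first - mat[i].second;
      if (gp > 0) {
        double w = g.geo_sum(gp);
        if (w > 0) { cats.push_back({w, 4, (long long)mat[i + 1].first, gp}); tot += w; }
      }
    }
  }
  return tot;
}

// r-th material site under two exclusion modes:
//   mode 0: skip the first site of every interval (circular interior sites)
//   mode 1: skip only the globally first material site (linear case)
static int pick_material_site(const ISet& mat, long long r, int mode) {
  for (size_t i = 0; i < mat.size(); ++i) {
    long long start = mat[i].first;
    if (mode == 0 || i == 0) start += 1;
    long long cnt = mat[i].second - start;
    if (cnt > 0) {
      if (r < cnt) return (int)(start + r);
      r -= cnt;
    }
  }
  Rcpp::stop("internal error: material site index out of range");
  return -1; // unreachable
}

static void within_sample(const ISet& mat, int G, bool circular, const Geom& g,
                          int& s_out, long long& l_out) {
  std::vector<Cat> cats;
  double tot = within_cats(mat, G, circular, g, cats);
  if (tot <= 0) Rcpp::stop("within-species event sampled at zero effective rate");
  double u = R::unif_rand() * tot;
  size_t ci = 0;
  for (; ci + 1 < cats.size(); ++ci) {
    if (u < cats[ci].w) break;
    u -= cats[ci].w;
  }
  const Cat& c = cats[ci];
  long long m = iset_total(mat);
  int k = (int)mat.size();
  if (circular) {
    switch (c.type) {
    case 0: { // interior site: uniform among m-k, l in [1, G-1]
      long long r = (long long)(R::unif_rand() * (double)(m - k));
      if (r >= m - k) r = m - k - 1;
      s_out = pick_material_site(mat, r, 0);
      l_out = rtgeom(g, 1, G - 1);
      break;
    }
    case 1: { // interval start site
      s_out = (int)c.a;
      l_out = rtgeom(g, 1, c.b);
      break;
    }
    default: { // gap run before interval starting at c.a, gap length c.b
      long long d = rtgeom(g, 1, c.b);
      s_out = (int)(((c.a - d) % G + G) % G);
      l_out = rtgeom(g, d + 1, (long long)G - c.b + d - 1);
      break;
    }
    }
  } else {
    switch (c.type) {
    case 0: { // any material site except the first; l unbounded
      long long r = (long long)(R::unif_rand() * (double)(m - 1));
      if (r >= m - 1) r = m - 2;
      s_out = pick_material_site(mat, r, 1);
      l_out = rgeom_ge(g, 1);
      break;
    }
    case 1: { // the first material site
      s_out = (int)c.a;
      l_out = rtgeom(g, 1, c.b);
      break;
    }
    case 3: { // leading gap: s = first - d, l in [d+1, D+d]
      long long d = rtgeom(g, 1, c.a);
      s_out = (int)(c.a - d);
      l_out = rtgeom(g, d + 1, c.b + d);
      break;
    }
    default: { // interior gap before interval starting at c.a
      long long d = rtgeom(g, 1, c.b);
      s_out = (int)(c.a - d);
      l_out = rgeom_ge(g, d + 1);
      break;
    }
    }
  }
}

// ----------------------------------------- effective external-rate sampling
//
// An external (between-species) event is effective iff the tract touches
// ancestral material at all; there is no bipartition requirement because the
// donor is not tracked inside the graph.

static double external_cats(const ISet& mat, int G, bool circular,
                            const Geom& g, std::vector<Cat>& cats) {
  cats.clear();
  int k = (int)mat.size();
  long long m = iset_total(mat);
  double tot = 0.0;
  cats.push_back({(double)m, 0, 0, 0});
  tot += (double)m;
  if (circular) {
    for (int i = 0; i < k; ++i) {
      long long gp = (i == k - 1)
        ? (long long)mat[0].first + G - mat[k - 1].second
        : (long long)mat[i + 1].first - mat[i].second;
      if (gp > 0) {
        double w = g.geo_sum(gp);
        if (w > 0) { cats.push_back({w, 1, (long long)mat[(i + 1) % k].first, gp}); tot += w; }
      }
    }
  } else {
    if (mat[0].first > 0) {
      double w = g.geo_sum(mat[0].first);
      if (w > 0) { cats.push_back({w, 1, (long long)mat[0].first, (long long)mat[0].first}); tot += w; }
    }
    for (int i = 0; i + 1 < k; ++i) {
      long long gp = (long long)mat[i + 1].first - mat[i].second;
      if (gp > 0) {
        double w = g.geo_sum(gp);
        if (w > 0) { cats.push_back({w, 1, (long long)mat[i + 1].first, gp}); tot += w; }
      }
    }
  }
  return tot;
}

static void external_sample(const ISet& mat, int G, bool circular,
                            const Geom& g, int& s_out, long long& l_out) {
  std::vector<Cat> cats;
  double tot = external_cats(mat, G, circular, g, cats);
  if (tot <= 0) Rcpp::stop("external event sampled at zero effective rate");
  double u = R::unif_rand() * tot;
  size_t ci = 0;
  for (; ci + 1 < cats.size(); ++ci) {
    if (u < cats[ci].w) break;
    u -= cats[ci].w;
  }
  const Cat& c = cats[ci];
  long long m = iset_total(mat);
  if (c.type == 0) { // start on a material site
    long long r = (long long)(R::unif_rand() * (double)m);
    if (r >= m) r = m - 1;
    for (size_t i = 0; i < mat.size(); ++i) {
      long long cnt = mat[i].second - mat[i].first;
      if (r < cnt) { s_out = (int)(mat[i].first + r); break; }
      r -= cnt;
    }
    l_out = rgeom_ge(g, 1);
  } else {           // start d sites before the interval starting at c.a
    long long d = rtgeom(g, 1, c.b);
    s_out = (int)(((c.a - d) % G + G) % G);
    l_out = rgeom_ge(g, d + 1);
  }
}

// -------------------------------------------------------- exported helpers

// [[Rcpp::export]]
double cpp_within_weight(IntegerMatrix mat, int G, bool circular, double delta) {
  ISet m = iset_from_matrix(mat);
  if (m.empty()) Rcpp::stop("empty ancestral material");
  Geom g(delta);
  std::vector<Cat> cats;
  return within_cats(m, G, circular, g, cats);
}

// [[Rcpp::export]]
double cpp_external_weight(IntegerMatrix mat, int G, bool circular, double delta) {
  ISet m = iset_from_matrix(mat);
  if (m.empty()) Rcpp::stop("empty ancestral material");
  Geom g(delta);
  std::vector<Cat> cats;
  return external_cats(m, G, circular, g, cats);
}

// [[Rcpp::export]]
List cpp_sample_within(IntegerMatrix mat, int G, bool circular, double delta) {
  ISet m = iset_from_matrix(mat);
  if (m.empty()) Rcpp::stop("empty ancestral material");
  Geom g(delta);
  int s; long long l;
  within_sample(m, G, circular, g, s, l);
  ISet tract = wrap_tract(s, l, G, circular);
  return List::create(_["s"] = s, _["len"] = (double)l,
                      _["tract"] = iset_to_matrix(tract));
}

// [[Rcpp::export]]
List cpp_sample_external(IntegerMatrix mat, int G, bool circular, double delta) {
  ISet m = iset_from_matrix(mat);
  if (m.empty()) Rcpp::stop("empty ancestral material");
  Geom g(delta);
  int s; long long l;
  external_sample(m, G, circular, g, s, l);
  ISet tract = wrap_tract(s, l, G, circular);
  return List::create(_["s"] = s, _["len"] = (double)l,
                      _["tract"] = iset_to_matrix(tract));
}

// ------------------------------------------------------------ the ARG loop

struct ArgBuild {
  std::vector<int> kind, child1, child2, pcont, pdon;
  std::vector<double> ntime, ndiv;
  std::vector<int> as_, ae_;                    // interval arena
  std::vector<int> snap_off, snap_n, aux_off, aux_n;

  int add_iset(const ISet& s) {
    int off = (int)as_.size();
    for (const PI& p : s) { as_.push_back(p.first); ae_.push_back(p.second); }
    return off;
  }
  int push(int k, double t, int c1, int c2,
           const ISet& snap, const ISet& aux, double dv) {
    kind.push_back(k); ntime.push_back(t);
    child1.push_back(c1); child2.push_back(c2);
    pcont.push_back(-1); pdon.push_back(-1);
    snap_off.push_back(add_iset(snap)); snap_n.push_back((int)snap.size());
    aux_off.push_back(add_iset(aux)); aux_n.push_back((int)aux.size());
    ndiv.push_back(dv);
    return (int)kind.size() - 1;
  }
  ISet get(int off, int n) const {
    ISet s; s.reserve(n);
    for (int i = 0; i < n; ++i) s.push_back(PI(as_[off + i], ae_[off + i]));
    return s;
  }
};

struct Lin {
  ISet mat;
  bool clonal;
  int origin;     // node at the tip-ward end of this lineage
  int slot;       // 0 = continuing/recipient, 1 = donor
  double wsum, esum;
  int id;         // stable lineage identifier for the event list
  int ctip;       // clonal-frame label (-1 if not clonal)
};

// ensure a breakpoint exists at x
static void cov_cut(std::map<int, int>& cov, int x, int G) {
  if (x >= G) return;
  std::map<int, int>::iterator it = cov.lower_bound(x);
  if (it == cov.end() || it->first != x) {
    --it;
    cov[x] = it->second;
  }
}

// decrement lineage counts over `s`; regions whose count hits 1 are fully
// coalesced within the sample: they are zeroed here and reported in `newly1`
static void cov_dec(std::map<int, int>& cov, const ISet& s, int G, ISet& newly1) {
  for (const PI& p : s) {
    cov_cut(cov, p.first, G);
    cov_cut(cov, p.second, G);
    std::map<int, int>::iterator it = cov.find(p.first);
    while (it != cov.end() && it->first < p.second) {
      it->second -= 1;
      std::map<int, int>::iterator nx = std::next(it);
      int end = (nx == cov.end()) ? G : nx->first;
      if (it->second == 1) {
        newly1.push_back(PI(it->first, std::min(end, p.second)));
        it->second = 0;
      }
      it = nx;
    }
    // compact: merge runs that now share a count so the map stays small
    it = cov.lower_bound(p.first);
    if (it != cov.begin()) --it;
    int prev = it->second;
    ++it;
    while (it != cov.end() && it->first <= p.second) {
      if (it->second == prev) it = cov.erase(it);
      else { prev = it->second; ++it; }
    }
  }
}

// [[Rcpp::export]]
List cpp_simulate_arg(int n, int G, bool circular, IntegerMatrix spans_m,
                      double rho, double delta, double rho_ext, double delta_ext,
                      double div_min, double div_max, double max_events) {
  ISet spans = iset_from_matrix(spans_m);
  Geom gw(delta), ge(delta_ext);

  ArgBuild A;
  std::vector<int> eparent, echild, eslot;
  std::vector<bool> eclonal;
  std::vector<int> rnode, roff, rn;                 // resolution records
  std::vector<int> evkind, evlin, evoff, evn;       // event list
  std::vector<double> evtime, evdiv;
  std::vector<double> cmtime;                       // clonal-frame merges
  std::vector<int> cma, cmb;

  std::vector<Lin> lins;
  int next_id = n;
  for (int i = 0; i < n; ++i) {
    int leaf = A.push(0, 0.0, -1, -1, spans, ISet(), NA_REAL);
    Lin l; l.mat = spans; l.clonal = true; l.origin = leaf; l.slot = 0;
    l.id = i; l.ctip = i; l.wsum = 0.0; l.esum = 0.0;
    lins.push_back(l);
  }

  std::map<int, int> cov;
  cov[0] = 0;
  for (const PI& p : spans) { cov[p.first] = n; cov[p.second] = 0; }
  cov[G] = 0;
  long long live = iset_total(spans);

  // per-lineage effective rates (recomputed only when material changes),
  // with running totals maintained incrementally and refreshed periodically
  // against floating-point drift
  double Wtot = 0.0, Etot = 0.0;
  std::vector<Cat> scratch;
  auto set_rates = [&](Lin& l) {
    Wtot -= l.wsum; Etot -= l.esum;
    if (l.mat.empty()) { l.wsum = 0.0; l.esum = 0.0; return; }
    l.wsum = (rho > 0) ? 0.5 * rho * within_cats(l.mat, G, circular, gw, scratch) : 0.0;
    l.esum = (rho_ext > 0) ? 0.5 * rho_ext * external_cats(l.mat, G, circular, ge, scratch) : 0.0;
    Wtot += l.wsum; Etot += l.esum;
  };
  auto drop_rates = [&](const Lin& l) { Wtot -= l.wsum; Etot -= l.esum; };
  for (Lin& l : lins) set_rates(l);

  auto add_res = [&](const ISet& s, int node) {
    rnode.push_back(node);
    roff.push_back(A.add_iset(s));
    rn.push_back((int)s.size());
  };

  // remove fully-coalesced regions from every carrier (general form,
  // needed after external imports where the surviving carrier can be any
  // lineage; early exit once every pruned site is accounted for)
  auto prune_regions = [&](const ISet& regions) {
    if (regions.empty()) return;
    long long remaining = iset_total(regions);
    live -= remaining;
    for (size_t i = 0; i < lins.size() && remaining > 0;) {
      ISet part = iset_intersect(lins[i].mat, regions);
      if (!part.empty()) {
        remaining -= iset_total(part);
        lins[i].mat = iset_diff(lins[i].mat, part);
        add_res(part, lins[i].origin);
        if (lins[i].mat.empty() && !lins[i].clonal) {
          drop_rates(lins[i]);
          if (i != lins.size() - 1) lins[i] = std::move(lins.back());
          lins.pop_back();
          continue;
        }
        set_rates(lins[i]);
      }
      ++i;
    }
  };

  // after a coalescence the only possible carrier of a newly-single region
  // is the merged lineage itself (its two children were the only carriers)
  auto prune_merged = [&](const ISet& regions, Lin& merged) {
    if (regions.empty()) return;
    live -= iset_total(regions);
    merged.mat = iset_diff(merged.mat, regions);
    add_res(regions, merged.origin);
  };

  double t = 0.0;
  double events = 0.0;
  size_t peak_lineages = lins.size();
  while (!(live == 0 && lins.size() == 1)) {
    size_t k = lins.size();
    if (k > peak_lineages) peak_lineages = k;
    if (((long long)events & 2047LL) == 0LL) {   // periodic exact refresh
      Wtot = 0.0; Etot = 0.0;
      for (const Lin& l : lins) { Wtot += l.wsum; Etot += l.esum; }
    }
    double W = Wtot > 0 ? Wtot : 0.0, E = Etot > 0 ? Etot : 0.0;
    double coal = 0.5 * (double)k * (double)(k - 1);
    double tot = coal + W + E;
    if (tot <= 0) Rcpp::stop("internal error: zero total rate with unresolved material");
    t += R::exp_rand() / tot;
    if (++events > max_events)
      Rcpp::stop("event cap exceeded (n=%d, G=%d, R=%g, delta=%g, R_e=%g, delta_e=%g): "
                 "raise max_events if this parameter set is intended",
                 n, G, rho, delta, rho_ext, delta_ext);
    double u = R::unif_rand() * tot;

    if (u < coal) {
      // ---- coalescence of a uniform pair
      int i = (int)(R::unif_rand() * k); if (i >= (int)k) i = (int)k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= (int)k - 1) j = (int)k - 2;
      if (j >= i) ++j;
      Lin a = lins[i], b = lins[j];
      ISet uni = iset_union(a.mat, b.mat);
      int C = A.push(1, t, a.origin, b.origin, uni, ISet(), NA_REAL);
      if (a.slot == 0) A.pcont[a.origin] = C; else A.pdon[a.origin] = C;
      if (b.slot == 0) A.pcont[b.origin] = C; else A.pdon[b.origin] = C;
      eparent.push_back(C); echild.push_back(a.origin); eslot.push_back(a.slot);
      eclonal.push_back(a.clonal);
      eparent.push_back(C); echild.push_back(b.origin); eslot.push_back(b.slot);
      eclonal.push_back(b.clonal);

      Lin merged;
      merged.mat = uni;
      merged.clonal = a.clonal || b.clonal;
      merged.origin = C; merged.slot = 0; merged.id = next_id++;
      merged.wsum = 0.0; merged.esum = 0.0;
      if (a.clonal && b.clonal) {
        cmtime.push_back(t); cma.push_back(a.ctip); cmb.push_back(b.ctip);
        merged.ctip = n + (int)cmtime.size() - 1;
      } else {
        merged.ctip = a.clonal ? a.ctip : (b.clonal ? b.ctip : -1);
      }
      ISet inter = iset_intersect(a.mat, b.mat);
      drop_rates(a); drop_rates(b);
      if (i < j) std::swap(i, j);           // i > j
      if (i != (int)lins.size() - 1) lins[i] = std::move(lins.back());
      lins.pop_back();
      if (j != (int)lins.size() - 1) lins[j] = std::move(lins.back());
      lins.pop_back();
      lins.push_back(std::move(merged));
      if (!inter.empty()) {
        ISet newly1;
        cov_dec(cov, inter, G, newly1);
        prune_merged(iset_canon(newly1), lins.back());
      }
      set_rates(lins.back());
    } else if (u < coal + W) {
      // ---- within-species recombination: split recipient / donor
      u -= coal;
      size_t li = k;
      for (size_t q = 0; q < k; ++q) {
        if (lins[q].wsum > 0) {
          li = q;
          if (u < lins[q].wsum) break;
          u -= lins[q].wsum;
        }
      }
      if (li == k) continue;   // numerically phantom total; no event
      int s; long long len;
      within_sample(lins[li].mat, G, circular, gw, s, len);
      ISet tract = wrap_tract(s, len, G, circular);
      ISet don = iset_intersect(lins[li].mat, tract);
      ISet rec = iset_diff(lins[li].mat, don);
      if (don.empty() || rec.empty())
        Rcpp::stop("internal error: ineffective within-species event sampled");
      int S = A.push(2, t, lins[li].origin, -1, lins[li].mat, don, NA_REAL);
      if (lins[li].slot == 0) A.pcont[lins[li].origin] = S;
      else A.pdon[lins[li].origin] = S;
      eparent.push_back(S); echild.push_back(lins[li].origin);
      eslot.push_back(lins[li].slot); eclonal.push_back(lins[li].clonal);
      evkind.push_back(0); evtime.push_back(t); evlin.push_back(lins[li].id);
      evoff.push_back(A.add_iset(tract)); evn.push_back((int)tract.size());
      evdiv.push_back(NA_REAL);

      lins[li].mat = rec; lins[li].origin = S; lins[li].slot = 0;
      set_rates(lins[li]);
      Lin d; d.mat = don; d.clonal = false; d.origin = S; d.slot = 1;
      d.id = next_id++; d.ctip = -1; d.wsum = 0.0; d.esum = 0.0;
      set_rates(d);
      lins.push_back(d);
    } else {
      // ---- between-species (external) import
      u -= coal + W;
      size_t li = k;
      for (size_t q = 0; q < k; ++q) {
        if (lins[q].esum > 0) {
          li = q;
          if (u < lins[q].esum) break;
          u -= lins[q].esum;
        }
      }
      if (li == k) continue;   // numerically phantom total; no event
      int s; long long len;
      external_sample(lins[li].mat, G, circular, ge, s, len);
      ISet tract = wrap_tract(s, len, G, circular);
      ISet imp = iset_intersect(lins[li].mat, tract);
      if (imp.empty())
        Rcpp::stop("internal error: external event missing ancestral material");
      double d = div_min + R::unif_rand() * (div_max - div_min);
      int Ei = A.push(3, t, lins[li].origin, -1, lins[li].mat, imp, d);
      if (lins[li].slot == 0) A.pcont[lins[li].origin] = Ei;
      else A.pdon[lins[li].origin] = Ei;
      eparent.push_back(Ei); echild.push_back(lins[li].origin);
      eslot.push_back(lins[li].slot); eclonal.push_back(lins[li].clonal);
      evkind.push_back(1); evtime.push_back(t); evlin.push_back(lins[li].id);
      evoff.push_back(A.add_iset(tract)); evn.push_back((int)tract.size());
      evdiv.push_back(d);

      ISet rem = iset_diff(lins[li].mat, imp);
      if (rem.empty() && !lins[li].clonal) {
        drop_rates(lins[li]);
        if (li != lins.size() - 1) lins[li] = std::move(lins.back());
        lins.pop_back();
      } else {
        lins[li].mat = rem; lins[li].origin = Ei; lins[li].slot = 0;
        set_rates(lins[li]);
      }
      ISet newly1;
      cov_dec(cov, imp, G, newly1);
      prune_regions(iset_canon(newly1));
    }
  }

  int nw = 0, ne = 0;
  for (int kk : evkind) { if (kk == 0) ++nw; else ++ne; }
  return List::create(
    _["kind"] = A.kind, _["time"] = A.ntime,
    _["child1"] = A.child1, _["child2"] = A.child2,
    _["p_cont"] = A.pcont, _["p_don"] = A.pdon, _["div"] = A.ndiv,
    _["arena_start"] = A.as_, _["arena_end"] = A.ae_,
    _["snap_off"] = A.snap_off, _["snap_n"] = A.snap_n,
    _["aux_off"] = A.aux_off, _["aux_n"] = A.aux_n,
    _["res_node"] = rnode, _["res_off"] = roff, _["res_n"] = rn,
    _["ev_kind"] = evkind, _["ev_time"] = evtime, _["ev_lin"] = evlin,
    _["ev_off"] = evoff, _["ev_n"] = evn, _["ev_div"] = evdiv,
    _["edge_parent"] = eparent, _["edge_child"] = echild,
    _["edge_slot"] = eslot, _["edge_clonal"] = eclonal,
    _["cm_time"] = cmtime, _["cm_a"] = cma, _["cm_b"] = cmb,
    _["n_within"] = nw, _["n_external"] = ne,
    _["peak_lineages"] = (int)peak_lineages,
    _["tmrca"] = cmtime.empty() ? NA_REAL : cmtime.back());
}

// ------------------------------------------------- sequence down the graph
//
// Contents are propagated root-ward to tip-ward.  Every node's content is
// defined on its material snapshot; regions resolved at the node (local
// MRCAs) receive the root sequence, import tracts receive the root homolog
// with divergence d injected, everything else is fetched from the routed
// parent and evolved under Jukes-Cantor at rate theta/2 per site.

static void jc_mutate(std::vector<unsigned char>& v, double rate_len) {
  if (rate_len <= 0 || v.empty()) return;
  int nm = (int)R::rpois(rate_len);
  int L = (int)v.size();
  for (int i = 0; i < nm; ++i) {
    int idx = (int)(R::unif_rand() * L); if (idx >= L) idx = L - 1;
    int shift = 1 + (int)(R::unif_rand() * 3.0); if (shift > 3) shift = 3;
    v[idx] = (unsigned char)((v[idx] + shift) & 3);
  }
}

// walk runs of `q` (subset of `dom`), calling
//   fn(dom_offset, q_offset, genome_start, len)
template <typename F>
static void for_runs(const ISet& dom, const ISet& q, F fn) {
  size_t i = 0;
  long long dpre = 0;   // sites of dom before interval i
  long long qpre = 0;
  for (size_t j = 0; j < q.size(); ++j) {
    int s = q[j].first, e = q[j].second;
    while (s < e) {
      while (i < dom.size() && dom[i].second <= s) {
        dpre += dom[i].second - dom[i].first;
        ++i;
      }
      if (i >= dom.size() || dom[i].first > s)
        Rcpp::stop("internal error: query interval outside content domain");
      int re = std::min(e, dom[i].second);
      fn(dpre + (s - dom[i].first), qpre, s, (long long)(re - s));
      qpre += re - s;
      s = re;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_alignment(
    IntegerVector kind, NumericVector ntime,
    IntegerVector child1, IntegerVector child2,
    IntegerVector pcont, IntegerVector pdon, NumericVector ndiv,
    IntegerVector arena_start, IntegerVector arena_end,
    IntegerVector snap_off, IntegerVector snap_n,
    IntegerVector aux_off, IntegerVector aux_n,
    IntegerVector res_node, IntegerVector res_off, IntegerVector res_n,
    IntegerMatrix spans_m, int n, IntegerVector rootseq, double theta) {
  int N = kind.size();
  ISet spans = iset_from_matrix(spans_m);
  long long Lseq = iset_total(spans);

  auto get_iset = [&](int off, int cnt) {
    ISet s; s.reserve(cnt);
    for (int i = 0; i < cnt; ++i)
      s.push_back(PI(arena_start[off + i], arena_end[off + i]));
    return s;
  };

  // resolution records grouped by node
  std::vector<ISet> resolved(N);
  for (int r = 0; r < res_node.size(); ++r) {
    ISet s = get_iset(res_off[r], res_n[r]);
    ISet& tgt = resolved[res_node[r]];
    tgt.insert(tgt.end(), s.begin(), s.end());
  }
  for (int v = 0; v < N; ++v) resolved[v] = iset_canon(resolved[v]);

  std::vector<int> pending(N, 0);
  for (int v = 0; v < N; ++v) {
    if (child1[v] >= 0) ++pending[v];
    if (child2[v] >= 0) ++pending[v];
  }

  std::vector<int> order(N);
  for (int v = 0; v < N; ++v) order[v] = v;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return ntime[a] > ntime[b]; });

  std::vector<ISet> domain(N);
  std::vector<std::vector<unsigned char> > content(N);

  IntegerMatrix out((int)n, (int)Lseq);

  for (int oi = 0; oi < N; ++oi) {
    int v = order[oi];
    ISet dom = get_iset(snap_off[v], snap_n[v]);
    domain[v] = dom;
    long long dl = iset_total(dom);
    std::vector<unsigned char>& cv = content[v];
    cv.assign((size_t)dl, 0);
    if (dl > 0) {
      ISet placed;                       // regions already filled
      // 1. locally resolved regions take the root sequence
      if (!resolved[v].empty()) {
        for_runs(dom, resolved[v],
                 [&](long long doff, long long, int gs, long long len) {
          for (long long x = 0; x < len; ++x)
            cv[doff + x] = (unsigned char)rootseq[gs + x];
        });
        placed = resolved[v];
      }
      // 2. import tract: root homolog plus injected divergence
      if (kind[v] == 3) {
        ISet tract = get_iset(aux_off[v], aux_n[v]);
        double d = ndiv[v];
        for_runs(dom, tract,
                 [&](long long doff, long long, int gs, long long len) {
          for (long long x = 0; x < len; ++x) {
            unsigned char b = (unsigned char)rootseq[gs + x];
            if (d > 0 && R::unif_rand() < d) {
              int shift = 1 + (int)(R::unif_rand() * 3.0); if (shift > 3) shift = 3;
              b = (unsigned char)((b + shift) & 3);
            }
            cv[doff + x] = b;
          }
        });
        placed = iset_union(placed, tract);
      }
      // 3. everything else comes from the routed parent, evolved
      ISet rest = placed.empty() ? dom : iset_diff(dom, placed);
      if (!rest.empty()) {
        ISet donor_mat = (kind[v] == 2) ? get_iset(aux_off[v], aux_n[v]) : ISet();
        ISet qd = (kind[v] == 2) ? iset_intersect(rest, donor_mat) : ISet();
        ISet qr = (kind[v] == 2) ? iset_diff(rest, qd) : rest;
        struct Route { ISet q; int parent; };
        std::vector<Route> routes;
        if (!qr.empty()) routes.push_back({qr, pcont[v]});
        if (!qd.empty()) routes.push_back({qd, pdon[v]});
        for (const Route& rt : routes) {
          if (rt.parent < 0)
            Rcpp::stop("internal error: missing parent for unresolved content");
          double dt = ntime[rt.parent] - ntime[v];
          long long ql = iset_total(rt.q);
          std::vector<unsigned char> buf((size_t)ql);
          for_runs(domain[rt.parent], rt.q,
                   [&](long long poff, long long qoff, int, long long len) {
            const std::vector<unsigned char>& pc = content[rt.parent];
            for (long long x = 0; x < len; ++x) buf[qoff + x] = pc[poff + x];
          });
          jc_mutate(buf, 0.5 * theta * dt * (double)ql);
          for_runs(dom, rt.q,
                   [&](long long doff, long long qoff, int, long long len) {
            for (long long x = 0; x < len; ++x) cv[doff + x] = buf[qoff + x];
          });
        }
      }
    }
    // leaves: emit
    if (kind[v] == 0) {
      // leaf domain is exactly the sequence-bearing spans, in order
      for (long long x = 0; x < dl; ++x) out(v, (int)x) = cv[(size_t)x];
    }
    // free parents whose children are all done
    int pars[2] = { pcont[v], pdon[v] };
    for (int pi = 0; pi < 2; ++pi) {
      int P = pars[pi];
      if (P >= 0 && --pending[P] == 0) {
        content[P].clear();
        content[P].shrink_to_fit();
      }
    }
  }
  return out;
}
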