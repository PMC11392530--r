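// Sequential coalescent (SMC') simulator with finite-site multi-marker
// mutation overlay. Trees are simulated left-to-right along the sequence:
// an initial coalescent tree, then at each recombination event a branch is
// cut and the detached lineage re-coalesces into the standing genealogy
// (back-coalescence with the cut branch itself is a silent event leaving the
// marginal tree unchanged). Times are in generations; the pair coalescence
// rate in an epoch of size N is 1/(2N).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Demog {
  std::vector<double> bnd;  // epoch starts, first 0
  std::vector<double> N;
  int epoch_of(double t) const {
    int i = (int)bnd.size() - 1;
    while (i > 0 && bnd[i] > t) --i;
    return i;
  }
  double size_at(double t) const { return N[epoch_of(t)]; }
};

// Waiting time to the next coalescence from t0 when the total rate is
// m / (2 N(t)) with m constant (m = k(k-1)/2 for k active lineages).
double coal_wait(const Demog& d, double t0, double m) {
  double e = exp_rand();
  double t = t0;
  int i = d.epoch_of(t0);
  for (;;) {
    double end = (i + 1 < (int)d.bnd.size()) ? d.bnd[i + 1] : R_PosInf;
    double rate = m / (2.0 * d.N[i]);
    if (!R_finite(end)) return t + e / rate;
    double cap = (end - t) * rate;
    if (e <= cap) return t + e / rate;
    e -= cap;
    t = end;
    ++i;
  }
}

struct Tree {
  int n, root;
  std::vector<int> parent, child1, child2;
  std::vector<double> time;

  Tree(int n_) : n(n_), root(-1),
    parent(2 * n_ - 1, -1), child1(2 * n_ - 1, -1), child2(2 * n_ - 1, -1),
    time(2 * n_ - 1, 0.0) {}

  int n_nodes() const { return 2 * n - 1; }

  double total_length() const {
    double B = 0;
    for (int v = 0; v < n_nodes(); ++v)
      if (v != root) B += time[parent[v]] - time[v];
    return B;
  }

  bool crossing(int v, double s) const {
    if (time[v] > s) return false;
    if (v == root) return true;  // root lineage extends upward
    return time[parent[v]] > s;
  }

  int count_crossing(double s) const {
    int c = 0;
    for (int v = 0; v < n_nodes(); ++v) if (crossing(v, s)) ++c;
    return c;
  }

  // nodes in pre-order from the root (parents before children)
  void preorder(std::vector<int>& ord) const {
    ord.clear();
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ord.push_back(v);
      if (child1[v] >= 0) { stack.push_back(child1[v]); stack.push_back(child2[v]); }
    }
  }

  double tmrca(int a, int b) const {
    std::vector<char> anc(n_nodes(), 0);
    for (int v = a; v >= 0; v = parent[v]) anc[v] = 1;
    for (int v = b; v >= 0; v = parent[v]) if (anc[v]) return time[v];
    return time[root];
  }
};

void initial_tree(Tree& tr, const Demog& d) {
  int n = tr.n;
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0;
  int nxt = n;
  while ((int)active.size() > 1) {
    int k = (int)active.size();
    t = coal_wait(d, t, k * (k - 1) / 2.0);
    int a = (int)std::floor(unif_rand() * k);
    int b = (int)std::floor(unif_rand() * (k - 1));
    if (b >= a) ++b;
    int va = active[a], vb = active[b];
    tr.time[nxt] = t;
    tr.child1[nxt] = va; tr.child2[nxt] = vb;
    tr.parent[va] = nxt; tr.parent[vb] = nxt;
    if (a > b) std::swap(a, b);
    active[a] = nxt;
    active.erase(active.begin() + b);
    ++nxt;
  }
  tr.root = active[0];
  tr.parent[tr.root] = -1;
}

// One SMC' recombination event. Returns true if the marginal tree changed.
bool recombine(Tree& tr, const Demog& d) {
  // pick the cut point: branch with prob proportional to length, height uniform
  double B = tr.total_length();
  double x = unif_rand() * B;
  int v = -1;
  for (int w = 0; w < tr.n_nodes(); ++w) {
    if (w == tr.root) continue;
    double len = tr.time[tr.parent[w]] - tr.time[w];
    if (x < len) { v = w; break; }
    x -= len;
  }
  if (v < 0) v = (tr.root == 0) ? 1 : 0;  // numeric guard
  double u = tr.time[v] + unif_rand() * (tr.time[tr.parent[v]] - tr.time[v]);

  // re-coalescence time: competing exponential over piecewise-constant
  // (lineage count)/(2N) segments; breakpoints at node times and epoch starts
  std::vector<double> brk;
  for (int w = 0; w < tr.n_nodes(); ++w)
    if (tr.time[w] > u) brk.push_back(tr.time[w]);
  for (size_t i = 0; i < d.bnd.size(); ++i)
    if (d.bnd[i] > u) brk.push_back(d.bnd[i]);
  std::sort(brk.begin(), brk.end());
  brk.push_back(R_PosInf);

  double e = exp_rand();
  double s0 = u, s = -1;
  for (size_t j = 0; j < brk.size(); ++j) {
    double s1 = brk[j];
    int cnt = tr.count_crossing(s0 + (R_finite(s1) ? (s1 - s0) * 1e-9 : 1e-9));
    if (cnt < 1) cnt = 1;
    double rate = cnt / (2.0 * d.size_at(s0));
    if (R_finite(s1)) {
      double cap = (s1 - s0) * rate;
      if (e > cap) { e -= cap; s0 = s1; continue; }
    }
    s = s0 + e / rate;
    break;
  }

  // partner branch uniform among those crossing s
  int cnt = tr.count_crossing(s);
  int pick = (int)std::floor(unif_rand() * cnt);
  int c = -1;
  for (int w = 0; w < tr.n_nodes(); ++w) {
    if (tr.crossing(w, s)) {
      if (pick == 0) { c = w; break; }
      --pick;
    }
  }
  if (c == v) return false;  // back-coalescence: silent event

  int p = tr.parent[v];
  int w = (tr.child1[p] == v) ? tr.child2[p] : tr.child1[p];
  int g = tr.parent[p];
  if (c == p) c = w;  // the branch above p belongs to w once p is spliced out
  // splice p out
  tr.parent[w] = g;
  if (g >= 0) { if (tr.child1[g] == p) tr.child1[g] = w; else tr.child2[g] = w; }
  else tr.root = w;
  // re-insert p as the new coalescent node joining v and c at time s
  int gp = tr.parent[c];
  tr.parent[p] = gp;
  if (gp >= 0) { if (tr.child1[gp] == c) tr.child1[gp] = p; else tr.child2[gp] = p; }
  else tr.root = p;
  tr.child1[p] = v; tr.child2[p] = c;
  tr.parent[v] = p; tr.parent[c] = p;
  tr.time[p] = s;
  return true;
}

}  // namespace

// Full tree-sequence simulation: stores every marginal tree.
// [[Rcpp::export(name = ".sim_arg_full_cpp")]]
List sim_arg_full_cpp(int n, double L, double r,
                      NumericVector boundaries, NumericVector sizes) {
  if (n < 2) stop("need at least 2 haplotypes");
  if (L <= 0) stop("zero-length sequence");
  Demog d;
  d.bnd = as<std::vector<double> >(boundaries);
  d.N = as<std::vector<double> >(sizes);

  Tree tr(n);
  initial_tree(tr, d);

  std::vector<double> spans, tmrcas, times;
  std::vector<int> parents;
  long n_events = 0, n_silent = 0;

  double pos = 0, tree_start = 0;
  for (;;) {
    double B = tr.total_length();
    double dist = (r > 0) ? exp_rand() / (r * B) : R_PosInf;
    double nxt = pos + dist;
    bool at_end = (!R_finite(nxt) || nxt >= L);
    bool changed = false;
    if (!at_end) {
      ++n_events;
      // snapshot only if the event will change the tree; recombine mutates,
      // so test first on a copy of the decision: we snapshot lazily by
      // copying the tree, attempting the event, and emitting if changed.
      Tree before = tr;
      changed = recombine(tr, d);
      if (changed) {
        spans.push_back(nxt - tree_start);
        tmrcas.push_back(before.tmrca(0, 1));
        for (int v = 0; v < before.n_nodes(); ++v) {
          parents.push_back(before.parent[v]);
          times.push_back(before.time[v]);
        }
        tree_start = nxt;
      } else {
        ++n_silent;
      }
      pos = nxt;
      continue;
    }
    spans.push_back(L - tree_start);
    tmrcas.push_back(tr.tmrca(0, 1));
    for (int v = 0; v < tr.n_nodes(); ++v) {
      parents.push_back(tr.parent[v]);
      times.push_back(tr.time[v]);
    }
    break;
  }

  int ntree = (int)spans.size();
  int nn = 2 * n - 1;
  IntegerMatrix pm(nn, ntree);
  NumericMatrix tm(nn, ntree);
  for (int k = 0; k < ntree; ++k)
    for (int v = 0; v < nn; ++v) {
      pm(v, k) = parents[(size_t)k * nn + v];
      tm(v, k) = times[(size_t)k * nn + v];
    }
  return List::create(_["span"] = NumericVector(spans.begin(), spans.end()),
                      _["parent"] = pm, _["time"] = tm,
                      _["tmrca"] = NumericVector(tmrcas.begin(), tmrcas.end()),
                      _["n_events"] = (double)n_events,
                      _["n_silent"] = (double)n_silent);
}

namespace {

// ---- site-set descriptors -------------------------------------------------
// mode 0: periodic pattern: marker occupies residues `res` (sorted) of each
//         period of length P
// mode 1: complement of the sorted integer positions `excl`
// mode 2: exactly the sorted integer positions `incl`
struct SiteSet {
  int mode;
  int P;
  std::vector<int> res;
  const int* excl; int n_excl;
  const int* incl; int n_incl;

  // number of marker sites at positions < b (b >= 0)
  double count_before(double b) const {
    long bi = (long)std::ceil(b);
    if (bi <= 0) return 0;
    if (mode == 0) {
      long q = bi / P, rem = bi % P;
      long c = q * (long)res.size();
      for (size_t i = 0; i < res.size(); ++i) if (res[i] < rem) ++c;
      return (double)c;
    } else if (mode == 1) {
      long below = std::lower_bound(excl, excl + n_excl, (int)bi) - excl;
      return (double)(bi - below);
    } else {
      return (double)(std::lower_bound(incl, incl + n_incl, (int)bi) - incl);
    }
  }

  // position of the j-th marker site (0-based j)
  long jth(long j) const {
    if (mode == 0) {
      long q = j / (long)res.size(), rem = j % (long)res.size();
      return q * P + res[rem];
    } else if (mode == 1) {
      // binary search smallest p with (p+1 - #excl<=p) == j+1
      long lo = j, hi = j + n_excl;
      while (lo < hi) {
        long mid = (lo + hi) / 2;
        long below = std::lower_bound(excl, excl + n_excl, (int)(mid + 1)) - excl;
        if (mid + 1 - below >= j + 1) hi = mid; else lo = mid + 1;
      }
      return lo;
    } else {
      return incl[j];
    }
  }
};

SiteSet parse_siteset(List ss) {
  SiteSet s;
  s.mode = as<int>(ss["mode"]);
  s.P = 1; s.excl = s.incl = NULL; s.n_excl = s.n_incl = 0;
  if (s.mode == 0) {
    s.P = as<int>(ss["period"]);
    s.res = as<std::vector<int> >(ss["residues"]);
  } else if (s.mode == 1) {
    IntegerVector e = ss["exclude"];
    s.excl = e.begin(); s.n_excl = e.size();
  } else {
    IntegerVector e = ss["include"];
    s.incl = e.begin(); s.n_incl = e.size();
  }
  return s;
}

// symmetric endpoint transition: returns new state after duration len
int sym_endpoint(int state, int nbs, double mu, double len) {
  double pstay = 1.0 / nbs + (nbs - 1.0) / nbs *
    std::exp(-mu * len * nbs / (nbs - 1.0));
  if (unif_rand() < pstay) return state;
  int k = (int)std::floor(unif_rand() * (nbs - 1));
  return (k >= state) ? k + 1 : k;
}

// asymmetric (two-state) endpoint transition; state 0 = U, 1 = M
int asym_endpoint(int state, double mu_gain, double mu_loss, double len) {
  double lam = mu_gain + mu_loss;
  double pm = mu_gain / lam;
  double decay = std::exp(-lam * len);
  double p_m = (state == 1) ? pm + (1 - pm) * decay : pm * (1 - decay);
  return (unif_rand() < p_m) ? 1 : 0;
}

struct TreeView {
  // columns of the stored tree-sequence matrices
  const int* parent;
  const double* time;
  int nn, n;
  int root() const {
    for (int v = 0; v < nn; ++v) if (parent[v] < 0) return v;
    return nn - 1;
  }
};

void preorder_view(const TreeView& tv, std::vector<int>& ord) {
  // children lists
  std::vector<int> c1(tv.nn, -1), c2(tv.nn, -1);
  for (int v = 0; v < tv.nn; ++v) {
    int p = tv.parent[v];
    if (p >= 0) { if (c1[p] < 0) c1[p] = v; else c2[p] = v; }
  }
  ord.clear();
  std::vector<int> stack;
  stack.push_back(tv.root());
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    ord.push_back(v);
    if (c1[v] >= 0) { stack.push_back(c1[v]); stack.push_back(c2[v]); }
  }
}

}  // namespace

// Overlay finite-site mutations of one marker class onto a stored tree
// sequence. Returns polymorphic positions and their leaf states (all sites
// if keep_monomorphic); ancestral states are drawn from the stationary
// distribution of the marker's chain.
// [[Rcpp::export(name = ".overlay_marker_cpp")]]
List overlay_marker_cpp(List arg, List siteset, String model,
                        double mu, int nbs, double mu_gain, double mu_loss,
                        bool keep_monomorphic = false) {
  NumericVector span = arg["span"];
  IntegerMatrix pm = arg["parent"];
  NumericMatrix tm = arg["time"];
  int nn = pm.nrow(), ntree = pm.ncol();
  int n = (nn + 1) / 2;
  SiteSet ss = parse_siteset(siteset);
  bool symmetric = (model == "symmetric");

  std::vector<int> out_pos;
  std::vector<int> out_states;  // column-major: site-major blocks of n
  double x0 = 0;

  std::vector<int> ord;
  std::vector<double> blen(nn);
  std::vector<int> state(nn);

  for (int k = 0; k < ntree; ++k) {
    TreeView tv; tv.parent = &pm(0, k); tv.time = &tm(0, k); tv.nn = nn; tv.n = n;
    double x1 = x0 + span[k];
    double c0 = ss.count_before(x0), c1 = ss.count_before(x1);
    long cnt = (long)(c1 - c0);
    if (cnt > 0) {
      preorder_view(tv, ord);
      double B = 0;
      for (int v = 0; v < nn; ++v) {
        int p = tv.parent[v];
        blen[v] = (p >= 0) ? tv.time[p] - tv.time[v] : 0;
        B += blen[v];
      }
      double rate_site = symmetric ? mu : (mu_gain + mu_loss);
      bool dense = rate_site * B > 0.1;
      if (!dense && symmetric) {
        // sparse: Poisson number of events over (sites x branches)
        double lambda = mu * B * (double)cnt;
        int nev = (int)R::rpois(lambda);
        if (nev > 0) {
          // events grouped per site: (site index local, node, height)
          std::map<long, std::vector<std::pair<double, int> > > by_site;
          for (int e = 0; e < nev; ++e) {
            long j = (long)std::floor(unif_rand() * cnt);
            double xb = unif_rand() * B;
            int v = 0;
            for (int w = 0; w < nn; ++w) { if (xb < blen[w]) { v = w; break; } xb -= blen[w]; }
            double h = tv.time[v] + unif_rand() * blen[v];
            by_site[j].push_back(std::make_pair(h, v));
          }
          for (std::map<long, std::vector<std::pair<double, int> > >::iterator
                 it = by_site.begin(); it != by_site.end(); ++it) {
            long posj = ss.jth((long)c0 + it->first);
            std::vector<std::pair<double, int> >& ev = it->second;
            // resolve leaf states: ancestral uniform; walk pre-order applying
            // this site's events on each branch in decreasing height order
            int anc = (int)std::floor(unif_rand() * nbs);
            std::sort(ev.begin(), ev.end());  // ascending height
            for (size_t q = 0; q < ord.size(); ++q) {
              int v = ord[q];
              int p = tv.parent[v];
              int st = (p < 0) ? anc : state[p];
              if (p >= 0) {
                // events on branch v, from high to low
                for (int e = (int)ev.size() - 1; e >= 0; --e) {
                  if (ev[e].second == v) {
                    int kk = (int)std::floor(unif_rand() * (nbs - 1));
                    st = (kk >= st) ? kk + 1 : kk;
                  }
                }
              }
              state[v] = st;
            }
            bool poly = false;
            for (int i = 1; i < n; ++i) if (state[i] != state[0]) { poly = true; break; }
            if (poly || keep_monomorphic) {
              out_pos.push_back((int)posj);
              for (int i = 0; i < n; ++i) out_states.push_back(state[i]);
            }
          }
        }
        // note: in sparse mode, monomorphic sites without any event are not
        // returned even with keep_monomorphic; the R wrapper fills them from
        // the stationary distribution when a full site table is requested
      } else {
        // dense: endpoint sampling per site per branch
        for (long j = 0; j < cnt; ++j) {
          long posj = ss.jth((long)c0 + j);
          int anc;
          if (symmetric) anc = (int)std::floor(unif_rand() * nbs);
          else anc = (unif_rand() < mu_gain / (mu_gain + mu_loss)) ? 1 : 0;
          for (size_t q = 0; q < ord.size(); ++q) {
            int v = ord[q];
            int p = tv.parent[v];
            if (p < 0) { state[v] = anc; continue; }
            int st = state[p];
            if (symmetric) st = sym_endpoint(st, nbs, mu, blen[v]);
            else st = asym_endpoint(st, mu_gain, mu_loss, blen[v]);
            state[v] = st;
          }
          bool poly = false;
          for (int i = 1; i < n; ++i) if (state[i] != state[0]) { poly = true; break; }
          if (poly || keep_monomorphic) {
            out_pos.push_back((int)posj);
            for (int i = 0; i < n; ++i) out_states.push_back(state[i]);
          }
        }
      }
    }
    x0 = x1;
  }

  int S = (int)out_pos.size();
  IntegerMatrix st(n, S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < n; ++i) st(i, j) = out_states[(size_t)j * n + i];
  double tot = ss.count_before(x0);
  return List::create(_["positions"] = IntegerVector(out_pos.begin(), out_pos.end()),
                      _["states"] = st, _["total_sites"] = tot);
}

// Methylome overlay: site-level asymmetric chain plus region-level process.
// If region rates are both zero each site evolves on its own local tree;
// otherwise all sites of a region use the genealogy at the region midpoint,
// region events reset every site in the region to the region's new status.
// [[Rcpp::export(name = ".overlay_methylome_cpp")]]
List overlay_methylome_cpp(List arg, IntegerVector site_pos,
                           IntegerVector site_region,  // 0-based region index
                           NumericVector region_mid,
                           double mu_sm, double mu_su,
                           double mu_rm, double mu_ru) {
  NumericVector span = arg["span"];
  IntegerMatrix pm = arg["parent"];
  NumericMatrix tm = arg["time"];
  int nn = pm.nrow(), ntree = pm.ncol();
  int n = (nn + 1) / 2;
  int S = site_pos.size();
  int R = region_mid.size();
  bool region_on = (mu_rm > 0 || mu_ru > 0);

  // tree index per genomic position
  std::vector<double> cum(ntree + 1, 0.0);
  for (int k = 0; k < ntree; ++k) cum[k + 1] = cum[k] + span[k];
  IntegerMatrix st(n, S);
  IntegerMatrix region_leaf(n, R);
  IntegerVector region_anc(R);
  std::fill(region_leaf.begin(), region_leaf.end(), NA_INTEGER);

  std::vector<int> ord;
  std::vector<int> state(nn), rstate(nn);

  if (!region_on) {
    int k = 0;
    for (int j = 0; j < S; ++j) {
      double p = site_pos[j] + 0.5;
      while (k + 1 < ntree && cum[k + 1] <= p) ++k;
      TreeView tv; tv.parent = &pm(0, k); tv.time = &tm(0, k); tv.nn = nn; tv.n = n;
      preorder_view(tv, ord);
      if (mu_sm == 0 && mu_su == 0) {
        // frozen: every haplotype carries the ancestral state
        int anc = (unif_rand() < 0.5) ? 1 : 0;  // no rates: arbitrary fair draw
        for (int i = 0; i < n; ++i) st(i, j) = anc;
        continue;
      }
      double pmstat = mu_sm / (mu_sm + mu_su);
      int anc = (unif_rand() < pmstat) ? 1 : 0;
      for (size_t q = 0; q < ord.size(); ++q) {
        int v = ord[q];
        int par = tv.parent[v];
        if (par < 0) { state[v] = anc; continue; }
        state[v] = asym_endpoint(state[par], mu_sm, mu_su, tv.time[par] - tv.time[v]);
      }
      for (int i = 0; i < n; ++i) st(i, j) = state[i];
    }
    return List::create(_["states"] = st, _["region_leaf"] = region_leaf,
                        _["region_anc"] = region_anc);
  }

  // region mode: per region, simulate region chain with explicit event times
  // on the midpoint tree, then run each site down the same tree
  for (int rg = 0; rg < R; ++rg) {
    double p = region_mid[rg];
    int k = (int)(std::upper_bound(cum.begin(), cum.end(), p) - cum.begin()) - 1;
    if (k < 0) k = 0;
    if (k >= ntree) k = ntree - 1;
    TreeView tv; tv.parent = &pm(0, k); tv.time = &tm(0, k); tv.nn = nn; tv.n = n;
    preorder_view(tv, ord);

    // region chain: events per branch as (height, new_status), height desc
    double pr_stat = mu_rm / (mu_rm + mu_ru);
    int ranc = (unif_rand() < pr_stat) ? 1 : 0;
    region_anc[rg] = ranc;
    std::vector<std::vector<std::pair<double, int> > > rev(nn);
    for (size_t q = 0; q < ord.size(); ++q) {
      int v = ord[q];
      int par = tv.parent[v];
      if (par < 0) { rstate[v] = ranc; continue; }
      int stt = rstate[par];
      double h = tv.time[par];          // walk forward in time = downward in h
      double hend = tv.time[v];
      for (;;) {
        double rate = (stt == 1) ? mu_ru : mu_rm;
        double wait = (rate > 0) ? exp_rand() / rate : R_PosInf;
        if (h - wait <= hend) break;
        h -= wait;
        stt = 1 - stt;
        rev[v].push_back(std::make_pair(h, stt));
      }
      rstate[v] = stt;
    }
    for (int i = 0; i < n; ++i) region_leaf(i, rg) = rstate[i];

    // sites of this region: merged site chain with resets at region events
    for (int j = 0; j < S; ++j) {
      if (site_region[j] != rg) continue;
      for (size_t q = 0; q < ord.size(); ++q) {
        int v = ord[q];
        int par = tv.parent[v];
        if (par < 0) { state[v] = ranc; continue; }  // ancestral site = region status
        int stt = state[par];
        double h = tv.time[par], hend = tv.time[v];
        const std::vector<std::pair<double, int> >& evs = rev[v];
        bool has_site = (mu_sm > 0 || mu_su > 0);
        for (size_t e = 0; e < evs.size(); ++e) {
          if (has_site) stt = asym_endpoint(stt, mu_sm, mu_su, h - evs[e].first);
          stt = evs[e].second;  // reset to the region's new status
          h = evs[e].first;
        }
        if (has_site) stt = asym_endpoint(stt, mu_sm, mu_su, h - hend);
        state[v] = stt;
      }
      for (int i = 0; i < n; ++i) st(i, j) = state[i];
    }
  }
  return List::create(_["states"] = st, _["region_leaf"] = region_leaf,
                      _["region_anc"] = region_anc);
}
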