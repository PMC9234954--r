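// Clock-driven leaky integrate-and-fire engine with delayed delta-current
// synapses, spike recording, and supervised parallel-fiber plasticity.
//
// Units: time ms, potentials mV. Synaptic weights are instantaneous membrane
// kicks in mV (inhibitory weights are negative). "Teaching" projections carry
// no current; their presynaptic (inferior olive) spikes gate depression at the
// plastic projection. Generator neurons (lif = FALSE) never integrate; their
// spikes are injected from R and propagated like any other spike.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

struct Proj {
  // pre-major CSR over unique presynaptic gids
  std::vector<int> pre_gids, pre_off;
  std::vector<int> post;        // target gid per edge (pre-major order)
  std::vector<double> w;        // weight per edge (pre-major order)
  std::vector<int> orig;        // original (R-side) edge index per pre-major edge
  std::vector<int> pre_of_edge; // pre gid per pre-major edge
  int delay_steps = 1;
  bool teaching = false, plastic = false;
  int n_edges = 0;
  // post-major view (built for the plastic projection only)
  std::vector<int> pm_post_gids, pm_off, pm_edge;
  // per-pre targets sorted by post gid (plastic only; for O(log) LTP lookup)
  std::vector<int> srt_post, srt_edge; // same CSR offsets as pre_off
};

struct Net {
  double dt = 0.1;
  long step = 0;
  int n = 0;
  bool finalized = false;

  std::vector<double> V, vrest, vinf, vreset, vth, decay;
  std::vector<char> lif;
  std::vector<long> refrac_until;
  std::vector<int> tref_steps;
  std::vector<std::string> pop_name;
  std::vector<int> pop_first, pop_size;

  std::vector<Proj> projs;
  std::vector<std::vector<std::array<int, 3>>> adj; // gid -> {proj, start, end}

  std::vector<std::vector<std::pair<int, double>>> ring;
  long ring_size = 1;

  std::vector<int> sp_gid;
  std::vector<double> sp_t;

  std::vector<std::pair<long, int>> inj; // (step, gid)
  size_t inj_pos = 0;
  bool inj_dirty = false;

  // plasticity (single plastic projection)
  int plastic_proj = -1;
  bool plast_on = false;
  double ltp = 0.01, ltd = -0.03, wmin = 0.0, wmax = 1.0;
  long coinc_steps = 50, win_steps = 3000;
  std::vector<double> klut; // kernel value by lag in steps, length win_steps+1
  std::vector<char> is_plastic_pre, is_io, is_pc;
  std::vector<long> last_pre_spike;
  std::vector<std::vector<long>> pre_hist;
  std::vector<int> pc_of_io, pm_index_of_gid;
  std::vector<std::vector<long>> io_steps_pc; // indexed by pc gid
  std::vector<int> lif_ids;                   // integrating neurons only
  std::vector<std::pair<long, int>> recent_pre; // (step, pre) of PF spikes
  size_t recent_head = 0;
  std::vector<int> pre_csr_of_gid; // gid -> index into plastic pre CSR
};

static Net* get(SEXP xp) {
  Rcpp::XPtr<Net> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP eng_create(double dt) {
  if (dt <= 0) stop("dt must be > 0");
  Net* net = new Net();
  net->dt = dt;
  return Rcpp::XPtr<Net>(net, true);
}

// [[Rcpp::export]]
int eng_add_population(SEXP xp, std::string name, int size, bool lif,
                       double tau_m, double v_rest, double v_thresh,
                       double v_reset, double t_ref, double bias_mv) {
  Net* net = get(xp);
  if (net->finalized) stop("network is finalized; cannot add populations");
  if (size < 1) stop("population size must be >= 1");
  if (tau_m <= 0) stop("membrane time constant must be > 0");
  if (v_thresh <= v_reset) stop("spike threshold must exceed reset potential");
  if (t_ref < 0) stop("refractory period must be >= 0");
  int first = net->n;
  net->pop_name.push_back(name);
  net->pop_first.push_back(first);
  net->pop_size.push_back(size);
  double dec = std::exp(-net->dt / tau_m);
  int trs = (int)std::lround(t_ref / net->dt);
  for (int i = 0; i < size; ++i) {
    net->V.push_back(v_rest);
    net->vrest.push_back(v_rest);
    net->vinf.push_back(v_rest + bias_mv);
    net->vreset.push_back(v_reset);
    net->vth.push_back(v_thresh);
    net->decay.push_back(dec);
    net->lif.push_back(lif ? 1 : 0);
    net->refrac_until.push_back(std::numeric_limits<long>::min());
    net->tref_steps.push_back(trs);
  }
  net->n += size;
  return first;
}

// [[Rcpp::export]]
int eng_add_projection(SEXP xp, IntegerVector pre, IntegerVector post,
                       NumericVector w, double delay_ms, bool teaching,
                       bool plastic) {
  Net* net = get(xp);
  if (net->finalized) stop("network is finalized; cannot add projections");
  int ne = pre.size();
  if (post.size() != ne || w.size() != ne) stop("edge vectors must have equal length");
  int ds = (int)std::lround(delay_ms / net->dt);
  if (ds < 1) stop("projection delay must be >= the simulation step");
  Proj p;
  p.delay_steps = ds;
  p.teaching = teaching;
  p.plastic = plastic;
  p.n_edges = ne;
  // stable sort edge indices by pre gid
  std::vector<int> idx(ne);
  for (int i = 0; i < ne; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return pre[a] < pre[b]; });
  p.post.resize(ne);
  p.w.resize(ne);
  p.orig.resize(ne);
  p.pre_of_edge.resize(ne);
  int last = -1;
  for (int k = 0; k < ne; ++k) {
    int i = idx[k];
    int pg = pre[i];
    if (pg < 0 || pg >= net->n || post[i] < 0 || post[i] >= net->n)
      stop("edge references unknown neuron gid");
    if (pg != last) {
      p.pre_gids.push_back(pg);
      p.pre_off.push_back(k);
      last = pg;
    }
    p.post[k] = post[i];
    p.w[k] = w[i];
    p.orig[k] = i;
    p.pre_of_edge[k] = pg;
  }
  p.pre_off.push_back(ne);
  if (plastic) {
    if (net->plastic_proj >= 0) stop("only one plastic projection is supported");
    net->plastic_proj = (int)net->projs.size();
    // post-major index
    std::vector<int> pidx(ne);
    for (int i = 0; i < ne; ++i) pidx[i] = i;
    std::stable_sort(pidx.begin(), pidx.end(),
                     [&](int a, int b) { return p.post[a] < p.post[b]; });
    int lastp = -1;
    for (int k = 0; k < ne; ++k) {
      int e = pidx[k];
      if (p.post[e] != lastp) {
        p.pm_post_gids.push_back(p.post[e]);
        p.pm_off.push_back(k);
        lastp = p.post[e];
      }
      p.pm_edge.push_back(e);
    }
    p.pm_off.push_back(ne);
  }
  net->projs.push_back(std::move(p));
  return (int)net->projs.size() - 1;
}

// [[Rcpp::export]]
void eng_finalize(SEXP xp) {
  Net* net = get(xp);
  if (net->finalized) return;
  net->adj.assign(net->n, {});
  long maxd = 1;
  for (size_t pi = 0; pi < net->projs.size(); ++pi) {
    Proj& p = net->projs[pi];
    maxd = std::max(maxd, (long)p.delay_steps);
    for (size_t k = 0; k + 1 < p.pre_off.size(); ++k)
      net->adj[p.pre_gids[k]].push_back(
          {(int)pi, p.pre_off[k], p.pre_off[k + 1]});
  }
  net->ring_size = maxd + 2;
  net->ring.assign(net->ring_size, {});
  net->is_plastic_pre.assign(net->n, 0);
  net->is_io.assign(net->n, 0);
  net->is_pc.assign(net->n, 0);
  net->last_pre_spike.assign(net->n, std::numeric_limits<long>::min());
  net->pre_hist.assign(net->n, {});
  net->pc_of_io.assign(net->n, -1);
  net->pm_index_of_gid.assign(net->n, -1);
  net->io_steps_pc.assign(net->n, {});
  if (net->plastic_proj >= 0) {
    Proj& p = net->projs[net->plastic_proj];
    net->pre_csr_of_gid.assign(net->n, -1);
    for (size_t k = 0; k < p.pre_gids.size(); ++k) {
      net->is_plastic_pre[p.pre_gids[k]] = 1;
      net->pre_csr_of_gid[p.pre_gids[k]] = (int)k;
    }
    for (size_t k = 0; k < p.pm_post_gids.size(); ++k) {
      net->is_pc[p.pm_post_gids[k]] = 1;
      net->pm_index_of_gid[p.pm_post_gids[k]] = (int)k;
    }
    // per-pre target lists sorted by post gid
    p.srt_post.resize(p.n_edges);
    p.srt_edge.resize(p.n_edges);
    for (size_t k = 0; k + 1 < p.pre_off.size(); ++k) {
      int a = p.pre_off[k], b = p.pre_off[k + 1];
      std::vector<int> idx(b - a);
      for (int i = 0; i < b - a; ++i) idx[i] = a + i;
      std::sort(idx.begin(), idx.end(),
                [&](int x, int y) { return p.post[x] < p.post[y]; });
      for (int i = 0; i < b - a; ++i) {
        p.srt_post[a + i] = p.post[idx[i]];
        p.srt_edge[a + i] = idx[i];
      }
    }
  }
  for (int g = 0; g < net->n; ++g)
    if (net->lif[g]) net->lif_ids.push_back(g);
  net->finalized = true;
}

// [[Rcpp::export]]
void eng_set_plasticity(SEXP xp, double ltp, double ltd, double wmin,
                        double wmax, NumericVector kernel_lut,
                        double coincidence_ms, bool enabled) {
  Net* net = get(xp);
  if (net->plastic_proj < 0) stop("no plastic projection in the network");
  if (wmin < 0 || wmax <= wmin) stop("need 0 <= weight_min < weight_max");
  net->ltp = ltp;
  net->ltd = ltd;
  net->wmin = wmin;
  net->wmax = wmax;
  net->coinc_steps = (long)std::lround(coincidence_ms / net->dt);
  net->klut.assign(kernel_lut.begin(), kernel_lut.end());
  net->win_steps = (long)net->klut.size() - 1;
  net->plast_on = enabled;
}

// [[Rcpp::export]]
void eng_plasticity_enabled(SEXP xp, bool enabled) {
  get(xp)->plast_on = enabled;
}

// [[Rcpp::export]]
void eng_set_io_map(SEXP xp, IntegerVector io_gids, IntegerVector pc_gids) {
  Net* net = get(xp);
  if (!net->finalized) stop("finalize the network first");
  if (io_gids.size() != pc_gids.size()) stop("io/pc gid vectors differ in length");
  for (int i = 0; i < io_gids.size(); ++i) {
    net->is_io[io_gids[i]] = 1;
    net->pc_of_io[io_gids[i]] = pc_gids[i];
  }
}

// [[Rcpp::export]]
void eng_inject(SEXP xp, IntegerVector gids, NumericVector times_ms) {
  Net* net = get(xp);
  if (gids.size() != times_ms.size()) stop("gid/time vectors differ in length");
  for (int i = 0; i < gids.size(); ++i) {
    long s = (long)std::lround(times_ms[i] / net->dt);
    if (s <= net->step) s = net->step + 1;
    net->inj.push_back({s, gids[i]});
  }
  net->inj_dirty = true;
}

static inline double clipw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

static void do_plasticity(Net* net, int pc, long s) {
  Proj& p = net->projs[net->plastic_proj];
  int k = net->pm_index_of_gid[pc];
  if (k < 0) return;
  int a = p.pm_off[k], b = p.pm_off[k + 1];
  bool coinc = false;
  std::vector<long>& ios = net->io_steps_pc[pc];
  for (auto it = ios.rbegin(); it != ios.rend(); ++it) {
    if (s - *it > net->coinc_steps) break;
    coinc = true;
    break;
  }
  if (coinc) {
    for (int i = a; i < b; ++i) {
      int e = p.pm_edge[i];
      int pre = p.pre_of_edge[e];
      std::vector<long>& h = net->pre_hist[pre];
      double ks = 0.0;
      for (auto it = h.rbegin(); it != h.rend(); ++it) {
        long lag = s - *it;
        if (lag > net->win_steps) break;
        if (lag >= 0) ks += net->klut[lag];
      }
      if (ks > 0)
        p.w[e] = clipw(p.w[e] + net->ltd * ks, net->wmin, net->wmax);
    }
  } else {
    // scan only PFs active within the coincidence window (equivalent to the
    // full per-synapse scan: each active pre is applied once, at its latest
    // spike entry)
    while (net->recent_head < net->recent_pre.size() &&
           net->recent_pre[net->recent_head].first < s - net->coinc_steps)
      ++net->recent_head;
    if (net->recent_head > 65536) {
      net->recent_pre.erase(net->recent_pre.begin(),
                            net->recent_pre.begin() + net->recent_head);
      net->recent_head = 0;
    }
    for (size_t r = net->recent_head; r < net->recent_pre.size(); ++r) {
      int pre = net->recent_pre[r].second;
      if (net->last_pre_spike[pre] != net->recent_pre[r].first)
        continue; // superseded entry for this PF
      int k2 = net->pre_csr_of_gid[pre];
      int a2 = p.pre_off[k2], b2 = p.pre_off[k2 + 1];
      const int* lo = p.srt_post.data() + a2;
      const int* hi = p.srt_post.data() + b2;
      const int* it = std::lower_bound(lo, hi, pc);
      for (; it != hi && *it == pc; ++it) {
        int e = p.srt_edge[a2 + (int)(it - lo)];
        p.w[e] = clipw(p.w[e] + net->ltp, net->wmin, net->wmax);
      }
    }
  }
}

static void emit(Net* net, int g, long s) {
  net->sp_gid.push_back(g);
  net->sp_t.push_back(s * net->dt);
  if (net->is_plastic_pre[g]) {
    net->last_pre_spike[g] = s;
    net->recent_pre.push_back({s, g});
    std::vector<long>& h = net->pre_hist[g];
    h.push_back(s);
    while (!h.empty() && s - h.front() > net->win_steps) h.erase(h.begin());
  }
  if (net->is_io[g]) {
    int pc = net->pc_of_io[g];
    if (pc >= 0) net->io_steps_pc[pc].push_back(s);
  }
  if (net->plast_on && net->is_pc[g]) do_plasticity(net, g, s);
  for (auto& e : net->adj[g]) {
    Proj& p = net->projs[e[0]];
    if (p.teaching) continue;
    long slot = (s + p.delay_steps) % net->ring_size;
    for (int i = e[1]; i < e[2]; ++i)
      net->ring[slot].push_back({p.post[i], p.w[i]});
  }
}

// [[Rcpp::export]]
void eng_run(SEXP xp, double t_stop_ms) {
  Net* net = get(xp);
  if (!net->finalized) stop("finalize the network first");
  long target = (long)std::lround(t_stop_ms / net->dt);
  if (net->inj_dirty) {
    net->inj.erase(net->inj.begin(), net->inj.begin() + net->inj_pos);
    std::stable_sort(net->inj.begin(), net->inj.end(),
                     [](const std::pair<long, int>& a,
                        const std::pair<long, int>& b) { return a.first < b.first; });
    net->inj_pos = 0;
    net->inj_dirty = false;
  }
  int n = net->n;
  while (net->step < target) {
    long s = ++net->step;
    while (net->inj_pos < net->inj.size() && net->inj[net->inj_pos].first == s) {
      emit(net, net->inj[net->inj_pos].second, s);
      ++net->inj_pos;
    }
    // leak (exact exponential toward vinf)
    for (int g : net->lif_ids) {
      if (s < net->refrac_until[g])
        net->V[g] = net->vreset[g];
      else
        net->V[g] = net->vinf[g] + (net->V[g] - net->vinf[g]) * net->decay[g];
    }
    // delayed synaptic deliveries
    long slot = s % net->ring_size;
    for (auto& pr : net->ring[slot]) {
      int g = pr.first;
      if (net->lif[g] && s >= net->refrac_until[g]) net->V[g] += pr.second;
    }
    net->ring[slot].clear();
    // thresholds
    for (int g : net->lif_ids) {
      if (s < net->refrac_until[g]) continue;
      if (!std::isfinite(net->V[g]))
        stop("non-finite membrane potential in neuron gid %d", g);
      if (net->V[g] >= net->vth[g]) {
        emit(net, g, s);
        net->V[g] = net->vreset[g];
        net->refrac_until[g] = s + net->tref_steps[g] + 1;
      }
    }
  }
}

// [[Rcpp::export]]
List eng_spikes(SEXP xp, bool clear) {
  Net* net = get(xp);
  List out = List::create(_["gid"] = IntegerVector(net->sp_gid.begin(), net->sp_gid.end()),
                          _["time"] = NumericVector(net->sp_t.begin(), net->sp_t.end()));
  if (clear) {
    net->sp_gid.clear();
    net->sp_t.clear();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector eng_weights(SEXP xp, int proj) {
  Net* net = get(xp);
  Proj& p = net->projs[proj];
  NumericVector out(p.n_edges);
  for (int i = 0; i < p.n_edges; ++i) out[p.orig[i]] = p.w[i];
  return out;
}

// [[Rcpp::export]]
void eng_set_weights(SEXP xp, int proj, NumericVector w) {
  Net* net = get(xp);
  Proj& p = net->projs[proj];
  if (w.size() != p.n_edges) stop("weight vector length mismatch");
  for (int i = 0; i < p.n_edges; ++i) p.w[i] = w[p.orig[i]];
}

// [[Rcpp::export]]
void eng_reset(SEXP xp) {
  Net* net = get(xp);
  net->step = 0;
  for (int g = 0; g < net->n; ++g) {
    net->V[g] = net->vrest[g];
    net->refrac_until[g] = std::numeric_limits<long>::min();
  }
  for (auto& r : net->ring) r.clear();
  net->inj.clear();
  net->inj_pos = 0;
  net->inj_dirty = false;
  net->sp_gid.clear();
  net->sp_t.clear();
  if (net->finalized) {
    std::fill(net->last_pre_spike.begin(), net->last_pre_spike.end(),
              std::numeric_limits<long>::min());
    for (auto& h : net->pre_hist) h.clear();
    for (auto& v : net->io_steps_pc) v.clear();
    net->recent_pre.clear();
    net->recent_head = 0;
  }
}

// [[Rcpp::export]]
void eng_set_V(SEXP xp, IntegerVector gids, NumericVector v) {
  Net* net = get(xp);
  if (gids.size() != v.size()) stop("gid/value vectors differ in length");
  for (int i = 0; i < gids.size(); ++i) net->V[gids[i]] = v[i];
}

// [[Rcpp::export]]
NumericVector eng_get_V(SEXP xp, IntegerVector gids) {
  Net* net = get(xp);
  NumericVector out(gids.size());
  for (int i = 0; i < gids.size(); ++i) out[i] = net->V[gids[i]];
  return out;
}

// [[Rcpp::export]]
double eng_time(SEXP xp) {
  Net* net = get(xp);
  return net->step * net->dt;
}

// [[Rcpp::export]]
int eng_n_neurons(SEXP xp) { return get(xp)->n; }

// [[Rcpp::export]]
List eng_proj_info(SEXP xp, int proj) {
  Net* net = get(xp);
  Proj& p = net->projs[proj];
  return List::create(_["n_edges"] = p.n_edges,
                      _["delay_ms"] = p.delay_steps * net->dt,
                      _["teaching"] = p.teaching, _["plastic"] = p.plastic);
}
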