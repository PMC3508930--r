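// Coalescent MCMC for population split times on Y-STR data under the
// single-step stepwise mutation model (SMM).
//
// Likelihood: Felsenstein pruning per locus on a truncated integer repeat
// lattice. The displacement kernel along a branch of length t generations is
// P(d | t) = exp(-mu t) I_|d|(mu t) (modified Bessel function of the first
// kind), truncated at |d| <= kmax steps. The root state is uniform over the
// lattice.
//
// Prior: structured coalescent under a ranked population-merge schedule with
// a single effective size N shared by all branches (constant size), split
// times uniform (root on (0, tau_max), each child on (0, parent)), gamma
// prior on the per-locus mutation rate, lognormal prior on N.
//
// Moves: internal node time slides, fixed-height subtree re-attachment (SPR
// with identical forward/reverse candidate sets, Hastings 1), split-time
// window moves, multiplicative mutation-rate and size moves, and (for >2
// demes) ranked-topology refresh proposals. Conditional likelihood vectors
// are cached per node and only the changed root-ward path is recomputed.

#include <Rcpp.h>
#include <Rmath.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double bessel_kernel(double theta, int d) {
  if (theta <= 0.0) return d == 0 ? 1.0 : 0.0;
  // exponentially scaled: I_d(theta) * exp(-theta)
  return ::Rf_bessel_i(theta, (double)d, 2.0);
}

struct Lattice {
  std::vector<int> lo;   // per-locus lattice lower bound
  std::vector<int> S;    // per-locus lattice size
  int Smax = 0;
};

struct PopSchedule {
  // ranked merge schedule over cluster ids: initial clusters 0..D-1,
  // merge j creates cluster D+j at time tau[j] (tau ascending)
  int D = 0;
  std::vector<std::pair<int, int>> merges;
  std::vector<double> tau;                 // generations, ascending
  std::vector<std::vector<double>> mergeTime;  // deme x deme join time

  void refresh_merge_times() {
    mergeTime.assign(D, std::vector<double>(D, 0.0));
    // cluster membership per deme over the schedule
    std::vector<int> cl(D);
    for (int d = 0; d < D; ++d) cl[d] = d;
    for (size_t j = 0; j < merges.size(); ++j) {
      int a = merges[j].first, b = merges[j].second, neu = D + (int)j;
      for (int d1 = 0; d1 < D; ++d1)
        for (int d2 = 0; d2 < D; ++d2)
          if (d1 != d2 && ((cl[d1] == a && cl[d2] == b) ||
                           (cl[d1] == b && cl[d2] == a)))
            mergeTime[d1][d2] = tau[j];
      for (int d = 0; d < D; ++d)
        if (cl[d] == a || cl[d] == b) cl[d] = neu;
    }
  }

  int cluster_at(int deme, double t) const {
    int cl = deme;
    for (size_t j = 0; j < merges.size(); ++j) {
      if (tau[j] > t) break;
      if (cl == merges[j].first || cl == merges[j].second) cl = D + (int)j;
    }
    return cl;
  }

  std::string topo_string(const std::vector<std::string>& names) const {
    // canonical nested-set labels
    std::vector<std::string> lab(D + merges.size());
    for (int d = 0; d < D; ++d) lab[d] = names[d];
    std::string out;
    for (size_t j = 0; j < merges.size(); ++j) {
      std::string a = lab[merges[j].first], b = lab[merges[j].second];
      if (b < a) std::swap(a, b);
      lab[D + j] = "(" + a + "," + b + ")";
    }
    return merges.empty() ? (D == 1 ? names[0] : std::string("")) :
      lab[D + merges.size() - 1];
  }
};

struct State {
  int n, L, nnode, root, D;
  std::vector<int> par, c1, c2, repdeme;
  std::vector<double> tm;       // node times, generations (tips at 0)
  IntegerMatrix alleles;        // n x L
  Lattice lat;
  int kmax;
  double mu, N;
  PopSchedule sched;
  // cached conditionals
  std::vector<double> condL;    // [node][locus][state]
  std::vector<double> scal;     // [node][locus]
  double cur_loglik = 0.0, cur_logprior = 0.0;

  inline double* cl(int v, int l) { return &condL[((size_t)v * L + l) * lat.Smax]; }
  inline double& sc(int v, int l) { return scal[(size_t)v * L + l]; }

  double minvalid(int v) const {
    int d1 = repdeme[c1[v]], d2 = repdeme[c2[v]];
    if (d1 == d2) return 0.0;
    return sched.mergeTime[d1][d2];
  }

  void init_tips() {
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        double* p = cl(i, l);
        std::fill(p, p + lat.Smax, 0.0);
        p[alleles(i, l) - lat.lo[l]] = 1.0;
        sc(i, l) = 0.0;
      }
    }
  }

  // recompute conditional vectors of node v from its children
  void recompute_node(int v) {
    int ch[2] = {c1[v], c2[v]};
    std::vector<double> ker(2 * (kmax + 1));
    int keff[2] = {0, 0};
    for (int c = 0; c < 2; ++c) {
      double theta = mu * (tm[v] - tm[ch[c]]);
      double* kv = &ker[c * (kmax + 1)];
      for (int d = 0; d <= kmax; ++d) kv[d] = bessel_kernel(theta, d);
      // drop the negligible kernel tail (short branches have tiny support)
      int K = kmax;
      while (K > 0 && kv[K] < 1e-14) --K;
      keff[c] = K;
    }
    for (int l = 0; l < L; ++l) {
      double* out = cl(v, l);
      int S = lat.S[l];
      std::vector<double> tmp(S, 1.0);
      double scadd = 0.0;
      for (int c = 0; c < 2; ++c) {
        int u = ch[c];
        const double* kv = &ker[c * (kmax + 1)];
        int K = std::min(keff[c], S - 1);
        const double* cu = cl(u, l);
        for (int s = 0; s < S; ++s) {
          double acc = 0.0;
          int dlo = std::max(-K, -s), dhi = std::min(K, S - 1 - s);
          for (int d = dlo; d <= dhi; ++d)
            acc += kv[d < 0 ? -d : d] * cu[s + d];
          tmp[s] *= acc;
        }
        scadd += sc(u, l);
      }
      double mx = 0.0;
      for (int s = 0; s < S; ++s) if (tmp[s] > mx) mx = tmp[s];
      if (mx <= 0.0) mx = 1e-300;
      for (int s = 0; s < S; ++s) out[s] = tmp[s] / mx;
      for (int s = S; s < lat.Smax; ++s) out[s] = 0.0;
      sc(v, l) = scadd + std::log(mx);
    }
  }

  double loglik_from_root() {
    double ll = 0.0;
    for (int l = 0; l < L; ++l) {
      const double* r = cl(root, l);
      double s = 0.0;
      for (int i = 0; i < lat.S[l]; ++i) s += r[i];
      ll += std::log(s / lat.S[l]) + sc(root, l);
    }
    return ll;
  }

  bool genealogy_valid() const {
    for (int v = n; v < nnode; ++v) {
      if (tm[v] < minvalid(v) - 1e-12) return false;
      if (tm[v] <= std::max(tm[c1[v]], tm[c2[v]]) - 1e-12) return false;
    }
    return true;
  }

  // structured coalescent log density of the genealogy + parameter priors
  double logprior(double mu_mean, double mu_shape, double logN_mean,
                  double logN_sd, double tau_max) const {
    // parameter priors
    double lp = R::dgamma(mu, mu_shape, mu_mean / mu_shape, 1);
    lp += R::dlnorm(N, logN_mean, logN_sd, 1);
    // split-time priors: ranked uniforms. Root on (0, tau_max); each earlier
    // split uniform on (0, next). (For independent merges this is the density
    // of the ranked representation.)
    int M = (int)sched.tau.size();
    for (int j = 0; j < M; ++j) {
      double hi = (j == M - 1) ? tau_max : sched.tau[j + 1];
      if (sched.tau[j] <= 0 || sched.tau[j] >= hi) return -INFINITY;
      lp += -std::log(hi);
    }
    // genealogy density
    std::vector<int> ord(nnode - n);
    for (int v = n; v < nnode; ++v) ord[v - n] = v;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return tm[a] < tm[b]; });
    int ncl = D + M;
    std::vector<int> k(ncl, 0);
    for (int i = 0; i < n; ++i) k[repdeme[i]]++;
    double t_now = 0.0;
    size_t mi = 0, ci = 0;
    auto interval_rate = [&]() {
      double r = 0.0;
      for (int c = 0; c < ncl; ++c)
        if (k[c] >= 2) r += k[c] * (k[c] - 1) / 2.0;
      return r / N;
    };
    while (ci < ord.size()) {
      double t_next_merge = (mi < sched.tau.size()) ? sched.tau[mi] : INFINITY;
      double t_next_coal = tm[ord[ci]];
      if (t_next_merge < t_next_coal) {
        lp += -interval_rate() * (t_next_merge - t_now);
        int a = sched.merges[mi].first, b = sched.merges[mi].second;
        k[D + (int)mi] = k[a] + k[b];
        k[a] = k[b] = 0;
        t_now = t_next_merge;
        ++mi;
      } else {
        int v = ord[ci];
        lp += -interval_rate() * (t_next_coal - t_now);
        int c = sched.cluster_at(repdeme[v], t_next_coal);
        if (k[c] < 2) return -INFINITY;
        lp += -std::log(N);
        k[c] -= 1;
        t_now = t_next_coal;
        ++ci;
      }
    }
    return lp;
  }
};

// collect strictly-ascending ancestors of v (including v), sorted by time
static std::vector<int> path_to_root(const State& st, int v) {
  std::vector<int> out;
  while (v != -1) {
    out.push_back(v);
    v = st.par[v];
  }
  return out;  // already child-before-parent
}

static int unif_int(int n) {
  int i = (int)std::floor(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// [[Rcpp::export]]
double smm_loglik_cpp(IntegerMatrix alleles, IntegerVector parent,
                      IntegerVector child1, IntegerVector child2,
                      NumericVector times, double mu, int pad = 8,
                      int kmax = 15) {
  State st;
  st.alleles = alleles;
  st.n = alleles.nrow();
  st.L = alleles.ncol();
  st.nnode = 2 * st.n - 1;
  st.kmax = kmax;
  st.mu = mu;
  st.par.assign(parent.begin(), parent.end());
  st.c1.assign(child1.begin(), child1.end());
  st.c2.assign(child2.begin(), child2.end());
  st.tm.assign(times.begin(), times.end());
  st.root = -1;
  for (int v = 0; v < st.nnode; ++v) if (st.par[v] == -1) st.root = v;
  st.lat.lo.resize(st.L);
  st.lat.S.resize(st.L);
  for (int l = 0; l < st.L; ++l) {
    int mn = alleles(0, l), mx = alleles(0, l);
    for (int i = 1; i < st.n; ++i) {
      mn = std::min(mn, alleles(i, l));
      mx = std::max(mx, alleles(i, l));
    }
    st.lat.lo[l] = mn - pad;
    st.lat.S[l] = mx - mn + 2 * pad + 1;
    st.lat.Smax = std::max(st.lat.Smax, st.lat.S[l]);
  }
  st.condL.assign((size_t)st.nnode * st.L * st.lat.Smax, 0.0);
  st.scal.assign((size_t)st.nnode * st.L, 0.0);
  st.init_tips();
  std::vector<int> ord;
  for (int v = st.n; v < st.nnode; ++v) ord.push_back(v);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return st.tm[a] < st.tm[b]; });
  for (int v : ord) st.recompute_node(v);
  return st.loglik_from_root();
}

struct Backup {
  std::vector<int> nodes;
  std::vector<double> condL, scal, times;
  std::vector<int> par, c1, c2;
};

static void save_nodes(State& st, const std::vector<int>& nodes, Backup& bk) {
  bk.nodes = nodes;
  size_t sl = (size_t)st.L * st.lat.Smax;
  bk.condL.resize(nodes.size() * sl);
  bk.scal.resize(nodes.size() * st.L);
  for (size_t i = 0; i < nodes.size(); ++i) {
    std::copy(st.cl(nodes[i], 0), st.cl(nodes[i], 0) + sl,
              &bk.condL[i * sl]);
    std::copy(&st.scal[(size_t)nodes[i] * st.L],
              &st.scal[(size_t)nodes[i] * st.L] + st.L,
              &bk.scal[i * (size_t)st.L]);
  }
}

static void restore_nodes(State& st, const Backup& bk) {
  size_t sl = (size_t)st.L * st.lat.Smax;
  for (size_t i = 0; i < bk.nodes.size(); ++i) {
    std::copy(&bk.condL[i * sl], &bk.condL[i * sl] + sl,
              st.cl(bk.nodes[i], 0));
    std::copy(&bk.scal[i * (size_t)st.L],
              &bk.scal[i * (size_t)st.L] + st.L,
              &st.scal[(size_t)bk.nodes[i] * st.L]);
  }
}

// [[Rcpp::export]]
List run_split_mcmc(IntegerMatrix alleles, IntegerVector deme,
                    CharacterVector deme_names, List prior, List chain,
                    IntegerMatrix init_merges, NumericVector init_tau,
                    int pad = 8, int kmax = 15) {
  State st;
  st.alleles = alleles;
  st.n = alleles.nrow();
  st.L = alleles.ncol();
  st.nnode = 2 * st.n - 1;
  st.kmax = kmax;
  st.D = deme_names.size();

  double mu_mean = prior["mu_mean"], mu_shape = prior["mu_shape"];
  double logN_mean = prior["logN_mean"], logN_sd = prior["logN_sd"];
  double tau_max = prior["tau_max_gen"];
  int n_iter = chain["samples"], burnin = chain["burnin"],
      thin = chain["thin"];

  st.mu = mu_mean;
  st.N = std::exp(logN_mean);

  // schedule
  st.sched.D = st.D;
  for (int j = 0; j < init_merges.nrow(); ++j)
    st.sched.merges.push_back({init_merges(j, 0), init_merges(j, 1)});
  st.sched.tau.assign(init_tau.begin(), init_tau.end());
  st.sched.refresh_merge_times();

  // lattice
  st.lat.lo.resize(st.L);
  st.lat.S.resize(st.L);
  for (int l = 0; l < st.L; ++l) {
    int mn = alleles(0, l), mx = alleles(0, l);
    for (int i = 1; i < st.n; ++i) {
      mn = std::min(mn, alleles(i, l));
      mx = std::max(mx, alleles(i, l));
    }
    st.lat.lo[l] = mn - pad;
    st.lat.S[l] = mx - mn + 2 * pad + 1;
    st.lat.Smax = std::max(st.lat.Smax, st.lat.S[l]);
  }

  // initial genealogy: average-linkage (UPGMA-style) clustering on mean
  // squared repeat differences, with pair times from the stepwise moment
  // estimate t = ASD / (4 mu); cross-population joins are floored at the
  // relevant merge time. Starting from a distance-consistent tree puts
  // burn-in close to the posterior mass.
  st.par.assign(st.nnode, -1);
  st.c1.assign(st.nnode, -1);
  st.c2.assign(st.nnode, -1);
  st.tm.assign(st.nnode, 0.0);
  st.repdeme.assign(st.nnode, 0);
  for (int i = 0; i < st.n; ++i) st.repdeme[i] = deme[i];
  {
    std::vector<int> act;                  // active cluster -> node id
    std::vector<int> csize;
    for (int i = 0; i < st.n; ++i) { act.push_back(i); csize.push_back(1); }
    // average squared distance between clusters
    std::vector<std::vector<double>> Dm(st.n, std::vector<double>(st.n, 0.0));
    for (int i = 0; i < st.n; ++i)
      for (int j = i + 1; j < st.n; ++j) {
        double s2 = 0.0;
        for (int l = 0; l < st.L; ++l) {
          double d = alleles(i, l) - alleles(j, l);
          s2 += d * d;
        }
        Dm[i][j] = Dm[j][i] = s2 / st.L;
      }
    int nxt = st.n;
    while ((int)act.size() > 1) {
      int bi = 0, bj = 1;
      double best = INFINITY;
      for (size_t i = 0; i < act.size(); ++i)
        for (size_t j = i + 1; j < act.size(); ++j) {
          double pen = Dm[i][j] / (4.0 * st.mu);
          double floorv = st.sched.mergeTime[st.repdeme[act[i]]]
                                            [st.repdeme[act[j]]];
          double t_est = std::max(pen, floorv);
          if (t_est < best) { best = t_est; bi = (int)i; bj = (int)j; }
        }
      int a = act[bi], b = act[bj];
      int v = nxt++;
      st.c1[v] = a; st.c2[v] = b;
      st.par[a] = st.par[b] = v;
      double floorv = st.sched.mergeTime[st.repdeme[a]][st.repdeme[b]];
      double tmin = std::max(std::max(st.tm[a], st.tm[b]), floorv);
      st.tm[v] = std::max(best, tmin * 1.0001 + 0.01);
      st.repdeme[v] = st.repdeme[a];
      // merge distance rows (size-weighted average linkage)
      int na = csize[bi], nb = csize[bj];
      for (size_t k2 = 0; k2 < act.size(); ++k2) {
        if ((int)k2 == bi || (int)k2 == bj) continue;
        Dm[bi][k2] = Dm[k2][bi] =
          (na * Dm[bi][k2] + nb * Dm[bj][k2]) / (na + nb);
      }
      act[bi] = v; csize[bi] = na + nb;
      act.erase(act.begin() + bj);
      csize.erase(csize.begin() + bj);
      for (auto& row : Dm) row.erase(row.begin() + bj);
      Dm.erase(Dm.begin() + bj);
    }
    st.root = act[0];
  }

  st.condL.assign((size_t)st.nnode * st.L * st.lat.Smax, 0.0);
  st.scal.assign((size_t)st.nnode * st.L, 0.0);
  st.init_tips();
  {
    std::vector<int> ord;
    for (int v = st.n; v < st.nnode; ++v) ord.push_back(v);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return st.tm[a] < st.tm[b]; });
    for (int v : ord) st.recompute_node(v);
  }
  st.cur_loglik = st.loglik_from_root();
  st.cur_logprior = st.logprior(mu_mean, mu_shape, logN_mean, logN_sd,
                                tau_max);

  int M = (int)st.sched.tau.size();
  int n_rec = 0;
  for (int it = burnin; it < n_iter; ++it) if ((it - burnin) % thin == 0) ++n_rec;
  NumericMatrix out_tau(n_rec, std::max(M, 1));
  NumericVector out_mu(n_rec), out_N(n_rec), out_lp(n_rec);
  CharacterVector out_topo(n_rec);
  std::vector<double> acc(7, 0.0), att(7, 1e-9);
  Backup bk;

  auto try_accept = [&](double d_lp) {
    return std::log(unif_rand()) < d_lp;
  };

  int rec = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- node time moves
    for (int rep = 0; rep < 3; ++rep) {
      int v = st.n + unif_int(st.nnode - st.n);
      double lo = std::max(std::max(st.tm[st.c1[v]], st.tm[st.c2[v]]),
                           st.minvalid(v));
      double logHR = 0.0, tnew;
      if (v == st.root) {
        double cur = st.tm[v] - lo;
        if (cur <= 0) cur = 1e-6;
        double fac = std::exp(0.8 * (unif_rand() - 0.5));
        tnew = lo + cur * fac;
        logHR = std::log(fac);
      } else {
        double hi = st.tm[st.par[v]];
        if (hi <= lo) continue;
        tnew = lo + unif_rand() * (hi - lo);
      }
      double told = st.tm[v];
      std::vector<int> dirty = path_to_root(st, v);
      save_nodes(st, dirty, bk);
      st.tm[v] = tnew;
      for (int u : dirty) st.recompute_node(u);
      double ll = st.loglik_from_root();
      double lp = st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max);
      att[0] += 1;
      if (R_finite(lp) &&
          try_accept(ll + lp - st.cur_loglik - st.cur_logprior + logHR)) {
        st.cur_loglik = ll; st.cur_logprior = lp; acc[0] += 1;
      } else {
        st.tm[v] = told;
        restore_nodes(st, bk);
      }
    }

    // --- SPR: re-attach a subtree at fixed height (several attempts per
    // sweep; topology mixing is the bottleneck in collapsed regimes)
    for (int spr_rep = 0; spr_rep < 3 && st.nnode - st.n >= 2; ++spr_rep) {
      int p = st.n + unif_int(st.nnode - st.n);
      if (p != st.root) {
        int u = (unif_rand() < 0.5) ? st.c1[p] : st.c2[p];
        int s = (u == st.c1[p]) ? st.c2[p] : st.c1[p];
        int gp = st.par[p];
        double tp = st.tm[p];
        // candidate attach edges in the detached state: x whose edge spans tp
        // (x != p and x not in subtree(u)); includes s (reverse move)
        std::vector<bool> in_sub(st.nnode, false);
        {
          std::vector<int> stack = {u};
          while (!stack.empty()) {
            int w = stack.back(); stack.pop_back();
            in_sub[w] = true;
            if (st.c1[w] != -1) { stack.push_back(st.c1[w]);
                                  stack.push_back(st.c2[w]); }
          }
        }
        std::vector<int> cand;
        for (int x = 0; x < st.nnode; ++x) {
          if (x == p || in_sub[x]) continue;
          // upper end of the edge above x in the detached state
          double hi;
          if (x == s) hi = st.tm[gp];
          else if (x == st.root) hi = INFINITY;
          else hi = st.tm[st.par[x]];
          if (st.tm[x] < tp && tp < hi &&
              st.sched.mergeTime[st.repdeme[u]][st.repdeme[x]] <= tp)
            cand.push_back(x);
        }
        att[1] += 1;
        if (!cand.empty()) {
          int x = cand[unif_int((int)cand.size())];
          if (x != s) {
            // structural surgery
            std::vector<int> dirty_old = path_to_root(st, gp);
            // detach p: replace p by s under gp
            if (st.c1[gp] == p) st.c1[gp] = s; else st.c2[gp] = s;
            st.par[s] = gp;
            // insert p above x
            int xp = st.par[x];
            st.par[x] = p;
            if (st.c1[p] == s) st.c1[p] = x; else if (st.c2[p] == s) st.c2[p] = x;
            st.par[p] = xp;
            if (xp != -1) {
              if (st.c1[xp] == x) st.c1[xp] = p; else st.c2[xp] = p;
            } else {
              st.root = p;
            }
            // repdeme maintenance along both paths
            std::vector<int> dirty_new = path_to_root(st, p);
            std::vector<int> dirty = dirty_old;
            for (int w : dirty_new)
              if (std::find(dirty.begin(), dirty.end(), w) == dirty.end())
                dirty.push_back(w);
            std::sort(dirty.begin(), dirty.end(),
                      [&](int a, int b) { return st.tm[a] < st.tm[b]; });
            // save structure for rollback
            Backup sbk;
            save_nodes(st, dirty, sbk);
            bool valid = true;
            for (int w : dirty) {
              st.repdeme[w] = st.repdeme[st.c1[w]];
              if (st.tm[w] < st.minvalid(w) - 1e-12 ||
                  st.tm[w] <= std::max(st.tm[st.c1[w]], st.tm[st.c2[w]]) - 1e-12)
                valid = false;
            }
            double ll = -INFINITY, lp = -INFINITY;
            if (valid) {
              for (int w : dirty) st.recompute_node(w);
              ll = st.loglik_from_root();
              lp = st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max);
            }
            if (valid && R_finite(lp) &&
                try_accept(ll + lp - st.cur_loglik - st.cur_logprior)) {
              st.cur_loglik = ll; st.cur_logprior = lp; acc[1] += 1;
            } else {
              // undo surgery
              if (xp != -1) {
                if (st.c1[xp] == p) st.c1[xp] = x; else st.c2[xp] = x;
              } else {
                st.root = x;
              }
              st.par[x] = xp;
              if (st.c1[p] == x) st.c1[p] = s; else st.c2[p] = s;
              st.par[s] = p;
              st.par[p] = gp;
              if (st.c1[gp] == s) st.c1[gp] = p; else st.c2[gp] = p;
              restore_nodes(st, sbk);
              for (int w : dirty) st.repdeme[w] = st.repdeme[st.c1[w]];
            }
          }
        }
      }
    }

    // --- split-time moves (prior only)
    for (int j = 0; j < M; ++j) {
      double lo = (j == 0) ? 0.0 : st.sched.tau[j - 1];
      double hi = (j == M - 1) ? tau_max : st.sched.tau[j + 1];
      double width = (hi - lo) / 4.0;
      double told = st.sched.tau[j];
      double tnew = told + (unif_rand() - 0.5) * width;
      while (tnew < lo || tnew > hi) {     // reflect
        if (tnew < lo) tnew = 2 * lo - tnew;
        if (tnew > hi) tnew = 2 * hi - tnew;
      }
      st.sched.tau[j] = tnew;
      st.sched.refresh_merge_times();
      att[2] += 1;
      double lp = st.genealogy_valid() ?
        st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max) :
        -INFINITY;
      if (R_finite(lp) && try_accept(lp - st.cur_logprior)) {
        st.cur_logprior = lp; acc[2] += 1;
      } else {
        st.sched.tau[j] = told;
        st.sched.refresh_merge_times();
      }
    }

    // --- joint time-scale move: all node times, split times and N scale by
    // f while mu scales by 1/f; every branch's mu*t is unchanged, so the
    // likelihood (and the cached conditionals) are exactly invariant. This
    // slides the state along the rate-time ridge that STR data leave
    // unidentified, letting the informative rate prior anchor the time axis.
    {
      double f = std::exp(0.4 * (unif_rand() - 0.5));
      int n_int = st.nnode - st.n;
      std::vector<double> tm_old(st.tm);
      std::vector<double> tau_old = st.sched.tau;
      double mu_old = st.mu, N_old = st.N;
      for (int v = st.n; v < st.nnode; ++v) st.tm[v] *= f;
      for (double& tj : st.sched.tau) tj *= f;
      st.sched.refresh_merge_times();
      st.mu = mu_old / f;
      st.N = N_old * f;
      double logJ = (n_int + M + 1 - 1) * std::log(f);
      double lp = st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max);
      att[6] += 1;
      if (R_finite(lp) && try_accept(lp - st.cur_logprior + logJ)) {
        st.cur_logprior = lp; acc[6] += 1;
      } else {
        st.tm = tm_old;
        st.sched.tau = tau_old;
        st.sched.refresh_merge_times();
        st.mu = mu_old;
        st.N = N_old;
      }
    }

    // --- N move (prior only)
    {
      double fac = std::exp(0.4 * (unif_rand() - 0.5));
      double Nold = st.N;
      st.N = Nold * fac;
      att[3] += 1;
      double lp = st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max);
      if (R_finite(lp) && try_accept(lp - st.cur_logprior + std::log(fac))) {
        st.cur_logprior = lp; acc[3] += 1;
      } else st.N = Nold;
    }

    // --- mu move (full recompute), amortized
    if (it % 5 == 0) {
      double fac = std::exp(0.25 * (unif_rand() - 0.5));
      double muold = st.mu;
      std::vector<int> all;
      for (int v = st.n; v < st.nnode; ++v) all.push_back(v);
      std::sort(all.begin(), all.end(),
                [&](int a, int b) { return st.tm[a] < st.tm[b]; });
      save_nodes(st, all, bk);
      st.mu = muold * fac;
      for (int v : all) st.recompute_node(v);
      double ll = st.loglik_from_root();
      double lp = st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max);
      att[4] += 1;
      if (R_finite(lp) &&
          try_accept(ll + lp - st.cur_loglik - st.cur_logprior +
                     std::log(fac))) {
        st.cur_loglik = ll; st.cur_logprior = lp; acc[4] += 1;
      } else {
        st.mu = muold;
        restore_nodes(st, bk);
      }
    }

    // --- ranked-topology refresh (>2 demes)
    if (st.D > 2 && it % 5 == 1) {
      PopSchedule old = st.sched;
      // random sequential merging = uniform over ranked labeled histories
      std::vector<int> cls;
      for (int d = 0; d < st.D; ++d) cls.push_back(d);
      st.sched.merges.clear();
      int neu = st.D;
      while (cls.size() > 1) {
        int i = unif_int((int)cls.size());
        int a = cls[i]; cls.erase(cls.begin() + i);
        int j2 = unif_int((int)cls.size());
        int b = cls[j2]; cls.erase(cls.begin() + j2);
        st.sched.merges.push_back({a, b});
        cls.push_back(neu++);
      }
      st.sched.refresh_merge_times();
      att[5] += 1;
      double lp = st.genealogy_valid() ?
        st.logprior(mu_mean, mu_shape, logN_mean, logN_sd, tau_max) :
        -INFINITY;
      if (R_finite(lp) && try_accept(lp - st.cur_logprior)) {
        st.cur_logprior = lp; acc[5] += 1;
      } else st.sched = old;
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < M; ++j) out_tau(rec, j) = st.sched.tau[j];
      out_mu[rec] = st.mu;
      out_N[rec] = st.N;
      out_lp[rec] = st.cur_loglik + st.cur_logprior;
      std::vector<std::string> nm(st.D);
      for (int d = 0; d < st.D; ++d) nm[d] = as<std::string>(deme_names[d]);
      out_topo[rec] = st.sched.topo_string(nm);
      ++rec;
    }
  }

  NumericVector acc_rate(7);
  for (int i = 0; i < 7; ++i) acc_rate[i] = acc[i] / att[i];
  acc_rate.names() = CharacterVector::create("node_time", "spr", "tau", "N",
                                             "mu", "topology", "scale");
  return List::create(_["tau"] = out_tau, _["mu"] = out_mu, _["N"] = out_N,
                      _["log_post"] = out_lp, _["topology"] = out_topo,
                      _["acceptance"] = acc_rate,
                      _["final_loglik"] = st.cur_loglik);
}
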