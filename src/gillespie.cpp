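#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

// Self-contained RNG (splitmix64-seeded xoshiro256++) so that per-replicate
// streams are a pure function of (master seed, replicate index): replicate k
// of a batch is identical whether run alone or as part of the batch, on any
// platform.
namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1): never exactly 0, safe for log()
  double unif() { return ((next() >> 11) + 1.0) * 0x1.0p-53; }
  double rexp(double rate) { return -std::log(unif()) / rate; }
};

inline uint64_t stream_seed(uint64_t master, uint64_t rep) {
  uint64_t x = master * 0x9e3779b97f4a7c15ULL + rep + 1;
  return Xoshiro::splitmix64(x);
}

// Sparse out-edge structure (CSR by source node) + simulation state.
struct SISWorld {
  int n;
  const int *ptr;     // length n+1, 0-based offsets into (to, rate)
  const int *to;      // 0-based targets
  const double *rate;
  const double *g;    // recovery rates
  std::vector<int> infected;        // 0/1 per node
  std::vector<double> pressure;     // infectious pressure on each node
  double recov_total;
  double press_total;               // sum of pressure over susceptible nodes

  void reset(const std::vector<int> &init) {
    infected.assign(n, 0);
    pressure.assign(n, 0.0);
    recov_total = 0.0;
    for (int i : init) infected[i] = 1;
    for (int i : init) {
      recov_total += g[i];
      for (int e = ptr[i]; e < ptr[i + 1]; ++e) pressure[to[e]] += rate[e];
    }
    press_total = 0.0;
    for (int j = 0; j < n; ++j)
      if (!infected[j]) press_total += pressure[j];
  }

  void infect(int j) {
    infected[j] = 1;
    press_total -= pressure[j];
    recov_total += g[j];
    for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
      int k = to[e];
      pressure[k] += rate[e];
      if (!infected[k]) press_total += rate[e];
    }
  }

  void recover(int i) {
    infected[i] = 0;
    recov_total -= g[i];
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      int k = to[e];
      pressure[k] -= rate[e];
      if (!infected[k]) press_total -= rate[e];
    }
    press_total += pressure[i];
  }
};

// One Gillespie event. Returns node, sets kind (0 infection, 1 recovery).
// Assumes total rate > 0.
inline int step(SISWorld &w, Xoshiro &rng, int &kind) {
  double total = w.recov_total + w.press_total;
  double u = rng.unif() * total;
  if (u < w.recov_total) {
    kind = 1;
    double acc = 0.0;
    int last = -1;
    for (int i = 0; i < w.n; ++i)
      if (w.infected[i]) {
        acc += w.g[i];
        last = i;
        if (u <= acc) return i;
      }
    return last; // guard against roundoff
  }
  kind = 0;
  u -= w.recov_total;
  double acc = 0.0;
  int last = -1;
  for (int j = 0; j < w.n; ++j)
    if (!w.infected[j] && w.pressure[j] > 0) {
      acc += w.pressure[j];
      last = j;
      if (u <= acc) return j;
    }
  return last;
}

} // namespace

using namespace Rcpp;

// Run one trajectory. Stops at extinction, max_events, max_time or after
// max_infections infection events, whichever first. Times of events beyond
// max_time are not emitted (the run ends at max_time).
// [[Rcpp::export]]
List cpp_sis_run(int n, IntegerVector eptr, IntegerVector eto, NumericVector erate,
                 NumericVector g, IntegerVector init, double max_events,
                 double max_time, double max_infections, double seed,
                 bool record_trace) {
  SISWorld w;
  w.n = n; w.ptr = INTEGER(eptr); w.to = INTEGER(eto);
  w.rate = REAL(erate); w.g = REAL(g);
  std::vector<int> init0(init.begin(), init.end());
  w.reset(init0);
  Xoshiro rng(static_cast<uint64_t>(seed));

  std::vector<double> times;
  std::vector<int> kinds, nodes;
  double t = 0.0;
  double n_events = 0.0, n_inf = 0.0;
  bool extinct = w.recov_total == 0.0;
  double ext_time = extinct ? 0.0 : NA_REAL;

  while (!extinct && n_events < max_events && n_inf < max_infections) {
    double total = w.recov_total + w.press_total;
    double dt = rng.rexp(total);
    if (t + dt > max_time) { t = max_time; break; }
    t += dt;
    int kind;
    int node = step(w, rng, kind);
    if (kind == 1) w.recover(node); else { w.infect(node); n_inf += 1.0; }
    n_events += 1.0;
    if (record_trace) {
      times.push_back(t); kinds.push_back(kind); nodes.push_back(node + 1);
    }
    if (w.recov_total == 0.0) { extinct = true; ext_time = t; }
  }
  if (!extinct && t < max_time && n_events >= max_events) {
    // stopped by event count; end time is the time of the last event
  } else if (!extinct && max_time < R_PosInf && n_events < max_events &&
             n_inf < max_infections) {
    t = max_time;
  }

  LogicalVector final_inf(n);
  for (int i = 0; i < n; ++i) final_inf[i] = w.infected[i] == 1;
  return List::create(
      _["times"] = times, _["kinds"] = kinds, _["nodes"] = nodes,
      _["extinct"] = extinct, _["extinction_time"] = ext_time,
      _["end_time"] = t, _["n_events"] = n_events,
      _["n_infections"] = n_inf, _["final_infected"] = final_inf);
}

// Batch of independent replicates; per-replicate summaries only.
// [[Rcpp::export]]
List cpp_sis_batch(int n, IntegerVector eptr, IntegerVector eto, NumericVector erate,
                   NumericVector g, IntegerVector init, int n_reps,
                   double max_events, double max_time, double max_infections,
                   double master_seed) {
  SISWorld w;
  w.n = n; w.ptr = INTEGER(eptr); w.to = INTEGER(eto);
  w.rate = REAL(erate); w.g = REAL(g);
  std::vector<int> init0(init.begin(), init.end());

  NumericVector infections(n_reps), ext_time(n_reps), end_time(n_reps);
  LogicalVector extinct(n_reps);
  IntegerMatrix final_state(n_reps, n);

  for (int r = 0; r < n_reps; ++r) {
    w.reset(init0);
    Xoshiro rng(stream_seed(static_cast<uint64_t>(master_seed),
                            static_cast<uint64_t>(r)));
    double t = 0.0, n_events = 0.0, n_inf = 0.0;
    bool ext = w.recov_total == 0.0;
    double et = ext ? 0.0 : NA_REAL;
    while (!ext && n_events < max_events && n_inf < max_infections) {
      double total = w.recov_total + w.press_total;
      double dt = rng.rexp(total);
      if (t + dt > max_time) { t = max_time; break; }
      t += dt;
      int kind;
      int node = step(w, rng, kind);
      if (kind == 1) w.recover(node); else { w.infect(node); n_inf += 1.0; }
      n_events += 1.0;
      if (w.recov_total == 0.0) { ext = true; et = t; }
    }
    if (!ext && max_time < R_PosInf && n_events < max_events && n_inf < max_infections)
      t = max_time;
    infections[r] = n_inf;
    extinct[r] = ext;
    ext_time[r] = et;
    end_time[r] = t;
    for (int i = 0; i < n; ++i) final_state(r, i) = w.infected[i];
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["infections"] = infections, _["extinct"] = extinct,
                      _["extinction_time"] = ext_time, _["end_time"] = end_time,
                      _["final_state"] = final_state);
}

// Time-average occupancy estimator for the QSD marginals.
// Replicates start from `init`; each must survive `burnin_events` events
// before contributing. Post-burn-in inter-event intervals are accumulated
// (per node, per contiguous batch of kept events) until `keep_events` kept
// events have been collected. A replicate that goes extinct before its
// burn-in completes counts as a (consecutive) retry; extinction after burn-in just ends
// the replicate's contribution (post-extinction data carry no information
// about the conditioned process).
// [[Rcpp::export]]
List cpp_qsd_occupancy(int n, IntegerVector eptr, IntegerVector eto,
                       NumericVector erate, NumericVector g, IntegerVector init,
                       double keep_events, double burnin_events, int n_batches,
                       int max_retries, double master_seed) {
  SISWorld w;
  w.n = n; w.ptr = INTEGER(eptr); w.to = INTEGER(eto);
  w.rate = REAL(erate); w.g = REAL(g);
  std::vector<int> init0(init.begin(), init.end());

  NumericMatrix occ(n_batches, n);      // infected time per node per batch
  NumericVector batch_time(n_batches);
  double batch_size = std::ceil(keep_events / n_batches);
  double kept = 0.0;
  int retries = 0, replicates = 0;
  uint64_t rep = 0;

  while (kept < keep_events) {
    if (retries > max_retries)
      return List::create(_["failed"] = true, _["retries"] = retries,
                          _["replicates"] = replicates, _["kept"] = kept);
    w.reset(init0);
    Xoshiro rng(stream_seed(static_cast<uint64_t>(master_seed), rep++));
    replicates++;
    double n_events = 0.0;
    bool ext = w.recov_total == 0.0;
    bool contributed = false;
    while (!ext) {
      double total = w.recov_total + w.press_total;
      double dt = rng.rexp(total);
      if (n_events >= burnin_events) {
        int b = static_cast<int>(kept / batch_size);
        if (b >= n_batches) b = n_batches - 1;
        for (int i = 0; i < w.n; ++i)
          if (w.infected[i]) occ(b, i) += dt;
        batch_time[b] += dt;
        kept += 1.0;
        contributed = true;
        if (kept >= keep_events) break;
      }
      int kind;
      int node = step(w, rng, kind);
      if (kind == 1) w.recover(node); else w.infect(node);
      n_events += 1.0;
      if (w.recov_total == 0.0) ext = true;
      if (static_cast<long long>(n_events) % 8192 == 0) Rcpp::checkUserInterrupt();
    }
    if (!contributed) retries++; else retries = 0;
  }
  return List::create(_["failed"] = false, _["occupancy"] = occ,
                      _["batch_time"] = batch_time, _["retries"] = retries,
                      _["replicates"] = replicates, _["kept"] = kept);
}
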