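// Fixed-step kinetic Monte-Carlo engine for the 26-unit thin-filament model.
// Transition probabilities are precomputed per (state, neighbor-context) row
// on the R side; only the Ca2+-binding entries carry a concentration
// coefficient, so a time-varying transient costs one multiply per lookup.
// The per-unit fast path is a single uniform draw compared against the
// row's total step probability (<= 0.1 by the integrator guard); the
// transition scan only runs when an event fires.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64 for seeding, xoshiro256++ for the stream: deterministic across
// platforms, one stream per trajectory.
inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

}  // namespace

// [[Rcpp::export(name = ".sim_filament_cpp")]]
List sim_filament_cpp(NumericVector p_const, NumericVector p_ca,
                      IntegerVector target, IntegerVector ntrans,
                      int kmax, int n_units,
                      NumericVector ca_trace, double dt,
                      int n_traj, int record_every,
                      IntegerVector init_states, double seed,
                      int occ_burnin, int win_start) {
  const int n_steps = ca_trace.size();
  const int n_rec = (n_steps + record_every - 1) / record_every;
  const bool want_occ = occ_burnin >= 0 && occ_burnin < n_steps;
  std::vector<double> force_acc(n_rec, 0.0);
  std::vector<double> occ(24, 0.0);
  NumericVector traj_mean(n_traj);
  const uint64_t base_seed = static_cast<uint64_t>(seed);

  // Per-state tropomyosin context code (1 = B, 2 = C, 3 = M); 0 = free end.
  std::vector<int> tm_code(24);
  for (int s = 0; s < 24; ++s) tm_code[s] = s / 8 + 1;

  // Pre-scale by dt and accumulate per-row totals for the fast path.
  const int n_rows = 24 * 16;
  const int tab = n_rows * kmax;
  std::vector<double> pc(tab), pa(tab), tot_c(n_rows, 0.0), tot_a(n_rows, 0.0);
  for (int r = 0; r < n_rows; ++r) {
    for (int k = 0; k < kmax; ++k) {
      pc[r * kmax + k] = p_const[r * kmax + k] * dt;
      pa[r * kmax + k] = p_ca[r * kmax + k] * dt;
      tot_c[r] += pc[r * kmax + k];
      tot_a[r] += pa[r * kmax + k];
    }
  }

  std::vector<int> state(n_units);
  double occ_steps = 0.0;

  for (int tr = 0; tr < n_traj; ++tr) {
    Xoshiro256pp rng(base_seed + 0x9E3779B97F4A7C15ULL * (tr + 1));
    int m_count = 0;
    for (int u = 0; u < n_units; ++u) {
      state[u] = init_states[u];
      m_count += (state[u] >= 16);
    }
    double win_force = 0.0;
    long win_n = 0;

    for (int t = 0; t < n_steps; ++t) {
      const double ca = ca_trace[t];
      for (int u = 0; u < n_units; ++u) {
        const int cl = (u == 0) ? 0 : tm_code[state[u - 1]];
        const int cr = (u == n_units - 1) ? 0 : tm_code[state[u + 1]];
        const int row = state[u] * 16 + cl * 4 + cr;
        const double r = rng.unif();
        if (r >= tot_c[row] + ca * tot_a[row]) continue;  // no event
        const int base = row * kmax;
        const int nt = ntrans[row];
        double acc = 0.0;
        for (int k = 0; k < nt; ++k) {
          acc += pc[base + k] + ca * pa[base + k];
          if (r < acc) {
            m_count += (target[base + k] >= 16) - (state[u] >= 16);
            state[u] = target[base + k];
            break;
          }
        }
      }
      if (t % record_every == 0) force_acc[t / record_every] += m_count;
      if (t >= win_start) { win_force += m_count; ++win_n; }
      if (want_occ && t >= occ_burnin) {
        for (int u = 0; u < n_units; ++u) occ[state[u]] += 1.0;
        occ_steps += n_units;
      }
    }
    traj_mean[tr] = win_n > 0 ? win_force / win_n : NA_REAL;
  }

  NumericVector force(n_rec);
  for (int i = 0; i < n_rec; ++i) force[i] = force_acc[i] / n_traj;
  NumericVector occupancy(24);
  if (occ_steps > 0)
    for (int s = 0; s < 24; ++s) occupancy[s] = occ[s] / occ_steps;

  return List::create(_["force"] = force,
                      _["occupancy"] = occupancy,
                      _["traj_mean"] = traj_mean);
}
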