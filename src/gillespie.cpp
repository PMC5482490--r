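// Gillespie engine for the closed-loop TASEP on a single transcript.
//
// Lattice sites are 1..L; site L is the termination site.  Only A-site
// positions are tracked (ascending order = 5'->3').  Reaction rules:
//   * de novo initiation at rate alpha, enabled iff no A-site lies in
//     sites 1..footprint; places an A-site at site 1
//   * elongation of the ribosome at site i < L at elong[i-1], enabled iff
//     the next A-site downstream (if any) is > i + footprint
//   * release at rate beta when an A-site occupies site L
//   * reinitiation at rate r when an A-site occupies site L, enabled iff
//     no A-site lies in sites 1..footprint; moves that A-site to site 1
// Completions are counted when an A-site *arrives* at site L, so each
// reinitiation cycle contributes one completion.
//
// Two RNG draws per event, in the order (waiting time, channel).  Each
// replicate k uses an independent xoshiro256++ stream seeded by
// splitmix64(splitmix64(root_seed) ^ k * 0x9E3779B97F4A7C15).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]; strictly positive so log() is safe
  double unif() { return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0); }
};

uint64_t replicate_seed(uint64_t root, uint64_t k) {
  uint64_t x = root;
  uint64_t h = splitmix64(x);
  uint64_t y = h ^ (k * 0x9E3779B97F4A7C15ULL);
  return splitmix64(y);
}

struct RunResult {
  double occ_integral = 0.0;
  double de_novo = 0.0, reinits = 0.0, releases = 0.0, completions = 0.0;
  double first_arrival = NA_REAL;
  int final_n = 0;
  bool terminal_occupied = false;
  bool frozen = false;
};

// One trajectory.  grid/grid_sum: running across-run sums of the instantaneous
// ribosome count sampled at fixed times (pre-event count over each interval).
RunResult run_one(int L, const std::vector<double> &elong, double alpha,
                  double reinit_rate, double release_rate, int footprint,
                  double lifetime, Xoshiro256pp &rng, bool start_occupied,
                  bool stop_at_first_completion,
                  const std::vector<double> &grid,
                  std::vector<double> *grid_sum) {
  RunResult res;
  std::vector<int> pos;  // ascending A-site positions
  pos.reserve(L / footprint + 1);
  if (start_occupied) pos.push_back(1);
  std::vector<int> mov;       // indices of movable ribosomes, reused per event
  std::vector<double> movr;   // their elongation rates
  mov.reserve(L / footprint + 1);
  movr.reserve(L / footprint + 1);
  double t = 0.0;
  size_t gidx = 0;

  auto record_until = [&](double t_new, int n_now) {
    if (!grid_sum) return;
    while (gidx < grid.size() && grid[gidx] <= t_new) {
      (*grid_sum)[gidx] += n_now;
      ++gidx;
    }
  };

  if (lifetime <= 0.0) {
    res.final_n = (int)pos.size();
    return res;
  }

  for (;;) {
    const int n = (int)pos.size();
    const bool entry_free = pos.empty() || pos.front() > footprint;
    const bool terminal = !pos.empty() && pos.back() == L;

    mov.clear();
    movr.clear();
    double elong_sum = 0.0;
    for (int i = 0; i < n; ++i) {
      if (pos[i] < L && (i == n - 1 || pos[i + 1] - pos[i] > footprint)) {
        const double k = elong[pos[i] - 1];
        mov.push_back(i);
        movr.push_back(k);
        elong_sum += k;
      }
    }
    double total = elong_sum;
    if (entry_free) total += alpha;
    if (terminal) {
      total += release_rate;
      if (entry_free) total += reinit_rate;
    }

    if (total <= 0.0) {  // frozen: advance to end of life
      res.frozen = true;
      if (R_FINITE(lifetime)) {
        res.occ_integral += n * (lifetime - t);
        record_until(lifetime, n);
      }
      break;
    }

    const double dt = -std::log(rng.unif()) / total;
    if (t + dt > lifetime) {  // event past end of life: discard, close integral
      res.occ_integral += n * (lifetime - t);
      record_until(lifetime, n);
      break;
    }
    res.occ_integral += n * dt;
    record_until(t + dt, n);
    t += dt;

    // channel selection, fixed order: init, elongation (5'->3'), release, reinit
    double u = rng.unif() * total;
    bool done = false;
    if (entry_free) {
      if (u < alpha) {
        pos.insert(pos.begin(), 1);
        res.de_novo += 1;
        done = true;
      } else {
        u -= alpha;
      }
    }
    if (!done) {
      for (size_t m = 0; m < mov.size() && !done; ++m) {
        if (u < movr[m]) {
          const int i = mov[m];
          pos[i] += 1;
          if (pos[i] == L) {
            res.completions += 1;
            if (stop_at_first_completion) {
              res.first_arrival = t;
              res.final_n = (int)pos.size();
              res.terminal_occupied = true;
              return res;
            }
          }
          done = true;
        } else {
          u -= movr[m];
        }
      }
    }
    if (!done && terminal) {
      if (u < release_rate || !entry_free) {
        pos.pop_back();
        res.releases += 1;
        done = true;
      } else {
        // reinitiation (last channel catches numerical remainder)
        pos.pop_back();
        pos.insert(pos.begin(), 1);
        res.reinits += 1;
        done = true;
      }
    }
    if (!done) {
      // float round-off at the end of the cumulative walk: apply the last
      // enabled channel in the fixed order
      if (!mov.empty()) {
        const int i = mov.back();
        pos[i] += 1;
        if (pos[i] == L) res.completions += 1;
      } else if (entry_free) {
        pos.insert(pos.begin(), 1);
        res.de_novo += 1;
      }
    }
  }

  res.final_n = (int)pos.size();
  res.terminal_occupied = !pos.empty() && pos.back() == L;
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simulate_batch")]]
List cpp_simulate_batch(int L, NumericVector elong, double alpha,
                        double reinit_rate, double release_rate, int footprint,
                        double lifetime, int n_runs, double seed,
                        int first_replicate, NumericVector sample_times,
                        bool start_occupied, bool stop_at_first_completion) {
  std::vector<double> el(elong.begin(), elong.end());
  std::vector<double> grid(sample_times.begin(), sample_times.end());
  std::vector<double> grid_sum(grid.size(), 0.0);

  NumericVector occ(n_runs), de_novo(n_runs), reinits(n_runs), releases(n_runs),
      completions(n_runs), first_arrival(n_runs), final_n(n_runs);
  LogicalVector terminal_occupied(n_runs), frozen(n_runs);

  const uint64_t root = (uint64_t)((int64_t)seed);
  for (int j = 0; j < n_runs; ++j) {
    const uint64_t k = (uint64_t)(first_replicate + j);
    Xoshiro256pp rng(replicate_seed(root, k));
    RunResult r = run_one(L, el, alpha, reinit_rate, release_rate, footprint,
                          lifetime, rng, start_occupied,
                          stop_at_first_completion, grid,
                          grid.empty() ? nullptr : &grid_sum);
    occ[j] = r.occ_integral;
    de_novo[j] = r.de_novo;
    reinits[j] = r.reinits;
    releases[j] = r.releases;
    completions[j] = r.completions;
    first_arrival[j] = r.first_arrival;
    final_n[j] = r.final_n;
    terminal_occupied[j] = r.terminal_occupied;
    frozen[j] = r.frozen;
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["occupancy_integral"] = occ, _["de_novo"] = de_novo,
      _["reinits"] = reinits, _["releases"] = releases,
      _["completions"] = completions, _["first_arrival"] = first_arrival,
      _["final_n"] = final_n, _["terminal_occupied"] = terminal_occupied,
      _["frozen"] = frozen);
  if (!grid.empty()) out["grid_count_sum"] = NumericVector(grid_sum.begin(), grid_sum.end());
  return out;
}
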