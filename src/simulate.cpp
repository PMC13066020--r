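// Monte-Carlo core for stochastic asynchronous Boolean network ensembles.
//
// Rules are compiled (in R) to a postfix bytecode per node:
//   opcode >= 0 : push state of node <opcode>
//   -1 : push FALSE        -2 : push TRUE
//   -3 : NOT               -4 : AND (binary)        -5 : OR (binary)
//
// One time step applies one uniformly random permutation of all nodes
// sequentially against the evolving state (scheme 0), or updates a single
// uniformly random node (scheme 1). A node whose rule is satisfied switches
// ON with probability equal to its polymorphism, otherwise OFF; clamps
// override everything inside their window.
//
// RNG: one mt19937_64 substream per repetition, seeded via splitmix64 from
// the master seed and the repetition index. Within a repetition the draw
// order is: initialization (node 0..n-1), then per step the permutation
// draws followed by one polymorphism draw per satisfied stochastic node.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0); // 53-bit mantissa
}

static inline uint64_t bounded(std::mt19937_64 &rng, uint64_t k) {
  return (uint64_t)(((unsigned __int128)rng() * (unsigned __int128)k) >> 64);
}

static inline bool eval_program(const int *code, int len,
                                const std::vector<uint8_t> &state,
                                std::vector<uint8_t> &stack) {
  int sp = 0;
  for (int i = 0; i < len; ++i) {
    int op = code[i];
    if (op >= 0) {
      stack[sp++] = state[op];
    } else if (op == -1) {
      stack[sp++] = 0;
    } else if (op == -2) {
      stack[sp++] = 1;
    } else if (op == -3) {
      stack[sp - 1] = !stack[sp - 1];
    } else if (op == -4) {
      uint8_t b = stack[--sp];
      stack[sp - 1] = stack[sp - 1] && b;
    } else { // -5
      uint8_t b = stack[--sp];
      stack[sp - 1] = stack[sp - 1] || b;
    }
  }
  return stack[0] != 0;
}

// [[Rcpp::export(name = ".simulate_ensemble_cpp")]]
NumericMatrix simulate_ensemble_cpp(IntegerVector prog,
                                    IntegerVector prog_start,
                                    NumericVector poly,
                                    NumericVector init_prob,
                                    int steps,
                                    int reps,
                                    double seed,
                                    IntegerVector clamp_node,
                                    IntegerVector clamp_value,
                                    NumericVector clamp_start,
                                    NumericVector clamp_end,
                                    bool evolving,
                                    int scheme) {
  const int n = poly.size();
  const int nclamp = clamp_node.size();
  std::vector<long long> counts((size_t)n * (steps + 1), 0);
  std::vector<uint8_t> state(n), snapshot(n), stack(256);
  std::vector<int> perm(n);
  std::vector<int8_t> clamp_now(n);
  const uint64_t master = (uint64_t)(int64_t)seed;

  for (int rep = 0; rep < reps; ++rep) {
    std::mt19937_64 rng(splitmix64(master ^ splitmix64((uint64_t)rep + 1)));
    for (int i = 0; i < n; ++i)
      state[i] = (unif01(rng) < init_prob[i]) ? 1 : 0;
    for (int i = 0; i < n; ++i)
      if (state[i]) counts[(size_t)i * (steps + 1)] += 1;

    for (int t = 1; t <= steps; ++t) {
      // active clamps this step
      std::fill(clamp_now.begin(), clamp_now.end(), (int8_t)-1);
      for (int c = 0; c < nclamp; ++c)
        if (clamp_start[c] <= t && t < clamp_end[c])
          clamp_now[clamp_node[c]] = (int8_t)clamp_value[c];

      const std::vector<uint8_t> *readfrom = &state;
      if (!evolving) { snapshot = state; readfrom = &snapshot; }

      if (scheme == 0) {
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = n - 1; i > 0; --i) {
          int j = (int)bounded(rng, (uint64_t)(i + 1));
          std::swap(perm[i], perm[j]);
        }
        for (int k = 0; k < n; ++k) {
          int i = perm[k];
          uint8_t newv;
          if (clamp_now[i] >= 0) {
            newv = (uint8_t)clamp_now[i];
          } else {
            bool sat = eval_program(&prog[prog_start[i]],
                                    prog_start[i + 1] - prog_start[i],
                                    *readfrom, stack);
            if (!sat) newv = 0;
            else if (poly[i] >= 1.0) newv = 1;
            else newv = (unif01(rng) < poly[i]) ? 1 : 0;
          }
          state[i] = newv;
        }
      } else { // single random node per step
        int i = (int)bounded(rng, (uint64_t)n);
        uint8_t newv;
        if (clamp_now[i] >= 0) {
          newv = (uint8_t)clamp_now[i];
        } else {
          bool sat = eval_program(&prog[prog_start[i]],
                                  prog_start[i + 1] - prog_start[i],
                                  *readfrom, stack);
          if (!sat) newv = 0;
          else if (poly[i] >= 1.0) newv = 1;
          else newv = (unif01(rng) < poly[i]) ? 1 : 0;
        }
        state[i] = newv;
        // clamps hold even for nodes not selected this step
        for (int c = 0; c < nclamp; ++c)
          if (clamp_start[c] <= t && t < clamp_end[c])
            state[clamp_node[c]] = (uint8_t)clamp_value[c];
      }

      for (int i = 0; i < n; ++i)
        if (state[i]) counts[(size_t)i * (steps + 1) + t] += 1;
    }
  }

  NumericMatrix freq(n, steps + 1);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t <= steps; ++t)
      freq(i, t) = (double)counts[(size_t)i * (steps + 1) + t] / (double)reps;
  return freq;
}

// Single stochastic node update, exposed for unit-level semantics tests.
// [[Rcpp::export(name = ".update_node_cpp")]]
LogicalVector update_node_cpp(IntegerVector prog, NumericVector state,
                              double poly, double seed, int ndraws) {
  std::mt19937_64 rng(splitmix64((uint64_t)(int64_t)seed));
  std::vector<uint8_t> st(state.size());
  for (int i = 0; i < state.size(); ++i) st[i] = state[i] != 0 ? 1 : 0;
  std::vector<uint8_t> stack(256);
  LogicalVector out(ndraws);
  for (int d = 0; d < ndraws; ++d) {
    bool sat = eval_program(&prog[0], prog.size(), st, stack);
    if (!sat) out[d] = false;
    else if (poly >= 1.0) out[d] = true;
    else out[d] = unif01(rng) < poly;
  }
  return out;
}
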