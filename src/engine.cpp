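// Gillespie simulation core for Boolean networks as continuous-time Markov
// chains. Rate expressions arrive pre-compiled (R side) to a postfix bytecode
// evaluated on a fixed-size stack; per-trajectory RNG streams are derived
// from the master seed with splitmix64 so results are independent of
// execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <unordered_map>
#include <random>

using namespace Rcpp;

// Opcodes; must match .compileAst() on the R side.
enum Op {
  PUSH_CONST = 1, PUSH_NODE = 2, OP_NOT = 3, OP_NEG = 4, OP_AND = 5,
  OP_OR = 6, OP_XOR = 7, OP_ADD = 8, OP_SUB = 9, OP_MUL = 10, OP_DIV = 11,
  OP_IFELSE = 12
};

struct Program {
  std::vector<int> ops;
  std::vector<int> args;
  std::vector<double> consts;
};

static double evalProgram(const Program& p, const std::vector<int>& state) {
  double stack[256];
  int sp = 0;
  const size_t n = p.ops.size();
  for (size_t i = 0; i < n; ++i) {
    switch (p.ops[i]) {
    case PUSH_CONST: stack[sp++] = p.consts[p.args[i]]; break;
    case PUSH_NODE:  stack[sp++] = state[p.args[i]]; break;
    case OP_NOT: stack[sp - 1] = (stack[sp - 1] == 0.0) ? 1.0 : 0.0; break;
    case OP_NEG: stack[sp - 1] = -stack[sp - 1]; break;
    case OP_AND: sp--; stack[sp - 1] = (stack[sp - 1] != 0.0 && stack[sp] != 0.0) ? 1.0 : 0.0; break;
    case OP_OR:  sp--; stack[sp - 1] = (stack[sp - 1] != 0.0 || stack[sp] != 0.0) ? 1.0 : 0.0; break;
    case OP_XOR: sp--; stack[sp - 1] = ((stack[sp - 1] != 0.0) != (stack[sp] != 0.0)) ? 1.0 : 0.0; break;
    case OP_ADD: sp--; stack[sp - 1] += stack[sp]; break;
    case OP_SUB: sp--; stack[sp - 1] -= stack[sp]; break;
    case OP_MUL: sp--; stack[sp - 1] *= stack[sp]; break;
    case OP_DIV:
      sp--;
      if (stack[sp] == 0.0) throw std::runtime_error("division by zero in rate expression");
      stack[sp - 1] /= stack[sp];
      break;
    case OP_IFELSE:
      sp -= 2;
      stack[sp - 1] = (stack[sp - 1] != 0.0) ? stack[sp] : stack[sp + 1];
      break;
    }
  }
  return stack[0];
}

static std::vector<Program> unpackPrograms(const List& opsL, const List& argsL,
                                           const List& constsL) {
  std::vector<Program> out(opsL.size());
  for (int i = 0; i < opsL.size(); ++i) {
    IntegerVector o = opsL[i], a = argsL[i];
    NumericVector c = constsL[i];
    out[i].ops.assign(o.begin(), o.end());
    out[i].args.assign(a.begin(), a.end());
    out[i].consts.assign(c.begin(), c.end());
  }
  return out;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Uniform in [0, 1) built from raw 53-bit output: bit-identical across
// standard libraries (uniform_real_distribution is not).
static inline double nextUniform(std::mt19937_64& gen) {
  return (gen() >> 11) * (1.0 / 9007199254740992.0);
}

struct InitialSampler {
  // per block: node indices (0-based), cumulative probs, atoms (rows) x nodes
  std::vector<std::vector<int>> nodes;
  std::vector<std::vector<double>> cumProbs;
  std::vector<std::vector<std::vector<int>>> atoms;
  std::vector<int> freeNodes;
  double defaultP;
  std::vector<int> forcedIdx, forcedVal;

  void sample(std::mt19937_64& gen, std::vector<int>& state) const {
    for (size_t b = 0; b < nodes.size(); ++b) {
      double u = nextUniform(gen);
      size_t k = 0;
      while (k + 1 < cumProbs[b].size() && u >= cumProbs[b][k]) ++k;
      for (size_t j = 0; j < nodes[b].size(); ++j)
        state[nodes[b][j]] = atoms[b][k][j];
    }
    for (int idx : freeNodes)
      state[idx] = (nextUniform(gen) < defaultP) ? 1 : 0;
    for (size_t i = 0; i < forcedIdx.size(); ++i)
      state[forcedIdx[i]] = forcedVal[i];
  }
};

static InitialSampler buildSampler(const List& blockNodes, const List& blockProbs,
                                   const List& blockAssign, double defaultP,
                                   const IntegerVector& forcedIdx,
                                   const IntegerVector& forcedVal, int nNodes) {
  InitialSampler s;
  s.defaultP = defaultP;
  std::vector<bool> covered(nNodes, false);
  for (int b = 0; b < blockNodes.size(); ++b) {
    IntegerVector nd = blockNodes[b];
    NumericVector pr = blockProbs[b];
    IntegerMatrix as = blockAssign[b];
    s.nodes.emplace_back(nd.begin(), nd.end());
    std::vector<double> cum(pr.size());
    double acc = 0.0;
    for (int k = 0; k < pr.size(); ++k) { acc += pr[k]; cum[k] = acc; }
    s.cumProbs.push_back(cum);
    std::vector<std::vector<int>> at(as.nrow(), std::vector<int>(as.ncol()));
    for (int r = 0; r < as.nrow(); ++r)
      for (int c = 0; c < as.ncol(); ++c) at[r][c] = as(r, c);
    s.atoms.push_back(at);
    for (int k = 0; k < nd.size(); ++k) covered[nd[k]] = true;
  }
  for (int i = 0; i < forcedIdx.size(); ++i) {
    s.forcedIdx.push_back(forcedIdx[i]);
    s.forcedVal.push_back(forcedVal[i]);
    covered[forcedIdx[i]] = true;  // forced overrides both blocks and default
  }
  for (int i = 0; i < nNodes; ++i)
    if (!covered[i]) s.freeNodes.push_back(i);
  return s;
}

static std::string stateString(const std::vector<int>& state) {
  std::string s(state.size(), '0');
  for (size_t i = 0; i < state.size(); ++i) if (state[i]) s[i] = '1';
  return s;
}

static double propensity(const std::vector<Program>& up,
                         const std::vector<Program>& down,
                         const std::vector<int>& state, int i,
                         const CharacterVector& nodeNamesV) {
  double r = state[i] == 0 ? evalProgram(up[i], state) : evalProgram(down[i], state);
  if (!std::isfinite(r) || r < 0.0) {
    std::string nm = as<std::string>(nodeNamesV[i]);
    throw std::runtime_error("invalid rate (" + std::to_string(r) + ") for node '" +
                             nm + "' in state " + stateString(state));
  }
  return r;
}

// [[Rcpp::export(name = ".ensembleCpp")]]
List ensembleCpp(List upOps, List upArgs, List upConsts,
                 List downOps, List downArgs, List downConsts,
                 CharacterVector nodeNamesV,
                 List blockNodes, List blockProbs, List blockAssign,
                 double defaultP,
                 IntegerVector forcedIdx, IntegerVector forcedVal,
                 IntegerVector outputIdx,
                 int sampleCount, double maxTime, int timePoints,
                 double seed) {
  const int n = nodeNamesV.size();
  const int W = timePoints;
  const double wWidth = maxTime / W;
  std::vector<Program> up = unpackPrograms(upOps, upArgs, upConsts);
  std::vector<Program> down = unpackPrograms(downOps, downArgs, downConsts);
  InitialSampler sampler = buildSampler(blockNodes, blockProbs, blockAssign,
                                        defaultP, forcedIdx, forcedVal, n);
  const uint64_t seed64 = (uint64_t)(int64_t)seed;

  std::unordered_map<int, std::vector<double>> stateOcc;  // projKey -> per-window time
  NumericMatrix nodeOcc(W, n);
  std::unordered_map<int, int> lastCounts;                // projKey -> trajectories
  std::unordered_map<std::string, int> fixedCounts;       // full state -> trajectories

  std::vector<int> state(n);
  std::vector<double> props(n);

  auto projKey = [&](const std::vector<int>& st) {
    int key = 0;
    for (int j = 0; j < outputIdx.size(); ++j)
      if (st[outputIdx[j]]) key |= (1 << j);
    return key;
  };
  auto addSojourn = [&](double t0, double t1, const std::vector<int>& st) {
    if (t1 <= t0) return;
    int key = projKey(st);
    auto it = stateOcc.find(key);
    if (it == stateOcc.end())
      it = stateOcc.emplace(key, std::vector<double>(W, 0.0)).first;
    int w0 = (int)(t0 / wWidth);
    if (w0 >= W) w0 = W - 1;
    for (int w = w0; w < W; ++w) {
      double lo = w * wWidth, hi = lo + wWidth;
      if (lo >= t1) break;
      double overlap = std::min(hi, t1) - std::max(lo, t0);
      if (overlap > 0) {
        it->second[w] += overlap;
        for (int i = 0; i < n; ++i)
          if (st[i]) nodeOcc(w, i) += overlap;
      }
    }
  };

  for (int traj = 0; traj < sampleCount; ++traj) {
    std::mt19937_64 gen(splitmix64(seed64 ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(traj + 1))));
    sampler.sample(gen, state);
    double t = 0.0;
    bool atFixedPoint = false;
    while (true) {
      double R = 0.0;
      for (int i = 0; i < n; ++i) {
        props[i] = propensity(up, down, state, i, nodeNamesV);
        R += props[i];
      }
      if (R <= 0.0) {  // fixed point: held until maxTime
        addSojourn(t, maxTime, state);
        atFixedPoint = true;
        break;
      }
      double dt = -std::log(1.0 - nextUniform(gen)) / R;
      if (t + dt >= maxTime) {
        addSojourn(t, maxTime, state);
        break;
      }
      addSojourn(t, t + dt, state);
      t += dt;
      double u = nextUniform(gen) * R;
      double acc = 0.0;
      int flip = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += props[i];
        if (u < acc) { flip = i; break; }
      }
      state[flip] = 1 - state[flip];
    }
    lastCounts[projKey(state)]++;
    if (atFixedPoint) fixedCounts[stateString(state)]++;
    if ((traj & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // normalize occupancy to probabilities
  const double norm = 1.0 / (wWidth * sampleCount);
  IntegerVector stateKeys(stateOcc.size());
  NumericMatrix stateProbs(W, stateOcc.size());
  int col = 0;
  for (auto& kv : stateOcc) {
    stateKeys[col] = kv.first;
    for (int w = 0; w < W; ++w) stateProbs(w, col) = kv.second[w] * norm;
    ++col;
  }
  for (int w = 0; w < W; ++w)
    for (int i = 0; i < n; ++i) nodeOcc(w, i) *= norm;

  IntegerVector lastKeys(lastCounts.size());
  NumericVector lastFreq(lastCounts.size());
  col = 0;
  for (auto& kv : lastCounts) {
    lastKeys[col] = kv.first;
    lastFreq[col] = (double)kv.second / sampleCount;
    ++col;
  }
  CharacterVector fpStates(fixedCounts.size());
  NumericVector fpShare(fixedCounts.size());
  col = 0;
  for (auto& kv : fixedCounts) {
    fpStates[col] = kv.first;
    fpShare[col] = (double)kv.second / sampleCount;
    ++col;
  }
  return List::create(_["stateKeys"] = stateKeys, _["stateProbs"] = stateProbs,
                      _["nodeProbs"] = nodeOcc, _["lastKeys"] = lastKeys,
                      _["lastFreq"] = lastFreq, _["fixedStates"] = fpStates,
                      _["fixedShare"] = fpShare);
}

// Single-trajectory simulation with jump recording; trajectory `trajIndex`
// (1-based) reproduces exactly the corresponding member of the ensemble.
// [[Rcpp::export(name = ".trajectoryCpp")]]
List trajectoryCpp(List upOps, List upArgs, List upConsts,
                   List downOps, List downArgs, List downConsts,
                   CharacterVector nodeNamesV,
                   List blockNodes, List blockProbs, List blockAssign,
                   double defaultP,
                   IntegerVector forcedIdx, IntegerVector forcedVal,
                   double maxTime, double seed, int trajIndex) {
  const int n = nodeNamesV.size();
  std::vector<Program> up = unpackPrograms(upOps, upArgs, upConsts);
  std::vector<Program> down = unpackPrograms(downOps, downArgs, downConsts);
  InitialSampler sampler = buildSampler(blockNodes, blockProbs, blockAssign,
                                        defaultP, forcedIdx, forcedVal, n);
  const uint64_t seed64 = (uint64_t)(int64_t)seed;
  std::mt19937_64 gen(splitmix64(seed64 ^ (0x9E3779B97F4A7C15ULL * (uint64_t)trajIndex)));

  std::vector<int> state(n);
  sampler.sample(gen, state);
  IntegerVector initial(state.begin(), state.end());
  std::vector<double> jumpTimes;
  std::vector<int> flipped;
  std::vector<double> props(n);
  double t = 0.0;
  bool atFixedPoint = false;
  while (true) {
    double R = 0.0;
    for (int i = 0; i < n; ++i) {
      props[i] = propensity(up, down, state, i, nodeNamesV);
      R += props[i];
    }
    if (R <= 0.0) { atFixedPoint = true; break; }
    double dt = -std::log(1.0 - nextUniform(gen)) / R;
    if (t + dt >= maxTime) break;
    t += dt;
    double u = nextUniform(gen) * R;
    double acc = 0.0;
    int flip = n - 1;
    for (int i = 0; i < n; ++i) {
      acc += props[i];
      if (u < acc) { flip = i; break; }
    }
    state[flip] = 1 - state[flip];
    jumpTimes.push_back(t);
    flipped.push_back(flip + 1);  // 1-based for R
  }
  return List::create(_["initialState"] = initial,
                      _["jumpTimes"] = NumericVector(jumpTimes.begin(), jumpTimes.end()),
                      _["flippedNode"] = IntegerVector(flipped.begin(), flipped.end()),
                      _["finalState"] = IntegerVector(state.begin(), state.end()),
                      _["fixedPoint"] = atFixedPoint);
}

// Propensity matrix for explicitly listed states (rows); used by the
// exhaustive fixed-point search and the state-transition-graph utilities.
// [[Rcpp::export(name = ".propensitiesCpp")]]
NumericMatrix propensitiesCpp(List upOps, List upArgs, List upConsts,
                              List downOps, List downArgs, List downConsts,
                              CharacterVector nodeNamesV, IntegerMatrix states) {
  const int n = nodeNamesV.size();
  std::vector<Program> up = unpackPrograms(upOps, upArgs, upConsts);
  std::vector<Program> down = unpackPrograms(downOps, downArgs, downConsts);
  NumericMatrix out(states.nrow(), n);
  std::vector<int> st(n);
  for (int r = 0; r < states.nrow(); ++r) {
    for (int i = 0; i < n; ++i) st[i] = states(r, i);
    for (int i = 0; i < n; ++i) out(r, i) = propensity(up, down, st, i, nodeNamesV);
  }
  return out;
}

// Enumerate all 2^n states, keep those with zero total propensity. Early
// pruning: a state is discarded at the first node with positive propensity.
// [[Rcpp::export(name = ".fixedPointsCpp")]]
IntegerMatrix fixedPointsCpp(List upOps, List upArgs, List upConsts,
                             List downOps, List downArgs, List downConsts,
                             CharacterVector nodeNamesV) {
  const int n = nodeNamesV.size();
  if (n > 20) throw std::runtime_error("exhaustive fixed-point search is limited to 20 nodes");
  std::vector<Program> up = unpackPrograms(upOps, upArgs, upConsts);
  std::vector<Program> down = unpackPrograms(downOps, downArgs, downConsts);
  std::vector<std::vector<int>> found;
  std::vector<int> st(n);
  const uint32_t total = 1u << n;
  for (uint32_t code = 0; code < total; ++code) {
    for (int i = 0; i < n; ++i) st[i] = (code >> i) & 1u;
    bool fixed = true;
    for (int i = 0; i < n; ++i) {
      if (propensity(up, down, st, i, nodeNamesV) > 0.0) { fixed = false; break; }
    }
    if (fixed) found.push_back(st);
    if ((code & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out(found.size(), n);
  for (size_t r = 0; r < found.size(); ++r)
    for (int i = 0; i < n; ++i) out(r, i) = found[r][i];
  return out;
}
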