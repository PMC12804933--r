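// Core simulation engine: repeated-match play with execution noise,
// finite-memory strategy automata, tabular multi-agent Q-learning, and
// matrix-mode Fermi imitation dynamics. All randomness draws from R's RNG
// so set.seed() in R makes every routine reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Action coding: 0 = C (cooperate), 1 = D (defect).
// Payoff vector pv = {R, S, T, P}; payoff to self = pv[2*self + opp].

enum Kind {
  K_TABLE = 0, K_REACTIVE1 = 1, K_TFT = 2, K_GTFT = 3, K_WSLS = 4,
  K_GRUDGE = 5, K_FOOLMEONCE = 6, K_OMEGATFT = 7, K_GRADUALTFT = 8,
  K_ALLC = 9, K_ALLD = 10
};

static inline int rand_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// State index for a partial history of the last min(t-1, mem) rounds.
// Pair digit = 2*opp + own; histories ordered oldest-first; histories of
// length k occupy a contiguous block after all shorter ones
// (offset = sum_{j<k} 4^j). Returns -1 in round 1 (no history).
static int encode_state_cpp(const std::vector<int> &own,
                            const std::vector<int> &opp,
                            int t, int mem) {
  int k = std::min(t - 1, mem);
  if (k <= 0) return -1;
  int offset = 0, pw = 1;
  for (int j = 1; j < k; ++j) { pw *= 4; offset += pw; }
  int rel = 0;
  for (int r = t - 1 - k; r <= t - 2; ++r)
    rel = rel * 4 + (2 * opp[r] + own[r]);
  return offset + rel;
}

struct Strategy {
  int kind = K_ALLC;
  int first_move = 2;          // 0 C, 1 D, 2 random
  int mem = 2;                 // table memory length
  std::vector<int> table;      // action per state index (table kind)
  double p[4] = {1, 1, 1, 1};  // reactive-1 cooperation probs [2*own+opp]
  double g = 0.3;              // GTFT forgiveness
  int dl_thresh = 3, rn_thresh = 8;  // OmegaTFT thresholds

  // automaton state (reset between matches)
  bool grudged = false;
  int defects = 0;             // opponent defections observed
  bool warn_pending = false;   // Fool-Me-Once warning scheduled
  int punish_left = 0, cool_left = 0;  // GradualTFT phases
  int deadlock = 0, randomness = 0;    // OmegaTFT counters

  void reset() {
    grudged = false; defects = 0; warn_pending = false;
    punish_left = 0; cool_left = 0; deadlock = 0; randomness = 0;
  }

  void from_list(const List &spec) {
    kind = as<int>(spec["kind_code"]);
    first_move = as<int>(spec["first_code"]);
    if (spec.containsElementNamed("memory") && !Rf_isNull(spec["memory"]))
      mem = as<int>(spec["memory"]);
    if (kind == K_TABLE)
      table = as<std::vector<int>>(spec["table"]);
    if (kind == K_REACTIVE1) {
      NumericVector pv = spec["p"];
      for (int i = 0; i < 4; ++i) p[i] = pv[i];
    }
    if (kind == K_GTFT) g = as<double>(spec["g"]);
    if (kind == K_OMEGATFT) {
      dl_thresh = as<int>(spec["deadlock_threshold"]);
      rn_thresh = as<int>(spec["randomness_threshold"]);
    }
  }

  // Intended action in round t (1-based); own/opp hold executed actions of
  // rounds 1..t-1. first_override: 0/1/2 force the round-1 rule, 3 = use
  // the strategy's own rule.
  int decide(const std::vector<int> &own, const std::vector<int> &opp,
             int t, const double *pv, int first_override) {
    if (t == 1) {
      int rule = (first_override == 3) ? first_move : first_override;
      if (rule == 2) return (unif_rand() < 0.5) ? 0 : 1;
      return rule;
    }
    int o1 = opp[t - 2], m1 = own[t - 2];
    switch (kind) {
    case K_TABLE:
      return table[encode_state_cpp(own, opp, t, mem)];
    case K_REACTIVE1:
      return (unif_rand() < p[2 * m1 + o1]) ? 0 : 1;
    case K_TFT:
      return o1;
    case K_GTFT:
      if (o1 == 0) return 0;
      return (unif_rand() < g) ? 0 : 1;
    case K_WSLS: {
      double u = pv[2 * m1 + o1];
      bool success = (u == pv[0] || u == pv[2]);  // R or T
      return success ? m1 : 1 - m1;
    }
    case K_GRUDGE:
      return grudged ? 1 : 0;
    case K_FOOLMEONCE:
      if (defects >= 2) return 1;
      if (warn_pending) { warn_pending = false; return 1; }
      return 0;
    case K_OMEGATFT:
      if (randomness >= rn_thresh) return 1;
      if (deadlock > dl_thresh) { deadlock = 0; return 0; }
      return o1;
    case K_GRADUALTFT:
      if (punish_left > 0) {
        punish_left--; if (punish_left == 0) cool_left = 2;
        return 1;
      }
      if (cool_left > 0) { cool_left--; return 0; }
      if (o1 == 1) {
        punish_left = defects;  // one defection per opponent defection so far
        punish_left--; if (punish_left == 0) cool_left = 2;
        return 1;
      }
      return 0;
    case K_ALLC: return 0;
    case K_ALLD: return 1;
    }
    return 0;
  }

  // Update internal counters after a round; own/opp hold executed actions
  // of rounds 1..t (the round just played is the last entry).
  void observe(const std::vector<int> &own, const std::vector<int> &opp) {
    int t = (int)own.size();
    int o1 = opp[t - 1], m1 = own[t - 1];
    switch (kind) {
    case K_GRUDGE:
      if (o1 == 1) grudged = true;
      break;
    case K_FOOLMEONCE:
      if (o1 == 1) {
        defects++;
        if (defects == 1) warn_pending = true;
      }
      break;
    case K_GRADUALTFT:
      if (o1 == 1) defects++;
      break;
    case K_OMEGATFT:
      if (t >= 2) {
        int o2 = opp[t - 2], m2 = own[t - 2];
        if (o1 != o2 || o1 != m1) randomness++;
        else if (randomness > 0) randomness--;
        if (o1 != o2 && m1 != m2 && o1 != m1) deadlock++;
        else deadlock = 0;
      }
      break;
    default: break;
    }
  }
};

static void play_rounds(Strategy &A, Strategy &B, int L, double eta,
                        const double *pv, int fa, int fb,
                        std::vector<int> &actsA, std::vector<int> &actsB,
                        double &meanA, double &meanB,
                        std::vector<double> *payA = nullptr,
                        std::vector<double> *payB = nullptr) {
  A.reset(); B.reset();
  actsA.clear(); actsB.clear();
  actsA.reserve(L); actsB.reserve(L);
  double sumA = 0, sumB = 0;
  for (int t = 1; t <= L; ++t) {
    int ia = A.decide(actsA, actsB, t, pv, fa);
    int ib = B.decide(actsB, actsA, t, pv, fb);
    if (eta > 0) {
      if (unif_rand() < eta) ia = 1 - ia;
      if (unif_rand() < eta) ib = 1 - ib;
    }
    actsA.push_back(ia); actsB.push_back(ib);
    double uA = pv[2 * ia + ib], uB = pv[2 * ib + ia];
    sumA += uA; sumB += uB;
    if (payA) payA->push_back(uA);
    if (payB) payB->push_back(uB);
    A.observe(actsA, actsB);
    B.observe(actsB, actsA);
  }
  meanA = sumA / L; meanB = sumB / L;
}

// [[Rcpp::export]]
List cpp_play_match(List sa, List sb, int rounds, double eta,
                    NumericVector payoffs, int first_a, int first_b) {
  Strategy A, B;
  A.from_list(sa); B.from_list(sb);
  double pv[4] = {payoffs[0], payoffs[1], payoffs[2], payoffs[3]};
  std::vector<int> actsA, actsB;
  std::vector<double> payA, payB;
  double mA, mB;
  play_rounds(A, B, rounds, eta, pv, first_a, first_b,
              actsA, actsB, mA, mB, &payA, &payB);
  return List::create(
      _["actions_a"] = wrap(actsA), _["actions_b"] = wrap(actsB),
      _["payoffs_a"] = wrap(payA), _["payoffs_b"] = wrap(payB),
      _["mean_a"] = mA, _["mean_b"] = mB);
}

// [[Rcpp::export]]
List cpp_match_means(List sa, List sb, int rounds, double eta,
                     NumericVector payoffs, int n_reps,
                     int first_a, int first_b) {
  Strategy A, B;
  A.from_list(sa); B.from_list(sb);
  double pv[4] = {payoffs[0], payoffs[1], payoffs[2], payoffs[3]};
  std::vector<int> actsA, actsB;
  double sA = 0, sB = 0, ssA = 0, ssB = 0;
  for (int r = 0; r < n_reps; ++r) {
    double mA, mB;
    play_rounds(A, B, rounds, eta, pv, first_a, first_b, actsA, actsB, mA, mB);
    sA += mA; sB += mB; ssA += mA * mA; ssB += mB * mB;
  }
  double mA = sA / n_reps, mB = sB / n_reps;
  double vA = (n_reps > 1) ? (ssA - n_reps * mA * mA) / (n_reps - 1.0) : 0.0;
  double vB = (n_reps > 1) ? (ssB - n_reps * mB * mB) / (n_reps - 1.0) : 0.0;
  if (vA < 0) vA = 0;
  if (vB < 0) vB = 0;
  return List::create(
      _["mean_a"] = mA, _["mean_b"] = mB,
      _["se_a"] = std::sqrt(vA / n_reps), _["se_b"] = std::sqrt(vB / n_reps));
}

// Multi-agent Q-learning over L-round repeated games against a mixed pool
// of learning agents and fixed mentors. Per iteration: draw a learner and
// an opponent (mentor with probability mentor_prob), play one match with
// random first moves, then apply the win/lose-conditioned per-round reward
// and Bellman updates in ascending round order for each learning seat.
// [[Rcpp::export]]
List cpp_train(int n_agents, double i_total, int rounds, double eta,
               NumericVector payoffs, double alpha, double gamma,
               double theta, double epsilon, int mem, List mentors,
               double mentor_prob, double init_range) {
  int n_states = 0, pw = 1;
  for (int j = 1; j <= mem; ++j) { pw *= 4; n_states += pw; }
  int n_mentors = mentors.size();
  double pv[4] = {payoffs[0], payoffs[1], payoffs[2], payoffs[3]};

  std::vector<std::vector<double>> Q(n_agents,
                                     std::vector<double>(n_states * 2, 0.0));
  if (init_range > 0)
    for (auto &q : Q)
      for (auto &v : q) v = unif_rand() * init_range;

  std::vector<Strategy> mentor_pool(n_mentors);
  for (int m = 0; m < n_mentors; ++m)
    mentor_pool[m].from_list(mentors[m]);

  std::vector<int> acts1, acts2, s1(rounds + 2), s2(rounds + 2),
      a1(rounds + 1), a2(rounds + 1);
  std::vector<double> u1(rounds + 1), u2(rounds + 1), w1(rounds + 1),
      w2(rounds + 1);

  long long total = (long long)i_total;
  for (long long it = 0; it < total; ++it) {
    int p1 = rand_int(n_agents);
    bool p2_mentor = (n_mentors > 0) && (unif_rand() < mentor_prob);
    int p2 = p2_mentor ? rand_int(n_mentors) : rand_int(n_agents);
    Strategy *ment = p2_mentor ? &mentor_pool[p2] : nullptr;
    if (ment) ment->reset();

    acts1.clear(); acts2.clear();
    for (int t = 1; t <= rounds; ++t) {
      s1[t] = encode_state_cpp(acts1, acts2, t, mem);
      s2[t] = encode_state_cpp(acts2, acts1, t, mem);
      int ia, ib;
      if (t == 1) ia = (unif_rand() < 0.5) ? 0 : 1;
      else if (unif_rand() < epsilon) ia = rand_int(2);
      else ia = (Q[p1][s1[t] * 2 + 1] > Q[p1][s1[t] * 2]) ? 1 : 0;
      if (ment) {
        ib = ment->decide(acts2, acts1, t, pv, 3);
      } else if (t == 1) {
        ib = (unif_rand() < 0.5) ? 0 : 1;
      } else if (unif_rand() < epsilon) {
        ib = rand_int(2);
      } else {
        ib = (Q[p2][s2[t] * 2 + 1] > Q[p2][s2[t] * 2]) ? 1 : 0;
      }
      if (eta > 0) {
        if (unif_rand() < eta) ia = 1 - ia;
        if (unif_rand() < eta) ib = 1 - ib;
      }
      acts1.push_back(ia); acts2.push_back(ib);
      a1[t] = ia; a2[t] = ib;
      u1[t] = pv[2 * ia + ib]; u2[t] = pv[2 * ib + ia];
      if (ment) ment->observe(acts2, acts1);
    }
    // bootstrap state after round L (episode treated as continuing)
    s1[rounds + 1] = encode_state_cpp(acts1, acts2, rounds + 1, mem);
    s2[rounds + 1] = encode_state_cpp(acts2, acts1, rounds + 1, mem);

    double m1 = 0, m2 = 0;
    for (int t = 1; t <= rounds; ++t) { m1 += u1[t]; m2 += u2[t]; }
    m1 /= rounds; m2 /= rounds;

    for (int t = 2; t <= rounds; ++t) {
      w1[t] = theta * u1[t] + ((m1 >= m2) ? (1 - theta) * m1 : 0.0);
      w2[t] = theta * u2[t] + ((m2 >= m1) ? (1 - theta) * m2 : 0.0);
    }
    for (int t = 2; t <= rounds; ++t) {
      int s = s1[t], sn = s1[t + 1];
      double qmax = std::max(Q[p1][sn * 2], Q[p1][sn * 2 + 1]);
      double &qv = Q[p1][s * 2 + a1[t]];
      qv += alpha * (w1[t] + gamma * qmax - qv);
      if (!ment) {
        int sB = s2[t], snB = s2[t + 1];
        double qmaxB = std::max(Q[p2][snB * 2], Q[p2][snB * 2 + 1]);
        double &qvB = Q[p2][sB * 2 + a2[t]];
        qvB += alpha * (w2[t] + gamma * qmaxB - qvB);
      }
    }
  }

  List out(n_agents);
  for (int a = 0; a < n_agents; ++a) {
    NumericMatrix m(n_states, 2);
    for (int s = 0; s < n_states; ++s) {
      m(s, 0) = Q[a][s * 2];
      m(s, 1) = Q[a][s * 2 + 1];
    }
    out[a] = m;
  }
  return out;
}

// Well-mixed Fermi imitation dynamics with mutation, using mean-field
// (payoff-matrix) payoffs: Ubar_i = (sum_k a_ik X_k - a_ii) / (N - 1).
// One elementary event = pick a focal individual; with probability mu it
// adopts a uniform-random pool strategy, otherwise it compares against a
// random other individual and imitates with the Fermi probability.
// [[Rcpp::export]]
List cpp_evolve_matrix(NumericMatrix A, IntegerVector counts0, double delta,
                       double mu, double n_events, int stride,
                       double burn_in, bool stop_when_absorbed) {
  int n = A.nrow();
  std::vector<long long> X(n);
  long long N = 0;
  for (int i = 0; i < n; ++i) { X[i] = counts0[i]; N += X[i]; }

  auto ubar = [&](int i) {
    double s = 0;
    for (int k = 0; k < n; ++k) s += A(i, k) * X[k];
    s -= A(i, i);
    return s / (double)(N - 1);
  };
  auto pick_by_counts = [&](long long total, int skip_one_of) {
    // draw an individual; if skip_one_of >= 0 one individual of that
    // strategy is excluded (the focal player)
    double r = unif_rand() * (double)total;
    double c = 0;
    for (int k = 0; k < n; ++k) {
      double w = (double)X[k] - ((k == skip_one_of) ? 1.0 : 0.0);
      c += w;
      if (r < c) return k;
    }
    return n - 1;
  };

  long long total_events = (long long)n_events;
  long long burn = (long long)burn_in;
  int n_rec = (int)(total_events / stride) + 1;
  NumericMatrix traj(n_rec, n);
  NumericVector traj_payoff(n_rec), traj_event(n_rec);
  std::vector<double> acc(n, 0.0);
  long long acc_n = 0;
  int rec = 0;

  auto record = [&](long long ev) {
    if (rec >= n_rec) return;
    double mp = 0;
    for (int k = 0; k < n; ++k)
      if (X[k] > 0) mp += (double)X[k] * ubar(k);
    traj_payoff[rec] = mp / (double)N;
    traj_event[rec] = (double)ev;
    for (int k = 0; k < n; ++k) traj(rec, k) = (double)X[k] / (double)N;
    rec++;
  };

  record(0);
  long long ev = 0;
  for (ev = 1; ev <= total_events; ++ev) {
    int i = pick_by_counts(N, -1);
    if (mu > 0 && unif_rand() < mu) {
      int k = rand_int(n);
      X[i]--; X[k]++;
    } else {
      int j = pick_by_counts(N - 1, i);
      if (j != i) {
        double ui = ubar(i), uj = ubar(j);
        double pimit = 1.0 / (1.0 + std::exp(delta * (ui - uj)));
        if (unif_rand() < pimit) { X[i]--; X[j]++; }
      }
    }
    if (ev > burn) {
      for (int k = 0; k < n; ++k) acc[k] += (double)X[k];
      acc_n++;
    }
    if (ev % stride == 0) record(ev);
    if (stop_when_absorbed && mu == 0) {
      bool mono = false;
      for (int k = 0; k < n; ++k)
        if (X[k] == N) { mono = true; break; }
      if (mono) break;
    }
  }
  if (ev > total_events) ev = total_events;

  NumericVector avg(n), fin(n);
  for (int k = 0; k < n; ++k) {
    avg[k] = (acc_n > 0) ? acc[k] / ((double)acc_n * N) : NA_REAL;
    fin[k] = (double)X[k];
  }
  return List::create(
      _["trajectory"] = traj(Range(0, rec - 1), _),
      _["traj_payoff"] = traj_payoff[Range(0, rec - 1)],
      _["traj_event"] = traj_event[Range(0, rec - 1)],
      _["avg_freq"] = avg, _["final_counts"] = fin,
      _["events_run"] = (double)ev);
}

// [[Rcpp::export]]
int cpp_encode_state(IntegerVector own, IntegerVector opp, int mem) {
  std::vector<int> o(own.begin(), own.end()), p(opp.begin(), opp.end());
  return encode_state_cpp(o, p, (int)o.size() + 1, mem);
}
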