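#include <Rcpp.h>
using namespace Rcpp;

// Integer encodings at the C++ boundary (R wrappers translate labels):
//   odor:   0 = left_forced, 1 = right_forced, 2 = free
//   action: 0 = left, 1 = right
//   model:  1 = four_state, 2 = six_state, 3 = hybrid_value, 4 = hybrid_learning
// Parameter vector (fixed order): eta, gamma, beta, b, p, lambda, w4, eta_g
//
// Four-state table: 0 Left, 1 Right, 2 Left-NoRwd, 3 Right-NoRwd.
// Six-state table: odor * 2 + action (one state per odor/action pair).

static inline bool is_valid(int odor, int action) {
  return odor == 2 || odor == action;
}

static inline int s4_index(int odor, int action) {
  // valid pairs share Left/Right; invalid forced pairs hit the chosen
  // side's NoRwd state
  return is_valid(odor, action) ? action : 2 + action;
}

static inline int s6_index(int odor, int action) {
  return odor * 2 + action;
}

// paired same-side state for generalization (valid forced <-> free);
// -1 when the state has no pair (invalid forced states)
static inline int s6_pair(int odor, int action) {
  if (odor == 2) return s6_index(action, action);     // free -> valid forced
  if (odor == action) return s6_index(2, action);     // valid forced -> free
  return -1;
}

static inline double action_value(int model, int odor, int action,
                                  const double* V4, const double* V6,
                                  double w4) {
  switch (model) {
  case 1: return V4[s4_index(odor, action)];
  case 3: return w4 * V4[s4_index(odor, action)] +
                 (1.0 - w4) * V6[s6_index(odor, action)];
  default: return V6[s6_index(odor, action)];          // six_state, hybrid_learning
  }
}

static inline double p_left(int model, int odor, int prev,
                            const double* V4, const double* V6,
                            double beta, double b, double p, double lambda,
                            double w4) {
  double dvl = action_value(model, odor, 0, V4, V6, w4);
  double dvr = action_value(model, odor, 1, V4, V6, w4) + b;
  if (prev == 0) dvl += p;
  if (prev == 1) dvr += p;
  return (1.0 - lambda) / (1.0 + std::exp(-beta * (dvl - dvr))) + lambda / 2.0;
}

static inline void update_tables(int model, int odor, int action, bool valid,
                                 double r, double d, double* V4, double* V6,
                                 double eta, double gamma, double eta_g) {
  // unrewarded outcomes (r = 0) have target 0 regardless of delay
  double target = (valid && r > 0.0) ? std::pow(gamma, d) * r : 0.0;
  if (model == 1 || model == 3) {
    int i4 = s4_index(odor, action);
    V4[i4] += eta * (target - V4[i4]);
  }
  if (model != 1) {
    int i6 = s6_index(odor, action);
    V6[i6] += eta * (target - V6[i6]);
    if (model == 4 && valid) {
      int ip = s6_pair(odor, action);
      if (ip >= 0) V6[ip] += eta_g * (target - V6[ip]);
    }
  }
}

// Per-trial choice probabilities and log-likelihood of recorded choices.
// new_session marks trials where value tables and the perseveration memory
// reset (no carry-over across sessions by default).
// [[Rcpp::export]]
List cpp_trial_probs(int model, NumericVector params, IntegerVector odor,
                     IntegerVector choice, LogicalVector valid,
                     IntegerVector drops, NumericVector delay,
                     LogicalVector new_session, bool carry_over) {
  int n = odor.size();
  double eta = params[0], gamma = params[1], beta = params[2];
  double b = params[3], p = params[4], lambda = params[5];
  double w4 = params[6], eta_g = params[7];
  double V4[4] = {0, 0, 0, 0};
  double V6[6] = {0, 0, 0, 0, 0, 0};
  int prev = -1;
  NumericVector pl(n), ll(n);
  for (int t = 0; t < n; ++t) {
    if (new_session[t]) {
      prev = -1;
      if (!carry_over) {
        std::fill(V4, V4 + 4, 0.0);
        std::fill(V6, V6 + 6, 0.0);
      }
    }
    double pr = p_left(model, odor[t], prev, V4, V6, beta, b, p, lambda, w4);
    pl[t] = pr;
    ll[t] = std::log(choice[t] == 0 ? pr : 1.0 - pr);
    double d = NumericVector::is_na(delay[t]) ? 1.0 : delay[t];
    update_tables(model, odor[t], choice[t], valid[t], (double)drops[t], d,
                  V4, V6, eta, gamma, eta_g);
    prev = choice[t];
  }
  return List::create(_["p_left"] = pl, _["loglik"] = ll);
}

// Closed-loop simulation of one session: the agent chooses stochastically,
// outcomes are resolved against the block contingencies, and free choices
// of the long side in delay blocks drive the adaptive delay staircase.
// better_left[t] is TRUE when the left well holds the better outcome
// (short or big) on trial t; block_type[t] is 0 for delay, 1 for magnitude.
// [[Rcpp::export]]
List cpp_simulate_session(int model, NumericVector params, IntegerVector odor,
                          IntegerVector block_type, LogicalVector better_left,
                          double stair_delay, double stair_step_up,
                          double stair_step_down, double stair_min,
                          double stair_max) {
  int n = odor.size();
  double eta = params[0], gamma = params[1], beta = params[2];
  double b = params[3], p = params[4], lambda = params[5];
  double w4 = params[6], eta_g = params[7];
  double V4[4] = {0, 0, 0, 0};
  double V6[6] = {0, 0, 0, 0, 0, 0};
  int prev = -1;
  IntegerVector choice(n), drops(n);
  LogicalVector valid(n), correct(n);
  NumericVector delay(n), pl(n), stair_trace(n);
  RNGScope rng;
  for (int t = 0; t < n; ++t) {
    double pr = p_left(model, odor[t], prev, V4, V6, beta, b, p, lambda, w4);
    pl[t] = pr;
    int a = (unif_rand() < pr) ? 0 : 1;
    bool v = is_valid(odor[t], a);
    bool chose_better = (a == 0) == (bool)better_left[t];
    int r;
    double d;
    if (!v) {
      r = 0;
      d = NA_REAL;
    } else if (block_type[t] == 1) {           // magnitude block
      r = chose_better ? 2 : 1;
      d = 0.5;
    } else {                                   // delay block
      r = 1;
      d = chose_better ? 0.5 : stair_delay;
    }
    choice[t] = a;
    valid[t] = v;
    drops[t] = r;
    delay[t] = d;
    correct[t] = (odor[t] == 2) ? chose_better : v;
    stair_trace[t] = stair_delay;
    if (block_type[t] == 0 && odor[t] == 2) {  // free choice in a delay block
      stair_delay += chose_better ? -stair_step_down : stair_step_up;
      if (stair_delay < stair_min) stair_delay = stair_min;
      if (stair_delay > stair_max) stair_delay = stair_max;
    }
    double d_upd = ISNA(d) ? 1.0 : d;
    update_tables(model, odor[t], a, v, (double)r, d_upd,
                  V4, V6, eta, gamma, eta_g);
    prev = a;
  }
  return List::create(_["choice"] = choice, _["valid"] = valid,
                      _["reward_drops"] = drops, _["reward_delay_s"] = delay,
                      _["correct"] = correct, _["p_left"] = pl,
                      _["staircase_delay"] = stair_trace,
                      _["stair_end"] = stair_delay);
}
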