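#include <Rcpp.h>
using namespace Rcpp;

// Prospect utility of a reward: gains curved by mu, losses curved by nu and
// scaled by loss aversion lam; zero maps to zero utility.
static inline double utility_scalar(double reward, double mu, double nu,
                                    double lam) {
  if (reward > 0.0) return std::pow(reward, mu);
  if (reward < 0.0) return -lam * std::pow(-reward, nu);
  return 0.0;
}

// Overflow-safe two-option softmax: probability of option 1.
static inline double softmax_p1(double q1, double q2, double beta) {
  double x1 = beta * q1, x2 = beta * q2;
  double m = (x1 > x2) ? x1 : x2;
  double e1 = std::exp(x1 - m), e2 = std::exp(x2 - m);
  return e1 / (e1 + e2);
}

//' @name ll_qlearn_cpp
//' Forward-filter log-likelihood of a choice/reward sequence under the
//' prospect-utility Q-learning model. choices are 1 (right) / 2 (left);
//' Q starts at zero for both options. delta >= 0 takes the alpha_pos branch;
//' phi is added to the chosen option's value on every trial.
// [[Rcpp::export]]
double ll_qlearn_cpp(IntegerVector choices, NumericVector rewards,
                     double beta, double mu, double nu, double alpha_pos,
                     double alpha_neg, double lam, double phi) {
  int n = choices.size();
  double q1 = 0.0, q2 = 0.0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    // log P(choice) via log-sum-exp: finite even when the softmax
    // probability itself underflows to 0 in double precision
    double x1 = beta * q1, x2 = beta * q2;
    double m = (x1 > x2) ? x1 : x2;
    double lse = m + std::log(std::exp(x1 - m) + std::exp(x2 - m));
    int c = choices[t];
    ll += ((c == 1) ? x1 : x2) - lse;
    double u = utility_scalar(rewards[t], mu, nu, lam);
    if (c == 1) {
      double delta = u - q1;
      q1 += ((delta >= 0.0) ? alpha_pos : alpha_neg) * delta + phi;
    } else {
      double delta = u - q2;
      q2 += ((delta >= 0.0) ? alpha_pos : alpha_neg) * delta + phi;
    }
    if (!std::isfinite(q1) || !std::isfinite(q2)) return R_NegInf;
  }
  return ll;
}

//' @name simulate_qlearn_cpp
//' Forward simulation of one agent. p_win_right/p_win_left give the win
//' probability of each box per trial; u_choice/u_reward are pre-drawn
//' uniforms, one per trial position, so probing one trial's draw cannot
//' shift another's. Choice by inverse CDF: right iff u_choice < P(right).
// [[Rcpp::export]]
List simulate_qlearn_cpp(double beta, double mu, double nu, double alpha_pos,
                         double alpha_neg, double lam, double phi,
                         NumericVector p_win_right, NumericVector p_win_left,
                         double reward_win, double reward_loss,
                         NumericVector u_choice, NumericVector u_reward) {
  int n = p_win_right.size();
  IntegerVector choice(n);
  NumericVector reward(n), utility(n), delta(n), p_right(n);
  NumericVector q_right_before(n), q_left_before(n);
  NumericVector q_right_after(n), q_left_after(n);
  double q1 = 0.0, q2 = 0.0;
  for (int t = 0; t < n; ++t) {
    double p1 = softmax_p1(q1, q2, beta);
    p_right[t] = p1;
    q_right_before[t] = q1;
    q_left_before[t] = q2;
    int c = (u_choice[t] < p1) ? 1 : 2;
    choice[t] = c;
    double pwin = (c == 1) ? p_win_right[t] : p_win_left[t];
    double r = (u_reward[t] < pwin) ? reward_win : reward_loss;
    reward[t] = r;
    double u = utility_scalar(r, mu, nu, lam);
    utility[t] = u;
    if (c == 1) {
      double d = u - q1;
      delta[t] = d;
      q1 += ((d >= 0.0) ? alpha_pos : alpha_neg) * d + phi;
    } else {
      double d = u - q2;
      delta[t] = d;
      q2 += ((d >= 0.0) ? alpha_pos : alpha_neg) * d + phi;
    }
    q_right_after[t] = q1;
    q_left_after[t] = q2;
  }
  return List::create(
      _["choice"] = choice, _["reward"] = reward, _["utility"] = utility,
      _["delta"] = delta, _["p_right"] = p_right,
      _["q_right_before"] = q_right_before, _["q_left_before"] = q_left_before,
      _["q_right_after"] = q_right_after, _["q_left_after"] = q_left_after);
}
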